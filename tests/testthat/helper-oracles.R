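# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Queue-based flood fill connected-component labeling.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- r + nb[k, 1]; c2 <- c + nb[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- r2 + (c2 - 1L) * nr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# All-pairs Theil-Sen.
allpairs_sen <- function(x, y) {
  s <- c()
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j > i && x[j] != x[i]) s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
  }
  median(s)
}

# Sort-based percentile with linear interpolation between order statistics.
sort_percentile <- function(v, p) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  if (n == 0) return(NA_real_)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo + 1 >= n) return(v[n])
  v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
}

# Exhaustive continuous piecewise-linear least squares: minimum SSE over all
# interior-knot subsets of size <= max_segments - 1, solved with lm() on the
# hinge basis.
brute_force_segments_sse <- function(y, x = seq_along(y), max_segments = 3) {
  n <- length(y)
  cand <- x[2:(n - 1)]
  best <- sum(resid(lm(y ~ x))^2)
  for (k in seq_len(max_segments - 1)) {
    for (s in combn(cand, k, simplify = FALSE)) {
      d <- data.frame(y = y, x = x)
      fm <- y ~ x
      for (j in seq_along(s)) {
        d[[paste0("h", j)]] <- pmax(x - s[j], 0)
        fm <- stats::update(fm, paste(". ~ . +", paste0("h", j)))
      }
      sse <- sum(resid(lm(fm, data = d))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Morphological opening by direct set arithmetic with the cross element.
brute_opening <- function(mask, iterations = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  shift_ok <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    vr <- rs >= 1 & rs <= nr; vc <- cs >= 1 & cs <= nc
    out[vr, vc] <- m[rs[vr], cs[vc]]
    out
  }
  erode1 <- function(m)
    m & shift_ok(m, 1, 0) & shift_ok(m, -1, 0) & shift_ok(m, 0, 1) &
    shift_ok(m, 0, -1)
  dilate1 <- function(m)
    m | shift_ok(m, 1, 0) | shift_ok(m, -1, 0) | shift_ok(m, 0, 1) |
    shift_ok(m, 0, -1)
  for (i in seq_len(iterations)) mask <- erode1(mask)
  for (i in seq_len(iterations)) mask <- dilate1(mask)
  mask
}
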