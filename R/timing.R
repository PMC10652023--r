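#' Control parameters for temporal segmentation
#'
#' Parameters of the piecewise-linear spectral-temporal segmentation used to
#' date drainage events, following the canonical values of the
#' disturbance-detection algorithm family the method builds on.
#'
#' @param max_segments Maximum number of linear segments (>= 1).
#' @param spike_threshold Despiking strength in `(0, 1]`; 1 disables
#'   despiking (see [despike()]).
#' @param recovery_threshold Maximum allowed recovery rate as a fraction of
#'   the series range per year for increasing segments; values >= 1 disable
#'   the filter.
#' @param pval_threshold If the selected multi-segment model does not improve
#'   on a constant fit at this F-test level, the fit collapses to a single
#'   segment.
#' @param best_model_proportion In `(0, 1]`: among candidate models the
#'   fewest-segment one whose SSE is at most `best SSE / best_model_proportion`
#'   is returned.
#' @param min_observations Minimum non-missing observations required to fit;
#'   must be at least `max_segments + 1`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(max_segments = 6,
                                spike_threshold = 0.9,
                                recovery_threshold = 0.25,
                                pval_threshold = 0.05,
                                best_model_proportion = 0.75,
                                min_observations = max_segments + 1) {
  stopifnot(max_segments >= 1,
            spike_threshold > 0, spike_threshold <= 1,
            recovery_threshold > 0,
            best_model_proportion > 0, best_model_proportion <= 1,
            min_observations >= max_segments + 1)
  structure(list(max_segments = as.integer(max_segments),
                 spike_threshold = spike_threshold,
                 recovery_threshold = recovery_threshold,
                 pval_threshold = pval_threshold,
                 best_model_proportion = best_model_proportion,
                 min_observations = as.integer(min_observations)),
            class = "segmentation_params")
}

#' Dampen single-year spikes in an annual series
#'
#' An interior point is treated as a spike when it is a strict local
#' extremum, its deviation from the mean of its neighbours exceeds
#' `(1 - spike_threshold)` times the local (three-point) range, and the two
#' neighbours agree with each other to within the same tolerance (a genuine
#' one-year spike departs from a locally consistent level and returns to
#' it; a persistent step change does not, and is preserved). Spikes are
#' replaced by the neighbour mean. Endpoints are never touched;
#' `spike_threshold = 1` is the identity, and any monotone series passes
#' through unchanged.
#'
#' @param series Numeric vector (length >= 3); `NA`s are left in place and
#'   never used as neighbours.
#' @param spike_threshold In `(0, 1]`.
#' @return The despiked series.
#' @export
despike <- function(series, spike_threshold = 0.9) {
  n <- length(series)
  stopifnot(n >= 3, spike_threshold > 0, spike_threshold <= 1)
  if (spike_threshold >= 1) return(series)
  out <- series
  for (i in 2:(n - 1)) {
    y0 <- series[i - 1]; y1 <- series[i]; y2 <- series[i + 1]
    if (anyNA(c(y0, y1, y2))) next
    extremum <- (y1 > y0 && y1 > y2) || (y1 < y0 && y1 < y2)
    if (!extremum) next
    m <- (y0 + y2) / 2
    rng <- max(y0, y1, y2) - min(y0, y1, y2)
    tol <- (1 - spike_threshold) * rng
    if (abs(y1 - m) > tol && abs(y0 - y2) <= tol) out[i] <- m
  }
  out
}

# Continuous piecewise-linear least squares for a fixed interior-knot set,
# via the hinge basis [1, x, (x - k)+]. Returns sse and the coefficient fit.
fit_knots <- function(x, y, knots) {
  X <- cbind(1, x)
  for (k in knots) X <- cbind(X, pmax(x - k, 0))
  f <- stats::.lm.fit(X, y)
  list(sse = sum(f$residuals^2), coefficients = f$coefficients, knots = knots)
}

predict_knots <- function(fit, x) {
  X <- cbind(1, x)
  for (k in fit$knots) X <- cbind(X, pmax(x - k, 0))
  drop(X %*% fit$coefficients)
}

# Recovery-rate filter: reject models containing an increasing segment that
# recovers faster than `recovery_threshold` of the series range per year.
recovery_ok <- function(fit, x, yrange, threshold) {
  if (threshold >= 1 || yrange <= 0) return(TRUE)
  vx <- sort(unique(c(min(x), fit$knots, max(x))))
  vy <- predict_knots(fit, vx)
  dv <- diff(vy); dt <- diff(vx)
  !any(dv > 0 & (dv / yrange) / dt > threshold + 1e-12)
}

#' Piecewise-linear segmentation of an annual index series
#'
#' Fits a continuous piecewise-linear model with vertices at observed years.
#' For every segment count from 1 to `max_segments` a best interior-knot set
#' is found -- by exhaustive subset enumeration when the number of candidate
#' placements is small (the exact branch), otherwise by greedy forward
#' insertion of the knot that most reduces the residual sum of squares.
#' Among the candidate models, the one with the fewest segments whose SSE is
#' within `best_model_proportion` of the best is selected; an F-test against
#' the constant fit (`pval_threshold`) guards against overfitting pure noise.
#'
#' @param series Numeric vector of annual values (`NA` allowed).
#' @param params A [segmentation_params()].
#' @param years Observation years (default consecutive integers).
#' @param exhaustive_limit Maximum number of knot subsets enumerated before
#'   switching to the greedy search.
#' @return A `segmentation` object: `vertices` (data frame `year`, `value`),
#'   `slopes`, `sse`, `n_segments`, `fitted`, `years`; or `NULL` when fewer
#'   than `min_observations` values are available.
#' @export
fit_segments <- function(series, params = segmentation_params(),
                         years = seq_along(series),
                         exhaustive_limit = 1000) {
  ok <- !is.na(series)
  x <- as.numeric(years[ok]); y <- as.numeric(series[ok])
  n <- length(y)
  if (n < params$min_observations) return(NULL)
  yrange <- diff(range(y))
  max_knots <- min(params$max_segments - 1L, n - 2L)
  cand <- x[seq(2, n - 1)]
  filt <- function(fit) recovery_ok(fit, x, yrange, params$recovery_threshold)

  models <- vector("list", max_knots + 1L)
  models[[1]] <- fit_knots(x, y, numeric(0))
  n_subsets <- sum(vapply(seq_len(max_knots),
                          function(k) choose(length(cand), k), 1))
  if (max_knots >= 1) {
    if (is.finite(n_subsets) && n_subsets <= exhaustive_limit) {
      for (k in seq_len(max_knots)) {
        best <- NULL
        sets <- combn(cand, k, simplify = FALSE)
        for (s in sets) {
          f <- fit_knots(x, y, s)
          if (!filt(f)) next
          if (is.null(best) || f$sse < best$sse - 1e-12) best <- f
        }
        models[[k + 1L]] <- best
      }
    } else {
      knots <- numeric(0)
      for (k in seq_len(max_knots)) {
        best <- NULL
        for (kn in setdiff(cand, knots)) {
          f <- fit_knots(x, y, sort(c(knots, kn)))
          if (is.null(best) || f$sse < best$sse - 1e-12) best <- f
        }
        if (is.null(best)) break
        knots <- best$knots
        models[[k + 1L]] <- if (filt(best)) best else NULL
      }
    }
  }
  models <- Filter(Negate(is.null), models)
  sses <- vapply(models, `[[`, 1, "sse")
  best_sse <- min(sses)
  sel <- which(sses <= best_sse / params$best_model_proportion + 1e-12)[1]
  fit <- models[[sel]]

  # collapse to the straight-line fit when the chosen model does not beat a
  # constant at the configured level
  if (length(fit$knots) > 0 && yrange > 0) {
    sst <- sum((y - mean(y))^2)
    df1 <- length(fit$coefficients) - 1L
    df2 <- n - length(fit$coefficients)
    if (df2 > 0 && fit$sse > 0) {
      F <- ((sst - fit$sse) / df1) / (fit$sse / df2)
      p <- pf(F, df1, df2, lower.tail = FALSE)
      if (p > params$pval_threshold) fit <- models[[1]]
    }
  }

  vx <- sort(unique(c(min(x), fit$knots, max(x))))
  vy <- predict_knots(fit, vx)
  fitted <- predict_knots(fit, x)
  structure(list(vertices = data.frame(year = vx, value = vy),
                 slopes = diff(vy) / diff(vx),
                 sse = fit$sse, best_sse = best_sse,
                 n_segments = length(vx) - 1L,
                 fitted = fitted, years = x),
            class = "segmentation")
}

#' Disturbance year of one pixel from its segmentation
#'
#' Among segments with the requested sign of change and absolute fitted
#' change of at least `min_magnitude`, returns the end year of the
#' largest-magnitude one (water loss appears as a decrease in AWEI). `NA`
#' when no segment qualifies.
#'
#' @param seg A `segmentation` from [fit_segments()] (or `NULL`).
#' @param direction `"decrease"` (default; water loss) or `"increase"`.
#' @param min_magnitude Minimum absolute change of the fitted value across
#'   the segment.
#' @param use `"end"` (default): report the segment end year, the first year
#'   the new state is observed; `"start"` reports the last pre-change year.
#' @return Integer year or `NA`.
#' @export
pixel_disturbance_year <- function(seg, direction = c("decrease", "increase"),
                                   min_magnitude = 0, use = c("end", "start")) {
  direction <- match.arg(direction)
  use <- match.arg(use)
  if (is.null(seg)) return(NA_integer_)
  dv <- diff(seg$vertices$value)
  qual <- if (direction == "decrease") dv < 0 else dv > 0
  qual <- qual & abs(dv) >= min_magnitude
  if (!any(qual)) return(NA_integer_)
  i <- which(qual)[which.max(abs(dv)[qual])]
  yr <- if (use == "end") seg$vertices$year[i + 1L] else seg$vertices$year[i]
  as.integer(yr)
}

#' Lake-level drainage year from per-pixel disturbance years
#'
#' The modal year over the lake's dated pixels; ties are broken by the
#' earliest year. `NA`s (undated pixels) are ignored; if no pixel is dated
#' the result is `NA` and the event is retained as unresolved.
#'
#' @param pixel_years Integer vector of per-pixel disturbance years
#'   (may contain `NA`).
#' @return Integer year or `NA`.
#' @export
lake_drainage_year <- function(pixel_years) {
  ys <- pixel_years[!is.na(pixel_years)]
  if (length(ys) == 0) return(NA_integer_)
  u <- sort(unique(ys))
  counts <- vapply(u, function(v) sum(ys == v), 1L)
  as.integer(u[which.max(counts)])
}

#' Date drainage events by per-pixel temporal segmentation
#'
#' For every detected event, segments the annual AWEI composite series of
#' each footprint pixel that the fused loss mask marks as lost, extracts the
#' per-pixel disturbance year (largest decrease), and assigns the lake-level
#' drainage year as the mode.
#'
#' @param events Event table from [detect_drainage_events()].
#' @param pixels Footprint index list from [label_objects()].
#' @param awei_composites Named list (by year) of AWEI composite matrices.
#' @param loss_mask Fused loss mask.
#' @param params A [segmentation_params()].
#' @param min_magnitude Minimum AWEI drop for a pixel to count as disturbed.
#' @return `events` with `detected_year` and `n_dated_pixels` filled in.
#' @export
date_events <- function(events, pixels, awei_composites, loss_mask,
                        params = segmentation_params(), min_magnitude = 0.2) {
  if (nrow(events) == 0) {
    events$n_dated_pixels <- integer(0)
    return(events)
  }
  years <- as.integer(names(awei_composites))
  events$n_dated_pixels <- 0L
  for (e in seq_len(nrow(events))) {
    idx <- pixels[[as.character(events$lake_id[e])]]
    idx <- idx[loss_mask[idx]]
    if (length(idx) == 0) next
    series_mat <- vapply(awei_composites, function(m) m[idx],
                         numeric(length(idx)))
    if (is.null(dim(series_mat)))
      series_mat <- matrix(series_mat, nrow = length(idx))
    py <- vapply(seq_len(length(idx)), function(i) {
      s <- despike(series_mat[i, ], params$spike_threshold)
      seg <- fit_segments(s, params, years)
      pixel_disturbance_year(seg, "decrease", min_magnitude)
    }, NA_integer_)
    events$detected_year[e] <- lake_drainage_year(py)
    events$n_dated_pixels[e] <- sum(!is.na(py))
  }
  events
}
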