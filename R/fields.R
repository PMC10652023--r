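# Smooth Gaussian random fields, used for covariate and attribute layers.
# White noise is convolved (circularly, via FFT) with a Gaussian kernel and
# rescaled to zero mean / unit sd; callers scale and shift as needed.
gaussian_field <- function(nr, nc, range_px) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (range_px <= 0) return(w)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  kr <- exp(-0.5 * (dr / range_px)^2)
  kc <- exp(-0.5 * (dc / range_px)^2)
  K <- outer(kr, kc)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / sd(f)
}

# Threshold a field into k classes with target areal proportions.
classify_field <- function(field, mix) {
  mix <- mix / sum(mix)
  qs <- quantile(field, probs = cumsum(mix)[-length(mix)], names = FALSE)
  cls <- findInterval(field, qs) + 1L
  matrix(as.integer(cls), nrow(field), ncol(field))
}
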