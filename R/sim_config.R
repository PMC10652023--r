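#' Simulation configuration for synthetic Arctic lake scenes
#'
#' Builds and validates the parameter set controlling [simulate_scene()].
#' Defaults describe a 30 m, 2000-2020 scene whose statistical structure
#' mirrors the inputs of the circum-Arctic drainage analysis the package
#' implements: a truncated-Pareto lake-size spectrum dominated by small
#' (1-10 ha) lakes, a drained subset selected by a logistic model on lake
#' covariates, per-product omission/commission noise on the water-loss masks,
#' multi-observation annual reflectance with cloud dropouts and spikes, and
#' class-dependent post-drainage NDVI recovery (thermokarst basins overshoot
#' their surroundings by +0.06, non-thermokarst basins settle 0.09 below).
#'
#' @param grid_rows,grid_cols Pixel counts of the scene grid.
#' @param pixel_size Pixel edge length in meters (default 30).
#' @param years Inclusive calendar span of annual observations.
#' @param n_lakes Number of lakes to place.
#' @param area_log10_range Length-2 numeric, log10 lake area range in hectares.
#' @param area_pareto_exponent Pareto exponent of the lake-area spectrum
#'   (density ~ A^-a); 1.8 reproduces small/medium/large shares of roughly
#'   84/14/2 percent.
#' @param drain_prob_coefs Named coefficients of the logistic drainage model
#'   over standardized lake covariates. Recognised names: `intercept`,
#'   `air_temp_mean`, `elevation`, `active_layer`, `air_temp_trend`.
#' @param class_mix Named proportions of thermokarst-likelihood classes
#'   (`very_likely`, `likely`, `unlikely`); must sum to 1.
#' @param recovery_params Per-class list of `c(N0, delta_inf, tau)` for the
#'   exponential NDVI recovery curve (see [ndvi_recovery()]).
#' @param obs_per_year Number of valid-season observations per year.
#' @param obs_noise_sd Per-band reflectance noise standard deviation.
#' @param cloud_dropout_prob Probability that a pixel-observation is masked
#'   by the QA band.
#' @param spike_prob Probability per pixel-year that one observation is
#'   replaced by a haze-contaminated outlier.
#' @param product_error List with elements `jrc_like` and `glad_like`, each a
#'   named vector `c(omission, commission)` of per-pixel error probabilities.
#' @param drain_year_range Length-2 calendar-year range the true drainage
#'   years are drawn from; defaults to the year span trimmed by two years on
#'   either end.
#' @param residual_mix Data frame (`weight`, `lo`, `hi`) describing the
#'   mixture from which a drained lake's remnant-pond area fraction is drawn.
#'   The default leaves most drained lakes with small remnant ponds and gives
#'   roughly one in ten a residual fraction above 0.45 so that the >50 percent
#'   loss criterion is genuinely exercised.
#' @param ndvi_baseline_mean,ndvi_baseline_sd Mean and spatial standard
#'   deviation of the vegetated-land baseline NDVI field.
#' @param field_range_px Correlation length (pixels) of the smooth Gaussian
#'   random fields used for covariates and attribute layers.
#' @param composite_percentiles Named percentiles used for the annual
#'   composites of each index (NDVI and TCG default to 90, AWEI to 50).
#' @param seed Integer seed; identical config + seed gives identical scenes.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(grid_rows = 256,
                       grid_cols = 256,
                       pixel_size = 30,
                       years = 2000:2020,
                       n_lakes = 80,
                       area_log10_range = c(0, 2.6),
                       area_pareto_exponent = 1.8,
                       drain_prob_coefs = c(intercept = -2.7,
                                            air_temp_mean = 2.9,
                                            elevation = -1.9),
                       class_mix = c(very_likely = 0.25,
                                     likely = 0.35,
                                     unlikely = 0.40),
                       recovery_params = list(
                         very_likely = c(N0 = 0.05, delta_inf = 0.06, tau = 1.0),
                         likely      = c(N0 = 0.05, delta_inf = 0.00, tau = 2.0),
                         unlikely    = c(N0 = 0.05, delta_inf = -0.09, tau = 2.0)),
                       obs_per_year = 8,
                       obs_noise_sd = 0.02,
                       cloud_dropout_prob = 0.3,
                       spike_prob = 0.05,
                       product_error = list(
                         jrc_like  = c(omission = 0.05, commission = 0.02),
                         glad_like = c(omission = 0.05, commission = 0.02)),
                       drain_year_range = NULL,
                       residual_mix = data.frame(
                         weight = c(0.7, 0.2, 0.1),
                         lo = c(0.00, 0.25, 0.45),
                         hi = c(0.25, 0.45, 0.70)),
                       ndvi_baseline_mean = 0.45,
                       ndvi_baseline_sd = 0.03,
                       field_range_px = 40,
                       composite_percentiles = c(ndvi = 90, tcg = 90, awei = 50),
                       seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              pixel_size = pixel_size,
              years = as.integer(years),
              n_lakes = as.integer(n_lakes),
              area_log10_range = area_log10_range,
              area_pareto_exponent = area_pareto_exponent,
              drain_prob_coefs = drain_prob_coefs,
              class_mix = class_mix,
              recovery_params = recovery_params,
              obs_per_year = as.integer(obs_per_year),
              obs_noise_sd = obs_noise_sd,
              cloud_dropout_prob = cloud_dropout_prob,
              spike_prob = spike_prob,
              product_error = product_error,
              drain_year_range = drain_year_range,
              residual_mix = residual_mix,
              ndvi_baseline_mean = ndvi_baseline_mean,
              ndvi_baseline_sd = ndvi_baseline_sd,
              field_range_px = field_range_px,
              composite_percentiles = composite_percentiles,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x A `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  with(x, {
    if (grid_rows < 8 || grid_cols < 8) stop("grid must be at least 8x8")
    if (pixel_size <= 0) stop("pixel_size must be positive")
    if (length(years) < 3 || any(diff(years) != 1L))
      stop("years must be an inclusive run of at least 3 calendar years")
    if (n_lakes < 1) stop("n_lakes must be >= 1")
    probs <- c(cloud_dropout_prob, spike_prob,
               unlist(product_error, use.names = FALSE))
    if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
    if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
    if (any(class_mix < 0)) stop("class_mix proportions must be non-negative")
    for (nm in names(recovery_params)) {
      p <- recovery_params[[nm]]
      if (!all(c("N0", "delta_inf", "tau") %in% names(p)))
        stop("recovery_params entries need N0, delta_inf, tau")
      if (p[["tau"]] <= 0) stop("recovery tau must be positive")
    }
    if (obs_per_year < 1) stop("obs_per_year must be >= 1")
    if (obs_noise_sd < 0) stop("obs_noise_sd must be non-negative")
    if (!is.null(drain_year_range)) {
      if (drain_year_range[1] < min(years) || drain_year_range[2] > max(years))
        stop("drain_year_range must lie within the year span")
    }
  })
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %dx%d px @ %gm, years %d-%d, %d lakes, seed %d\n",
              x$grid_rows, x$grid_cols, x$pixel_size,
              min(x$years), max(x$years), x$n_lakes, x$seed))
  invisible(x)
}

# Default drainage-year range: trim two years from each end of the span so
# the temporal segmentation always has pre- and post-drainage anchor years.
default_drain_year_range <- function(cfg) {
  if (!is.null(cfg$drain_year_range)) return(as.integer(cfg$drain_year_range))
  ys <- cfg$years
  c(ys[3], ys[length(ys) - 2L])
}
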