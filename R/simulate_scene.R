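#' Post-drainage NDVI recovery curve
#'
#' Exponential approach of basin greenness toward an asymptote offset from
#' the surrounding vegetation:
#' `surround + delta_inf - (surround + delta_inf - N0) * exp(-t / tau)`.
#' With the shipped defaults, very-likely thermokarst basins overshoot their
#' surroundings by +0.06 NDVI and cross the surround level about two years
#' after drainage, while unlikely (non-thermokarst) basins settle 0.09 below
#' and stay below through year 15.
#'
#' @param t_since_drainage Years since drainage (>= 0), vectorized.
#' @param params Named vector `c(N0, delta_inf, tau)`: NDVI at drainage,
#'   asymptotic offset from the surround, and e-folding time in years
#'   (`tau > 0`).
#' @param surround_ndvi Surrounding-vegetation NDVI (scalar or vectorized).
#' @return NDVI values; equals `N0` at `t = 0` and tends monotonically to
#'   `surround_ndvi + delta_inf`.
#' @export
ndvi_recovery <- function(t_since_drainage, params, surround_ndvi) {
  stopifnot(params[["tau"]] > 0)
  asym <- surround_ndvi + params[["delta_inf"]]
  asym - (asym - params[["N0"]]) * exp(-t_since_drainage / params[["tau"]])
}

#' Degrade a truth loss mask into product-like loss masks
#'
#' Emulates the differing omission/commission profiles of the two
#' surface-water transition products: every true loss pixel is dropped
#' independently with the product's omission probability and every non-loss
#' land pixel is switched on with its commission probability; the two
#' products are degraded independently. Uses the current RNG state.
#'
#' @param truth_loss Logical matrix of true water-loss pixels.
#' @param product_error List with `jrc_like` and `glad_like`, each
#'   `c(omission, commission)` in `[0, 1]`.
#' @param water_mask Optional logical matrix of persistent water; commission
#'   noise is only drawn on land (non-loss, non-water) pixels.
#' @return List of logical matrices `jrc_like` and `glad_like`.
#' @export
degrade_products <- function(truth_loss, product_error, water_mask = NULL) {
  stopifnot(all(unlist(product_error) >= 0), all(unlist(product_error) <= 1))
  land <- !truth_loss
  if (!is.null(water_mask)) land <- land & !water_mask
  loss_idx <- which(truth_loss)
  land_idx <- which(land)
  degrade_one <- function(err) {
    m <- matrix(FALSE, nrow(truth_loss), ncol(truth_loss))
    if (length(loss_idx))
      m[loss_idx] <- runif(length(loss_idx)) >= err[["omission"]]
    if (length(land_idx) && err[["commission"]] > 0)
      m[land_idx] <- m[land_idx] | (runif(length(land_idx)) < err[["commission"]])
    m
  }
  list(jrc_like = degrade_one(product_error$jrc_like),
       glad_like = degrade_one(product_error$glad_like))
}

# Truncated-Pareto lake areas (ha). density ~ A^-alpha on [10^l1, 10^l2].
sample_lake_areas <- function(n, log10_range, alpha) {
  b <- alpha - 1
  amin <- 10^log10_range[1]; amax <- 10^log10_range[2]
  u <- runif(n)
  (amin^-b - u * (amin^-b - amax^-b))^(-1 / b)
}

# Rasterize one jittered axis-aligned ellipse inside a padded bounding box,
# then clean it with the same morphological opening the detection stage uses,
# so generated footprints are opening-invariant.
rasterize_lake <- function(r0, c0, ar, ac, nr, nc, jitter = 0.15) {
  rr <- max(1L, floor(r0 - ar - 2)):min(nr, ceiling(r0 + ar + 2))
  cc <- max(1L, floor(c0 - ac - 2)):min(nc, ceiling(c0 + ac + 2))
  q <- outer(((rr - r0) / ar)^2, ((cc - c0) / ac)^2, "+")
  inc <- q <= (1 + jitter * matrix(runif(length(q), -1, 1), nrow(q)))^1
  inc <- clean_mask(inc)
  if (!any(inc)) return(NULL)
  sub_idx <- which(inc)
  srow <- ((sub_idx - 1L) %% nrow(inc)) + 1L
  scol <- ((sub_idx - 1L) %/% nrow(inc)) + 1L
  cbind(rr[srow], cc[scol])
}

# Spectral model: vegetated-land bands as a function of target NDVI, and a
# fixed open-water spectrum. AWEI is negative over land and positive over
# water by construction.
land_bands_from_ndvi <- function(N) {
  nir <- matrix(0.30, nrow(N), ncol(N))
  list(blue = matrix(0.04, nrow(N), ncol(N)),
       green = 0.06 + 0.04 * N,
       red = nir * (1 - N) / (1 + N),
       nir = nir,
       swir1 = 0.22 - 0.12 * N,
       swir2 = 0.14 - 0.08 * N)
}

water_spectrum <- c(blue = 0.06, green = 0.09, red = 0.05,
                    nir = 0.02, swir1 = 0.01, swir2 = 0.005)

#' Simulate a synthetic Arctic lake scene
#'
#' Generates a seeded scene with known lakes, drainage events, product noise
#' and vegetation-recovery dynamics: lakes are jittered axis-aligned ellipses
#' (cleaned with the same morphological opening the detection stage applies,
#' and placed with a minimum 2-pixel gap), the drained subset is chosen by a
#' logistic model on lake covariates, drained footprints switch from
#' open-water to recovering-vegetation spectra at the true drainage year, and
#' annual multi-observation reflectance with QA dropouts is composited into
#' the annual index rasters the downstream stages consume.
#'
#' @param config A [sim_config()].
#' @param keep_observations Keep the raw per-year [observation_stack()] lists
#'   in the bundle (memory-heavy; intended for small test grids).
#' @return A `scene_bundle`: list with the truth table (`truth`), footprint
#'   and drained-pixel index lists, attribute rasters, the permanent-water
#'   extent, true and degraded loss masks, annual NDVI/TCG/AWEI composites,
#'   annual water masks, and the per-lake-year covariate table.
#' @export
simulate_scene <- function(config = sim_config(), keep_observations = FALSE) {
  config <- validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  ps <- config$pixel_size; years <- config$years
  rng_px <- config$field_range_px

  ## --- covariate and attribute fields ---------------------------------
  lat <- matrix(rep((seq_len(nr) - 1) / (nr - 1), nc), nr, nc)  # 0 north .. 1 south
  elevation <- pmax(100 + 70 * gaussian_field(nr, nc, rng_px) +
                      80 * (matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr),
                                   nr, nc) - 0.5), 0)
  air_temp_mean <- -2 - 0.012 * elevation - 6 * lat +
    1.0 * gaussian_field(nr, nc, rng_px)
  air_temp_trend <- pmax(0.04 + 0.02 * gaussian_field(nr, nc, rng_px), 0)
  precip_norm <- pmax(300 + 60 * gaussian_field(nr, nc, rng_px), 50)
  active_layer <- pmax(0.6 + 0.25 * gaussian_field(nr, nc, rng_px) -
                         0.2 * lat, 0.2)
  ndvi_base <- pmin(pmax(config$ndvi_baseline_mean +
                           config$ndvi_baseline_sd *
                           gaussian_field(nr, nc, rng_px), 0.2), 0.7)

  tk_levels <- c("very_likely", "likely", "unlikely")
  pf_levels <- c("continuous", "discontinuous", "sporadic", "isolated")
  gi_levels <- c("high", "medium", "low")
  thermokarst <- matrix(tk_levels[classify_field(
    gaussian_field(nr, nc, rng_px), config$class_mix)], nr, nc)
  pf_val <- lat + 0.10 * gaussian_field(nr, nc, rng_px)
  permafrost <- matrix(pf_levels[findInterval(pf_val, c(0.4, 0.65, 0.85)) + 1L],
                       nr, nc)
  ground_ice <- matrix(gi_levels[classify_field(
    gaussian_field(nr, nc, rng_px), c(0.3, 0.4, 0.3))], nr, nc)
  gy <- gaussian_field(nr, nc, rng_px)
  yedoma <- gy > quantile(gy, 0.85)
  gfld <- gaussian_field(nr, nc, rng_px)
  floodplain <- gfld > quantile(gfld, 0.90)
  zone <- matrix(1L, nr, nc)
  zone[seq_len(nr) > nr / 2, ] <- zone[seq_len(nr) > nr / 2, ] + 2L
  zone[, seq_len(nc) > nc / 2] <- zone[, seq_len(nc) > nc / 2] + 1L
  attributes <- list(thermokarst = thermokarst, permafrost = permafrost,
                     ground_ice = ground_ice,
                     yedoma = matrix(ifelse(yedoma, "yedoma", "non_yedoma"), nr, nc),
                     floodplain = matrix(ifelse(floodplain, "floodplain",
                                                "non_floodplain"), nr, nc),
                     zone = zone)

  ## --- lake placement --------------------------------------------------
  areas <- sample_lake_areas(config$n_lakes, config$area_log10_range,
                             config$area_pareto_exponent)
  occupied <- matrix(FALSE, nr, nc)     # footprints dilated by the 2-px gap
  footprints <- vector("list", config$n_lakes)
  shape <- vector("list", config$n_lakes)
  placed <- logical(config$n_lakes)
  gap_kern <- EBImage::makeBrush(5, shape = "box")
  for (i in order(areas, decreasing = TRUE)) {   # big lakes first
    px_target <- areas[i] * 1e4 / ps^2
    base <- sqrt(px_target / pi)
    # cap the aspect ratio so the semi-minor axis survives the double
    # erosion of the opening (no sub-1-ha object survives it in any case)
    aspect <- min(runif(1, 1, 2.2), max(1, (base / 2.6)^2))
    if (runif(1) < 0.5) { ar <- base * sqrt(aspect); ac <- base / sqrt(aspect)
    } else { ar <- base / sqrt(aspect); ac <- base * sqrt(aspect) }
    ar <- max(ar, 2.6); ac <- max(ac, 2.6)
    margin <- ceiling(max(ar, ac)) + 3
    if (2 * margin + 2 >= min(nr, nc)) next
    for (attempt in 1:40) {
      r0 <- runif(1, margin, nr - margin)
      c0 <- runif(1, margin, nc - margin)
      pix <- rasterize_lake(r0, c0, ar, ac, nr, nc)
      if (is.null(pix) || nrow(pix) < 4) next
      idx <- pix[, 1] + (pix[, 2] - 1L) * nr
      if (any(occupied[idx])) next
      footprints[[i]] <- idx
      shape[[i]] <- c(r0 = r0, c0 = c0, ar = ar, ac = ac)
      placed[i] <- TRUE
      rr <- range(pix[, 1]); cc <- range(pix[, 2])
      rpad <- max(1, rr[1] - 2):min(nr, rr[2] + 2)
      cpad <- max(1, cc[1] - 2):min(nc, cc[2] + 2)
      sub <- matrix(0, length(rpad), length(cpad))
      sub[cbind(match(pix[, 1], rpad), match(pix[, 2], cpad))] <- 1
      sub <- EBImage::dilate(sub, gap_kern)
      occupied[rpad, cpad] <- occupied[rpad, cpad] | (sub > 0)
      break
    }
  }
  n_failed <- sum(!placed)
  if (n_failed > 0)
    warning(sprintf("placed %d of %d lakes; grid too crowded for the rest",
                    sum(placed), config$n_lakes))
  keep <- which(placed)
  footprints <- footprints[keep]; shape <- shape[keep]
  n_lakes <- length(keep)
  if (n_lakes == 0) stop("no lakes could be placed on this grid")
  names(footprints) <- as.character(seq_len(n_lakes))

  ## --- truth table ------------------------------------------------------
  cnt <- lengths(footprints)
  rows <- lapply(footprints, function(ix) ((ix - 1L) %% nr) + 1L)
  cols <- lapply(footprints, function(ix) ((ix - 1L) %/% nr) + 1L)
  truth <- data.frame(
    lake_id = seq_len(n_lakes),
    pixel_count = as.integer(cnt),
    area_ha = cnt * ps^2 / 1e4,
    centroid_row = vapply(rows, mean, 1),
    centroid_col = vapply(cols, mean, 1),
    equivalent_diameter_m = 2 * sqrt(cnt * ps^2 / pi))
  truth <- assign_attributes(truth, footprints,
                             attributes[c("thermokarst", "permafrost",
                                          "ground_ice", "yedoma", "floodplain")])
  ci <- cbind(round(truth$centroid_row), round(truth$centroid_col))
  truth$elevation <- elevation[ci]
  truth$air_temp_mean <- air_temp_mean[ci]
  truth$air_temp_trend <- air_temp_trend[ci]
  truth$active_layer <- active_layer[ci]
  truth$precip_norm <- precip_norm[ci]

  ## --- drainage assignment ---------------------------------------------
  co <- config$drain_prob_coefs
  zsc <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  lin <- rep(if ("intercept" %in% names(co)) co[["intercept"]] else 0, n_lakes)
  for (nm in setdiff(names(co), "intercept")) {
    if (!nm %in% names(truth)) stop("unknown drainage covariate: ", nm)
    lin <- lin + co[[nm]] * zsc(truth[[nm]])
  }
  truth$drain_prob <- plogis(lin)
  truth$drained <- runif(n_lakes) < truth$drain_prob
  dyr <- default_drain_year_range(config)
  truth$true_drainage_year <- NA_integer_
  truth$true_drainage_year[truth$drained] <-
    sample(seq(dyr[1], dyr[2]), sum(truth$drained), replace = TRUE)

  ## remnant ponds and drained pixel sets
  rm_mix <- config$residual_mix
  drained_pixels <- setNames(vector("list", n_lakes), names(footprints))
  truth$residual_fraction <- 0
  for (i in which(truth$drained)) {
    comp <- sample(nrow(rm_mix), 1, prob = rm_mix$weight)
    res_target <- runif(1, rm_mix$lo[comp], rm_mix$hi[comp])
    fp <- footprints[[i]]
    pond <- integer(0)
    if (res_target > 0) {
      s <- shape[[i]]; scl <- sqrt(res_target)
      pr <- ((rows[[i]] - s[["r0"]]) / (s[["ar"]] * scl))^2 +
        ((cols[[i]] - s[["c0"]]) / (s[["ac"]] * scl))^2
      pond <- fp[pr <= 1]
    }
    drained_pixels[[i]] <- setdiff(fp, pond)
    truth$residual_fraction[i] <- length(pond) / length(fp)
  }
  truth$loss_fraction_true <- ifelse(truth$drained,
                                     1 - truth$residual_fraction, 0)
  truth$event_truth <- truth$drained & truth$area_ha > 1 &
    truth$loss_fraction_true > 0.5
  rp <- config$recovery_params
  truth$recovery_N0 <- vapply(truth$thermokarst, function(k) rp[[k]][["N0"]], 1)
  truth$recovery_delta_inf <- vapply(truth$thermokarst,
                                     function(k) rp[[k]][["delta_inf"]], 1)
  truth$recovery_tau <- vapply(truth$thermokarst, function(k) rp[[k]][["tau"]], 1)

  ## --- products ---------------------------------------------------------
  permanent_water <- matrix(FALSE, nr, nc)
  permanent_water[unlist(footprints)] <- TRUE
  truth_loss <- matrix(FALSE, nr, nc)
  truth_loss[unlist(drained_pixels)] <- TRUE
  final_water <- permanent_water & !truth_loss
  loss_masks <- degrade_products(truth_loss, config$product_error,
                                 water_mask = final_water)

  ## --- per-lake-year covariate table -------------------------------------
  anom <- rnorm(length(years), 0, 0.6)
  covariates <- do.call(rbind, lapply(seq_along(years), function(j) {
    y <- years[j]
    data.frame(
      lake_id = truth$lake_id, year = y,
      air_temp_annual = truth$air_temp_mean +
        truth$air_temp_trend * (y - years[1]) + anom[j] +
        rnorm(n_lakes, 0, 0.3),
      air_temp_summer = NA_real_,
      precip_annual = truth$precip_norm * (1 + 0.10 * rnorm(n_lakes)),
      snowfall_annual = 0.4 * truth$precip_norm * (1 + 0.10 * rnorm(n_lakes)))
  }))
  covariates$air_temp_summer <- covariates$air_temp_annual + 12 +
    rnorm(nrow(covariates), 0, 0.3)
  covariates <- covariates[order(covariates$lake_id, covariates$year), ]
  rownames(covariates) <- NULL

  ## --- annual observations and composites --------------------------------
  cp <- config$composite_percentiles
  composites <- list(ndvi = list(), tcg = list(), awei = list())
  valid_count <- list(); water_masks <- list()
  observations <- if (keep_observations) list() else NULL
  water_idx_all <- which(permanent_water)
  for (y in years) {
    N_tar <- ndvi_base
    drained_now <- matrix(FALSE, nr, nc)
    for (i in which(truth$drained & truth$true_drainage_year <= y)) {
      dp <- drained_pixels[[i]]
      t_s <- y - truth$true_drainage_year[i]
      N_tar[dp] <- ndvi_recovery(t_s, rp[[truth$thermokarst[i]]], ndvi_base[dp])
      drained_now[dp] <- TRUE
    }
    water_now_idx <- water_idx_all[!drained_now[water_idx_all]]
    clean <- land_bands_from_ndvi(N_tar)
    for (b in names(clean)) clean[[b]][water_now_idx] <- water_spectrum[[b]]
    spike_px <- if (config$spike_prob > 0)
      which(runif(nr * nc) < config$spike_prob) else integer(0)
    spike_obs <- if (length(spike_px))
      sample.int(config$obs_per_year, length(spike_px), replace = TRUE) else integer(0)
    obs <- vector("list", config$obs_per_year)
    for (o in seq_len(config$obs_per_year)) {
      bands <- lapply(clean, function(m) {
        if (config$obs_noise_sd > 0)
          m <- m + matrix(rnorm(nr * nc, 0, config$obs_noise_sd), nr, nc)
        sp <- spike_px[spike_obs == o]
        if (length(sp)) m[sp] <- m[sp] + 0.3
        pmin(pmax(m, 0), 1)
      })
      qa <- if (config$cloud_dropout_prob > 0)
        matrix(runif(nr * nc) >= config$cloud_dropout_prob, nr, nc)
      else matrix(TRUE, nr, nc)
      obs[[o]] <- observation_stack(bands, qa, y)
    }
    yk <- as.character(y)
    cn <- composite_observations(obs, "ndvi", cp[["ndvi"]])
    ca <- composite_observations(obs, "awei", cp[["awei"]])
    ct <- composite_observations(obs, "tcg", cp[["tcg"]])
    composites$ndvi[[yk]] <- cn$values
    composites$tcg[[yk]] <- ct$values
    composites$awei[[yk]] <- ca$values
    valid_count[[yk]] <- cn$valid_count
    wm <- water_mask_from_awei(ca$values, 0)
    wm[is.na(wm)] <- FALSE
    water_masks[[yk]] <- wm
    if (keep_observations) observations[[yk]] <- obs
  }

  structure(list(config = config, years = years, truth = truth,
                 footprints = footprints, drained_pixels = drained_pixels,
                 attributes = attributes,
                 permanent_water = permanent_water, truth_loss = truth_loss,
                 loss_masks = loss_masks, composites = composites,
                 valid_count = valid_count, water_masks = water_masks,
                 covariates = covariates,
                 fields = list(elevation = elevation,
                               air_temp_mean = air_temp_mean,
                               ndvi_base = ndvi_base),
                 placement_failures = n_failed,
                 observations = observations),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf(paste0("<scene_bundle> %dx%d px, years %d-%d, %d lakes ",
                     "(%d drained, %d truth events)\n"),
              x$config$grid_rows, x$config$grid_cols,
              min(x$years), max(x$years), nrow(x$truth),
              sum(x$truth$drained), sum(x$truth$event_truth)))
  invisible(x)
}

#' Simulate a lake population without rasterizing scenes
#'
#' Draws lake-level attributes, climate covariates and drainage outcomes from
#' the same structural model as [simulate_scene()], without placing lakes on
#' a pixel grid. Intended for driver-attribution experiments, which need
#' thousands of lakes -- far more than a desk-scale raster scene can hold.
#'
#' @param n_lakes Number of lakes.
#' @param config A [sim_config()]; supplies the drainage coefficients, class
#'   mix, year span, drainage-year range and area spectrum.
#' @param seed Integer seed (defaults to the config seed).
#' @return List with `lakes` (one row per lake: attributes, static
#'   covariates, `drain_prob`, `drained`, `true_drainage_year`) and
#'   `covariates` (per lake-year climate table).
#' @export
simulate_lake_population <- function(n_lakes, config = sim_config(),
                                     seed = config$seed) {
  config <- validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  years <- config$years
  lat <- runif(n_lakes)
  elevation <- rgamma(n_lakes, shape = 2, scale = 60)
  air_temp_mean <- -2 - 0.012 * elevation - 6 * lat + rnorm(n_lakes)
  air_temp_trend <- pmax(0, 0.04 + 0.02 * rnorm(n_lakes))
  active_layer <- pmax(0.2, 0.8 - 0.4 * lat + 0.15 * rnorm(n_lakes))
  precip_norm <- pmax(50, 300 + 60 * rnorm(n_lakes))
  tk_levels <- c("very_likely", "likely", "unlikely")
  lakes <- data.frame(
    lake_id = seq_len(n_lakes),
    area_ha = sample_lake_areas(n_lakes, config$area_log10_range,
                                config$area_pareto_exponent),
    thermokarst = sample(tk_levels, n_lakes, replace = TRUE,
                         prob = config$class_mix),
    permafrost = c("continuous", "discontinuous", "sporadic",
                   "isolated")[findInterval(lat + 0.1 * rnorm(n_lakes),
                                            c(0.4, 0.65, 0.85)) + 1L],
    ground_ice = sample(c("high", "medium", "low"), n_lakes, replace = TRUE,
                        prob = c(0.3, 0.4, 0.3)),
    floodplain = ifelse(runif(n_lakes) < 0.1, "floodplain", "non_floodplain"),
    elevation = elevation, air_temp_mean = air_temp_mean,
    air_temp_trend = air_temp_trend, active_layer = active_layer,
    precip_norm = precip_norm)
  co <- config$drain_prob_coefs
  zsc <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  lin <- rep(if ("intercept" %in% names(co)) co[["intercept"]] else 0, n_lakes)
  for (nm in setdiff(names(co), "intercept"))
    lin <- lin + co[[nm]] * zsc(lakes[[nm]])
  lakes$drain_prob <- plogis(lin)
  lakes$drained <- runif(n_lakes) < lakes$drain_prob
  dyr <- default_drain_year_range(config)
  lakes$true_drainage_year <- NA_integer_
  lakes$true_drainage_year[lakes$drained] <-
    sample(seq(dyr[1], dyr[2]), sum(lakes$drained), replace = TRUE)
  anom <- rnorm(length(years), 0, 0.6)
  covariates <- do.call(rbind, lapply(seq_along(years), function(j) {
    y <- years[j]
    data.frame(
      lake_id = lakes$lake_id, year = y,
      air_temp_annual = lakes$air_temp_mean +
        lakes$air_temp_trend * (y - years[1]) + anom[j] + rnorm(n_lakes, 0, 0.3),
      air_temp_summer = NA_real_,
      precip_annual = lakes$precip_norm * (1 + 0.10 * rnorm(n_lakes)),
      snowfall_annual = 0.4 * lakes$precip_norm * (1 + 0.10 * rnorm(n_lakes)))
  }))
  covariates$air_temp_summer <- covariates$air_temp_annual + 12 +
    rnorm(nrow(covariates), 0, 0.3)
  covariates <- covariates[order(covariates$lake_id, covariates$year), ]
  rownames(covariates) <- NULL
  list(lakes = lakes, covariates = covariates)
}
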