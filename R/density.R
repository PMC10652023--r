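#' Spatial density of drainage events by zone
#'
#' Counts events per zone (a lake belongs to the zone containing its
#' centroid) and divides by the zone area in square kilometres. Centroids
#' falling on a missing zone value are reported in an `"unassigned"` row.
#'
#' @param events Event table with `centroid_row`, `centroid_col`.
#' @param zone_raster Categorical matrix (integer or character; `NA` =
#'   nodata).
#' @param pixel_size Pixel edge length in meters.
#' @return Data frame: `zone`, `zone_area_km2`, `n_events`,
#'   `spatial_density` (events per km2).
#' @export
spatial_density <- function(events, zone_raster, pixel_size) {
  zones <- sort(unique(as.vector(zone_raster[!is.na(zone_raster)])))
  area_km2 <- vapply(zones, function(z)
    sum(zone_raster == z, na.rm = TRUE) * pixel_size^2 / 1e6, 1)
  zi <- zone_raster[cbind(round(events$centroid_row),
                          round(events$centroid_col))]
  counts <- vapply(zones, function(z) sum(!is.na(zi) & zi == z), 1L)
  out <- data.frame(zone = as.character(zones), zone_area_km2 = area_km2,
                    n_events = counts,
                    spatial_density = counts / area_km2)
  if (any(is.na(zi)))
    out <- rbind(out, data.frame(zone = "unassigned", zone_area_km2 = NA,
                                 n_events = sum(is.na(zi)),
                                 spatial_density = NA))
  rownames(out) <- NULL
  out
}

#' Lake-wise drainage density by stratum and size class
#'
#' The ratio of drained lakes to all lakes, per stratum and per size class
#' (plus an `"all"` size row). Only lakes above the area threshold enter the
#' denominators, matching the event definition. Strata with zero lakes give
#' `NA` (undefined), not zero.
#'
#' @param objects Lake table (needs `lake_id`, `area_ha`, the stratum
#'   column).
#' @param events Event table (needs `lake_id`).
#' @param stratum Stratum column name in `objects`, or `NULL` for a single
#'   overall stratum.
#' @param min_area_ha Area threshold for lakes counted (strict >, default 1).
#' @return Data frame: `stratum`, `size_class`, `n_lakes`, `n_drained`,
#'   `lakewise_density` (fraction in `[0, 1]`).
#' @export
lakewise_density <- function(objects, events, stratum = NULL,
                             min_area_ha = 1) {
  obj <- objects[objects$area_ha > min_area_ha, , drop = FALSE]
  obj$size_class <- as.character(size_class(obj$area_ha))
  obj$drained <- obj$lake_id %in% events$lake_id
  strata <- if (is.null(stratum)) rep("all", nrow(obj)) else
    as.character(obj[[stratum]])
  size_levels <- c("small", "medium", "large", "all")
  rows <- list()
  for (s in unique(strata)) {
    sub <- obj[strata == s, , drop = FALSE]
    for (sc in size_levels) {
      d <- if (sc == "all") sub else sub[sub$size_class == sc, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, size_class = sc, n_lakes = nrow(d),
        n_drained = sum(d$drained),
        lakewise_density = if (nrow(d) > 0) sum(d$drained) / nrow(d) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares trend of an annual series
#'
#' Least-squares slope with a two-tailed t-test on the slope, alongside the
#' Theil-Sen estimate. This mirrors the convention of reporting an OLS slope
#' and p-value for annual event counts while quoting Sen's slope for climate
#' series.
#'
#' @param years Numeric vector of years.
#' @param values Numeric vector, same length.
#' @return A `trend_result` list: `slope`, `intercept`, `p_value`,
#'   `sen_slope`.
#' @export
ols_trend <- function(years, values) {
  stopifnot(length(years) == length(values), length(years) >= 3)
  if (length(unique(years)) < 2) stop("years are constant; no trend defined")
  fit <- lm(values ~ years)
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) >= 2 && !is.nan(sm[2, 4])) sm[2, 4] else 0
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = unname(p),
                 sen_slope = theil_sen(years, values)),
            class = "trend_result")
}

#' Theil-Sen slope estimator
#'
#' Median over all pairwise slopes `(y_j - y_i) / (x_j - x_i)`, `i < j`;
#' pairs with duplicated `x` are skipped. Robust to isolated outliers.
#'
#' @param x,y Numeric vectors of equal length (>= 2 points).
#' @return The Sen slope.
#' @export
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  ij <- combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- (dy / dx)[dx != 0]
  if (length(s) == 0) stop("all x values are duplicated; no slope defined")
  median(s)
}

#' Annual event counts from dated events
#'
#' @param events Dated event table.
#' @param years Full year span (zero-filled where no events fall).
#' @return Data frame `year`, `n_events`.
#' @export
annual_event_counts <- function(events, years) {
  counts <- vapply(years, function(y)
    sum(!is.na(events$detected_year) & events$detected_year == y), 1L)
  data.frame(year = as.integer(years), n_events = counts)
}
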