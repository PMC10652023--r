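#' Median basin NDVI with water and negative-value masking
#'
#' Median of the composite over footprint pixels that are not currently
#' water and have non-negative values; standing water depresses NDVI, so
#' negative values are masked before the median. `NA` when no pixel survives.
#'
#' @param composite_values Composite raster (matrix).
#' @param footprint_idx Linear pixel indices of the basin.
#' @param water_mask Logical matrix for the same year (or `NULL`).
#' @param value_floor Mask values below this (default 0); `-Inf` disables.
#' @return Median value or `NA`.
#' @export
basin_median_ndvi <- function(composite_values, footprint_idx,
                              water_mask = NULL, value_floor = 0) {
  v <- composite_values[footprint_idx]
  keep <- !is.na(v) & v >= value_floor
  if (!is.null(water_mask)) keep <- keep & !water_mask[footprint_idx]
  if (!any(keep)) return(NA_real_)
  median(v[keep])
}

#' Surrounding-vegetation pixels of a lake
#'
#' Pixels within the disk of diameter `factor` times the lake's equivalent
#' diameter, centred at the lake centroid, excluding the lake's own
#' footprint, all other lake footprints, and (optionally) current water
#' pixels. Off-grid parts of the buffer are truncated.
#'
#' @param centroid_row,centroid_col Lake centroid (pixel coordinates).
#' @param equivalent_diameter_m Equal-area circle diameter in meters.
#' @param dims Grid dimensions `c(rows, cols)`.
#' @param pixel_size Pixel edge length in meters.
#' @param own_idx Linear indices of the lake's own footprint.
#' @param all_lakes_mask Logical matrix marking every lake footprint.
#' @param water_mask Optional logical matrix of current water.
#' @param factor Buffer diameter as a multiple of the lake diameter
#'   (default 2).
#' @return Integer vector of linear pixel indices (possibly empty).
#' @export
surround_pixels <- function(centroid_row, centroid_col, equivalent_diameter_m,
                            dims, pixel_size, own_idx = integer(0),
                            all_lakes_mask = NULL, water_mask = NULL,
                            factor = 2) {
  stopifnot(equivalent_diameter_m > 0)
  r_px <- factor * equivalent_diameter_m / 2 / pixel_size
  nr <- dims[1]; nc <- dims[2]
  rr <- max(1L, floor(centroid_row - r_px)):min(nr, ceiling(centroid_row + r_px))
  cc <- max(1L, floor(centroid_col - r_px)):min(nc, ceiling(centroid_col + r_px))
  if (length(rr) == 0 || length(cc) == 0) return(integer(0))
  d2 <- outer((rr - centroid_row)^2, (cc - centroid_col)^2, "+")
  sel <- which(d2 <= r_px^2)
  idx <- rr[((sel - 1L) %% length(rr)) + 1L] +
    (cc[((sel - 1L) %/% length(rr)) + 1L] - 1L) * nr
  idx <- setdiff(idx, own_idx)
  if (!is.null(all_lakes_mask)) idx <- idx[!all_lakes_mask[idx]]
  if (!is.null(water_mask)) idx <- idx[!water_mask[idx]]
  idx
}

#' Basin and surround greenness trajectory of one drained lake
#'
#' For every composite year, computes the median basin value (water and
#' negative values masked), the median over the surrounding buffer (same
#' masking; the buffer excludes all lake footprints), their difference
#' `delta`, and the alignment `years_since = year - drainage_year`.
#'
#' @param lake One-row data frame with `lake_id`, `centroid_row`,
#'   `centroid_col`, `equivalent_diameter_m`.
#' @param footprint_idx Linear indices of the basin (the full original lake
#'   footprint; remnant ponds are handled by the water mask).
#' @param composites Named list (by year) of index composite matrices.
#' @param water_masks Named list (by year) of logical water masks.
#' @param drainage_year Detected drainage year (integer); `NA` gives `NULL`.
#' @param all_lakes_mask Logical matrix of every lake footprint.
#' @param pixel_size Pixel edge length in meters.
#' @param factor Surround buffer factor, see [surround_pixels()].
#' @param surround_floor Apply the negative-value floor to the surround too
#'   (default `TRUE`).
#' @return A `trajectory` data frame: `lake_id`, `year`, `years_since`,
#'   `basin_median`, `surround_median`, `delta`, `basin_valid_px`,
#'   `surround_valid_px`; or `NULL` when `drainage_year` is missing.
#' @export
build_trajectory <- function(lake, footprint_idx, composites, water_masks,
                             drainage_year, all_lakes_mask, pixel_size,
                             factor = 2, surround_floor = TRUE) {
  if (is.na(drainage_year)) return(NULL)
  years <- as.integer(names(composites))
  dims <- dim(composites[[1]])
  out <- lapply(seq_along(years), function(j) {
    yk <- names(composites)[j]
    comp <- composites[[yk]]; wm <- water_masks[[yk]]
    b_keep <- !is.na(comp[footprint_idx]) & comp[footprint_idx] >= 0 &
      !wm[footprint_idx]
    basin <- if (any(b_keep)) median(comp[footprint_idx][b_keep]) else NA_real_
    sidx <- surround_pixels(lake$centroid_row, lake$centroid_col,
                            lake$equivalent_diameter_m, dims, pixel_size,
                            own_idx = footprint_idx,
                            all_lakes_mask = all_lakes_mask, water_mask = wm,
                            factor = factor)
    sv <- comp[sidx]
    s_keep <- !is.na(sv) & (if (surround_floor) sv >= 0 else TRUE)
    surround <- if (any(s_keep)) median(sv[s_keep]) else NA_real_
    data.frame(lake_id = lake$lake_id, year = years[j],
               years_since = years[j] - drainage_year,
               basin_median = basin, surround_median = surround,
               delta = basin - surround,
               basin_valid_px = sum(b_keep), surround_valid_px = sum(s_keep))
  })
  do.call(rbind, out)
}

#' Greenness trajectories for a table of dated events
#'
#' Runs [build_trajectory()] for every event with a resolved drainage year;
#' events with `detected_year = NA` are skipped with a message.
#'
#' @param events Dated event table (needs `detected_year`).
#' @param pixels Footprint index list.
#' @param composites,water_masks Named-by-year lists of matrices.
#' @param pixel_size Pixel edge length in meters.
#' @param factor Surround buffer factor.
#' @param quiet Suppress the skip message.
#' @return Long data frame of per-lake-year trajectory records.
#' @export
build_trajectories <- function(events, pixels, composites, water_masks,
                               pixel_size, factor = 2, quiet = FALSE) {
  all_lakes_mask <- matrix(FALSE, nrow(composites[[1]]), ncol(composites[[1]]))
  all_lakes_mask[unlist(pixels)] <- TRUE
  skipped <- sum(is.na(events$detected_year))
  if (skipped > 0 && !quiet)
    message(skipped, " event(s) without a resolved drainage year skipped")
  recs <- lapply(which(!is.na(events$detected_year)), function(e)
    build_trajectory(events[e, ], pixels[[as.character(events$lake_id[e])]],
                     composites, water_masks, events$detected_year[e],
                     all_lakes_mask, pixel_size, factor))
  if (length(recs) == 0) return(NULL)
  do.call(rbind, recs)
}

#' Stratified trajectory summaries and reference-year statistics
#'
#' Groups trajectory records by a stratum label and summarizes the
#' basin-minus-surround delta per years-since-drainage (median and
#' quartiles), plus a reference-year (default the tenth year after drainage)
#' summary of basin values and deltas.
#'
#' @param records Long trajectory table from [build_trajectories()], with a
#'   stratum column already joined.
#' @param stratum Name of the stratum column.
#' @param reference_year Years-since-drainage reference point (default 10).
#' @param years_since_range Post-drainage span summarized (default 0-15).
#' @return List with `trajectory` (stratum, years_since, n, median, q25,
#'   q75) and `reference` (stratum, n, median_delta, q25_delta, q75_delta,
#'   median_basin).
#' @export
group_trajectories <- function(records, stratum, reference_year = 10,
                               years_since_range = 0:15) {
  stopifnot(nrow(records) > 0, stratum %in% names(records))
  sub <- records[records$years_since %in% years_since_range &
                   !is.na(records$delta), ]
  qfun <- function(v) c(n = length(v), median = median(v),
                        q25 = unname(quantile(v, 0.25)),
                        q75 = unname(quantile(v, 0.75)))
  traj <- aggregate(sub$delta, by = list(stratum = sub[[stratum]],
                                         years_since = sub$years_since),
                    FUN = qfun)
  traj <- cbind(traj[c("stratum", "years_since")], as.data.frame(traj$x))
  ref <- records[records$years_since == reference_year & !is.na(records$delta), ]
  refs <- lapply(split(ref, ref[[stratum]]), function(d)
    data.frame(stratum = d[[stratum]][1], n = nrow(d),
               median_delta = median(d$delta),
               q25_delta = unname(quantile(d$delta, 0.25)),
               q75_delta = unname(quantile(d$delta, 0.75)),
               median_basin = median(d$basin_median, na.rm = TRUE)))
  list(trajectory = traj,
       reference = if (length(refs)) do.call(rbind, c(refs, make.row.names = FALSE))
       else NULL)
}
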