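#' Normalized Difference Vegetation Index
#'
#' `(nir - red) / (nir + red)`, the standard chlorophyll-sensitive greenness
#' proxy. Vectorized over rasters (matrices) or plain numerics. Pixels where
#' `nir + red` is zero are returned as `NA`.
#'
#' @param red,nir Reflectance in `[0, 1]` (scalar, vector or matrix).
#' @return NDVI values in `[-1, 1]` with the shape of the inputs.
#' @export
compute_ndvi <- function(red, nir) {
  s <- nir + red
  out <- (nir - red) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Automated Water Extraction Index (non-shadow variant)
#'
#' `4 (green - swir1) - (0.25 nir + 2.75 swir2)`. Positive values indicate
#' open water. The non-shadow variant is used throughout the package; the
#' published shadow variant can be selected where a mask function accepts a
#' `variant` argument.
#'
#' @param green,nir,swir1,swir2 Reflectance in `[0, 1]`.
#' @return AWEI values with the shape of the inputs.
#' @export
compute_awei <- function(green, nir, swir1, swir2) {
  4 * (green - swir1) - (0.25 * nir + 2.75 * swir2)
}

#' Tasseled Cap Greenness coefficient sets
#'
#' Published TM-era reflectance-factor coefficients (Crist 1985), applied
#' uniformly to all observations; the simulator emits harmonized reflectance
#' so a single coefficient set is appropriate.
#'
#' @param set Coefficient set name; only `"crist1985"` is shipped.
#' @return Named numeric vector over bands blue, green, red, nir, swir1, swir2.
#' @export
tcg_coefficients <- function(set = "crist1985") {
  switch(match.arg(set, "crist1985"),
         crist1985 = c(blue = -0.1603, green = -0.2819, red = -0.4934,
                       nir = 0.7940, swir1 = -0.0002, swir2 = -0.1446))
}

#' Tasseled Cap Greenness index
#'
#' Fixed linear combination of the six reflectance bands; higher for
#' vegetation, lower for water, and less sensitive to standing water than
#' NDVI.
#'
#' @param blue,green,red,nir,swir1,swir2 Reflectance in `[0, 1]`.
#' @param coefs Coefficient vector, see [tcg_coefficients()].
#' @return TCG values with the shape of the inputs.
#' @export
compute_tcg <- function(blue, green, red, nir, swir1, swir2,
                        coefs = tcg_coefficients()) {
  coefs[["blue"]] * blue + coefs[["green"]] * green + coefs[["red"]] * red +
    coefs[["nir"]] * nir + coefs[["swir1"]] * swir1 + coefs[["swir2"]] * swir2
}

#' Percentile composite of one pixel's valid observations
#'
#' Order statistic with linear interpolation between ranks (the convention of
#' `stats::quantile(type = 7)`), or the nearest-rank statistic with
#' `method = "nearest"`. `NA` observations are dropped; an empty set gives
#' `NA`.
#'
#' @param values Numeric vector of one pixel's observations.
#' @param p Percentile in `[0, 100]`.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A single composited value.
#' @export
percentile_composite <- function(values, p, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(p >= 0, p <= 100)
  v <- values[!is.na(values)]
  if (length(v) == 0) return(NA_real_)
  res <- cpp_row_percentile(matrix(v, nrow = 1), p, method == "linear")
  res$value[1]
}

#' Build an observation stack
#'
#' Bundles the six reflectance bands, the boolean QA raster and the calendar
#' year into the container consumed by [composite_observations()].
#'
#' @param bands Named list of six congruent matrices
#'   (`blue, green, red, nir, swir1, swir2`).
#' @param qa Logical matrix; `FALSE` excludes the pixel from all statistics.
#' @param year Calendar year.
#' @return An object of class `observation_stack`.
#' @export
observation_stack <- function(bands, qa, year) {
  need <- c("blue", "green", "red", "nir", "swir1", "swir2")
  stopifnot(all(need %in% names(bands)))
  d <- dim(bands[[1]])
  for (b in bands) stopifnot(identical(dim(b), d))
  stopifnot(identical(dim(qa), d))
  structure(list(bands = bands[need], qa = qa, year = as.integer(year)),
            class = "observation_stack")
}

index_from_stack <- function(stack, index) {
  b <- stack$bands
  switch(index,
         ndvi = compute_ndvi(b$red, b$nir),
         awei = compute_awei(b$green, b$nir, b$swir1, b$swir2),
         tcg  = compute_tcg(b$blue, b$green, b$red, b$nir, b$swir1, b$swir2),
         stop("unknown index: ", index))
}

#' Annual percentile composite of an index over observation stacks
#'
#' Computes the chosen multispectral index per observation, masks QA-false
#' pixels, and reduces across observations with a percentile composite.
#' Indices are computed before compositing so that each observation
#' contributes a physically consistent value.
#'
#' @param observations List of [observation_stack()] objects from one year.
#' @param index One of `"ndvi"`, `"tcg"`, `"awei"`.
#' @param p Percentile in `[0, 100]`.
#' @param method Interpolation method, see [percentile_composite()].
#' @return An `annual_composite`: list with `index_name`, `year`, `values`
#'   (matrix, `NA` where no valid observation exists) and `valid_count`.
#' @export
composite_observations <- function(observations, index = c("ndvi", "tcg", "awei"),
                                   p = 90, method = c("linear", "nearest")) {
  index <- match.arg(index)
  method <- match.arg(method)
  stopifnot(length(observations) >= 1)
  d <- dim(observations[[1]]$bands$red)
  year <- observations[[1]]$year
  obs <- vapply(observations, function(s) {
    v <- index_from_stack(s, index)
    v[!s$qa] <- NA_real_
    as.numeric(v)
  }, numeric(prod(d)))
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = length(observations))
  res <- cpp_row_percentile(obs, p, method == "linear")
  structure(list(index_name = index, year = year,
                 values = matrix(res$value, d[1], d[2]),
                 valid_count = matrix(res$n_valid, d[1], d[2])),
            class = "annual_composite")
}

#' Water mask from an AWEI raster
#'
#' A pixel is water iff `awei > threshold` (strict inequality). `NA` values
#' propagate as `NA`.
#'
#' @param awei AWEI raster (matrix) or vector.
#' @param threshold Finite decision threshold, default 0.
#' @return Logical mask with the shape of `awei`.
#' @export
water_mask_from_awei <- function(awei, threshold = 0) {
  stopifnot(is.finite(threshold))
  awei > threshold
}
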