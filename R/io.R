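#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows of values, north row
#' first). Values are printed with 17 significant digits, so a write/read
#' round trip reproduces doubles, nodata and the geotransform exactly.
#'
#' @param x Numeric or logical matrix (row 1 = northernmost row).
#' @param path File path (conventionally `.asc`).
#' @param xllcorner,yllcorner,cellsize Geotransform of the lower-left corner
#'   and the pixel size.
#' @param nodata Value written for `NA` cells.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   matrix with attributes `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
write_raster <- function(x, path, xllcorner = 0, yllcorner = 0,
                         cellsize = 30, nodata = -9999) {
  m <- x
  if (is.logical(m)) m <- m * 1L
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(xllcorner, digits = 17)),
           paste("yllcorner", format(yllcorner, digits = 17)),
           paste("cellsize", format(cellsize, digits = 17)),
           paste("NODATA_value", format(nodata, digits = 17)))
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  hv <- setNames(vapply(hdr, `[[`, "", 2), tolower(vapply(hdr, `[[`, "", 1)))
  nc <- as.integer(hv[["ncols"]]); nr <- as.integer(hv[["nrows"]])
  nodata <- as.numeric(hv[["nodata_value"]])
  vals <- scan(text = lines[-(1:6)], what = numeric(), quiet = TRUE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA
  attr(m, "xllcorner") <- as.numeric(hv[["xllcorner"]])
  attr(m, "yllcorner") <- as.numeric(hv[["yllcorner"]])
  attr(m, "cellsize") <- as.numeric(hv[["cellsize"]])
  attr(m, "nodata") <- nodata
  m
}

#' Check that two co-analyzed rasters are congruent
#'
#' @param a,b Matrices (as from [read_raster()]).
#' @param name_a,name_b Names used in the error message.
#' @return Invisibly `TRUE`; errors naming both rasters on mismatch.
#' @export
check_congruent <- function(a, b, name_a = "raster A", name_b = "raster B") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s (%s) and %s (%s) have different shapes", name_a,
                 paste(dim(a), collapse = "x"), name_b,
                 paste(dim(b), collapse = "x")))
  ga <- c(attr(a, "xllcorner"), attr(a, "yllcorner"), attr(a, "cellsize"))
  gb <- c(attr(b, "xllcorner"), attr(b, "yllcorner"), attr(b, "cellsize"))
  if (!is.null(ga) && !is.null(gb) && length(ga) == 3 && length(gb) == 3 &&
      any(ga != gb))
    stop(sprintf("%s and %s have different geotransforms", name_a, name_b))
  invisible(TRUE)
}

#' Read and write pipeline tables as CSV
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_table` returns `path` invisibly.
#' @export
write_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) read.csv(path)
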