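#' Morphological cleaning of a binary water mask
#'
#' Opening: erosion followed by dilation with a 1-pixel-radius (von Neumann
#' cross) structuring element, each applied `iterations` times. Separates
#' finely connected water bodies and removes isolated pixels; the output is
#' always a subset of the input (opening is anti-extensive) and re-applying
#' the operation leaves it unchanged (idempotent).
#'
#' @param water_mask Logical (or 0/1) matrix.
#' @param radius_px Structuring-element radius in pixels.
#' @param iterations Number of erode passes, then the same number of dilate
#'   passes.
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(water_mask, radius_px = 1, iterations = 2) {
  nr <- nrow(water_mask); nc <- ncol(water_mask)
  # pad with background so erosion also bites at the image border
  pad <- radius_px * iterations + 1L
  m <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- as.numeric(water_mask)
  kern <- EBImage::makeBrush(2L * radius_px + 1L, shape = "diamond")
  for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, kern)
  m[pad + seq_len(nr), pad + seq_len(nc)] > 0
}

# Union-find with path compression, used to merge diagonally adjacent
# 4-connected labels into 8-connected components.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label connected water objects
#'
#' Assigns every true pixel to exactly one maximal connected component and
#' summarizes each component as a lake object with pixel count, area,
#' centroid and equivalent (equal-area circle) diameter. 8-connectivity is
#' the default; 4-connectivity treats diagonal contact as separate objects.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @param pixel_size Pixel edge length in meters, for areas and diameters.
#' @return List with `labels` (integer matrix, 0 = background), `objects`
#'   (data frame: `lake_id`, `pixel_count`, `area_ha`, `centroid_row`,
#'   `centroid_col`, `equivalent_diameter_m`) and `pixels` (list of linear
#'   pixel indices per object, named by `lake_id`).
#' @export
label_objects <- function(mask, connectivity = 8, pixel_size = 30) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(as.numeric(mask), nr, nc)
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nr, nc)
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1) {
    parent <- seq_len(nlab)
    # diagonal neighbour pairs: down-right and down-left shifts
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        a <- uf_find(parent, pairs[k, 1]); b <- uf_find(parent, pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(nlab), function(i) uf_find(parent, i), 1L)
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(list(labels = lab,
                objects = data.frame(lake_id = integer(), pixel_count = integer(),
                                     area_ha = numeric(), centroid_row = numeric(),
                                     centroid_col = numeric(),
                                     equivalent_diameter_m = numeric()),
                pixels = list()))
  }
  # relabel consecutively, ordered by first (row-major) pixel appearance
  first_seen <- tapply(idx, lab[idx], min)
  old_ids <- as.integer(names(sort(first_seen)))
  remap <- integer(max(old_ids)); remap[old_ids] <- seq_along(old_ids)
  lab[idx] <- remap[lab[idx]]
  pixels <- split(idx, lab[idx])
  names(pixels) <- as.character(seq_along(pixels))
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  ids <- lab[idx]
  cnt <- as.integer(tabulate(ids))
  area_m2 <- cnt * pixel_size^2
  objects <- data.frame(
    lake_id = seq_along(cnt),
    pixel_count = cnt,
    area_ha = area_m2 / 1e4,
    centroid_row = as.numeric(tapply(rows, ids, mean)),
    centroid_col = as.numeric(tapply(cols, ids, mean)),
    equivalent_diameter_m = 2 * sqrt(area_m2 / pi))
  list(labels = lab, objects = objects, pixels = pixels)
}

#' Assign categorical attributes to lake objects
#'
#' Each lake gets, per attribute raster, the majority label over its
#' footprint; ties are broken by the label of the footprint pixel nearest the
#' centroid.
#'
#' @param objects,pixels From [label_objects()].
#' @param attribute_rasters Named list of congruent matrices (integer codes or
#'   character labels).
#' @return `objects` with one added column per attribute.
#' @export
assign_attributes <- function(objects, pixels, attribute_rasters) {
  nr <- NULL
  for (nm in names(attribute_rasters)) {
    ras <- attribute_rasters[[nm]]
    if (is.null(nr)) nr <- nrow(ras)
    objects[[nm]] <- vapply(seq_len(nrow(objects)), function(i) {
      idx <- pixels[[as.character(objects$lake_id[i])]]
      vals <- ras[idx]
      tab <- sort(table(vals), decreasing = TRUE)
      top <- names(tab)[tab == tab[1]]
      if (length(top) == 1) return(top)
      rows <- ((idx - 1L) %% nr) + 1L
      cols <- ((idx - 1L) %/% nr) + 1L
      d2 <- (rows - objects$centroid_row[i])^2 + (cols - objects$centroid_col[i])^2
      ord <- order(d2)
      as.character(vals[ord][match(TRUE, as.character(vals[ord]) %in% top)])
    }, character(1))
  }
  objects
}

#' Union of the two products' water-loss masks
#'
#' Pixelwise OR of the JRC-like and GLAD-like loss masks; combining the
#' products raises the detection rate because their omission errors differ.
#'
#' @param jrc_loss,glad_loss Congruent logical matrices.
#' @return Logical matrix.
#' @export
union_loss <- function(jrc_loss, glad_loss) {
  if (!identical(dim(jrc_loss), dim(glad_loss)))
    stop(sprintf("loss mask shapes differ: %s vs %s",
                 paste(dim(jrc_loss), collapse = "x"),
                 paste(dim(glad_loss), collapse = "x")))
  a <- jrc_loss; a[is.na(a)] <- FALSE
  b <- glad_loss; b[is.na(b)] <- FALSE
  a | b
}

#' Fraction of a lake footprint covered by the loss mask
#'
#' @param footprint_idx Linear pixel indices of the lake footprint.
#' @param loss_mask Logical matrix.
#' @return Fraction in `[0, 1]`.
#' @export
drainage_fraction <- function(footprint_idx, loss_mask) {
  if (length(footprint_idx) == 0) stop("empty lake footprint")
  mean(loss_mask[footprint_idx], na.rm = TRUE)
}

#' Size class of a lake by initial area
#'
#' Small `[1, 10)` ha, medium `[10, 100)` ha, large `>= 100` ha (half-open at
#' the joints).
#'
#' @param area_ha Numeric vector of areas in hectares.
#' @return Factor with levels small, medium, large.
#' @export
size_class <- function(area_ha) {
  cut(area_ha, breaks = c(-Inf, 10, 100, Inf), right = FALSE,
      labels = c("small", "medium", "large"))
}

#' Detect lake drainage events
#'
#' A lake qualifies as a drainage event iff its initial area strictly exceeds
#' `min_area_ha` and the fraction of its footprint covered by the fused loss
#' mask strictly exceeds `min_fraction`.
#'
#' @param objects,pixels From [label_objects()] (attributes optional).
#' @param loss_mask Fused loss mask, see [union_loss()].
#' @param min_area_ha Initial-area threshold in hectares (strict >).
#' @param min_fraction Loss-fraction threshold (strict >).
#' @return Data frame of events: the qualifying `objects` rows plus
#'   `loss_fraction`, `size_class` and `detected_year` (`NA` until filled by
#'   [date_events()]).
#' @export
detect_drainage_events <- function(objects, pixels, loss_mask,
                                   min_area_ha = 1, min_fraction = 0.5) {
  if (nrow(objects) == 0) {
    ev <- objects
    ev$loss_fraction <- numeric(0); ev$size_class <- character(0)
    ev$detected_year <- integer(0)
    return(ev)
  }
  frac <- vapply(objects$lake_id, function(id)
    drainage_fraction(pixels[[as.character(id)]], loss_mask), numeric(1))
  keep <- objects$area_ha > min_area_ha & frac > min_fraction
  ev <- objects[keep, , drop = FALSE]
  ev$loss_fraction <- frac[keep]
  ev$size_class <- as.character(size_class(ev$area_ha))
  ev$detected_year <- rep(NA_integer_, nrow(ev))
  rownames(ev) <- NULL
  ev
}
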