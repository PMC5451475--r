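#' Build the ETDRS measurement grid
#'
#' Constructs pixel masks for the 1 mm central circle, the 1-3 mm
#' parafoveal annulus and the full 3 mm circle of the ETDRS grid. A pixel
#' belongs to a zone iff its centre lies within the defining circle(s);
#' the annulus is the outer disk minus the inner disk, so the zones are
#' disjoint by construction. The grid centre defaults to the image centre;
#' in the full pipeline it is placed at the FAZ centroid (the fovea proxy).
#'
#' @param geometry A [scan_geometry()].
#' @param center Optional `c(row, col)` pixel (1-based) for the grid centre.
#' @param inner_diameter_mm,outer_diameter_mm Zone diameters (default 1, 3).
#' @return A list of class `etdrs_grid` with logical masks `central`,
#'   `parafoveal`, `total`, the `center` pixel and zone areas in mm^2.
#' @section Errors: `octa_grid_outside` if the outer circle extends beyond
#'   the image by more than half a pixel.
#' @export
build_etdrs_grid <- function(geometry, center = NULL, inner_diameter_mm = 1,
                             outer_diameter_mm = 3) {
  stopifnot(inherits(geometry, "scan_geometry"),
            outer_diameter_mm > inner_diameter_mm, inner_diameter_mm > 0)
  nr <- geometry$height_px; nc <- geometry$width_px
  if (is.null(center)) center <- c(nr %/% 2L + 1L, nc %/% 2L + 1L)
  center <- as.integer(round(center))
  stopifnot(length(center) == 2L)
  ps <- pixel_scale(geometry)
  cy <- (center[1] - 0.5) * ps$y
  cx <- (center[2] - 0.5) * ps$x
  r_in <- inner_diameter_mm / 2
  r_out <- outer_diameter_mm / 2
  # allow at most half a pixel of overhang: an exactly inscribed grid on an
  # even pixel count has no pixel whose centre is the continuous centre
  tol_x <- ps$x / 2 + 1e-12
  tol_y <- ps$y / 2 + 1e-12
  if (cx - r_out < -tol_x || cx + r_out > geometry$width_mm + tol_x ||
      cy - r_out < -tol_y || cy + r_out > geometry$height_mm + tol_y) {
    stop(errorCondition(
      sprintf("outer %g mm circle at pixel (%d, %d) does not fit the %g x %g mm scan",
              outer_diameter_mm, center[1], center[2],
              geometry$width_mm, geometry$height_mm),
      class = c("octa_grid_outside", "error", "condition")))
  }
  x <- (seq_len(nc) - 0.5) * ps$x
  y <- (seq_len(nr) - 0.5) * ps$y
  d2 <- outer(y - cy, x - cx, function(a, b) a^2 + b^2)
  total <- d2 <= r_out^2
  central <- d2 <= r_in^2
  parafoveal <- total & !central
  structure(list(center = center, inner_diameter_mm = inner_diameter_mm,
                 outer_diameter_mm = outer_diameter_mm,
                 central = central, parafoveal = parafoveal, total = total,
                 area_mm2 = c(central = sum(central) * ps$area,
                              parafoveal = sum(parafoveal) * ps$area,
                              total = sum(total) * ps$area)),
            class = "etdrs_grid")
}

#' Inventory of non-perfused regions
#'
#' Non-perfused regions are dark (background) areas of the binarized image
#' larger than `min_area_mm2` (default 0.02 mm^2, strictly greater-than).
#' Components are 8-connected sets of background pixels; they are clipped to
#' the region of interest before the area test, so a component straddling
#' the region boundary counts only its in-region pixels. At 3 mm / 320 px
#' geometry the 0.02 mm^2 cutoff corresponds to 228 pixels or more.
#'
#' @param mask A [binary_image()] vessel mask.
#' @param region Logical matrix restricting the analysis (e.g. an ETDRS zone
#'   mask); default: whole image.
#' @param min_area_mm2 Strict lower area bound for a qualifying component.
#' @return A `data.frame` (class `nonperfusion_inventory`) with one row per
#'   qualifying component: `label`, `pixel_count`, `area_mm2`. The label
#'   matrix of all in-region background components is kept in attribute
#'   `labels`.
#' @export
find_nonperfusion <- function(mask, region = NULL, min_area_mm2 = 0.02) {
  stopifnot(inherits(mask, "binary_image"))
  if (is.null(region)) region <- matrix(TRUE, nrow(mask$pixels), ncol(mask$pixels))
  stopifnot(is.logical(region), all(dim(region) == dim(mask$pixels)))
  ps <- pixel_scale(mask$geometry)
  dark <- (!mask$pixels) & region
  labels <- cpp_label(dark, 8L)
  counts <- tabulate(labels[labels > 0L])
  areas <- counts * ps$area
  keep <- which(areas > min_area_mm2)
  inv <- data.frame(label = keep,
                    pixel_count = counts[keep],
                    area_mm2 = areas[keep])
  attr(inv, "labels") <- labels
  attr(inv, "min_area_mm2") <- min_area_mm2
  class(inv) <- c("nonperfusion_inventory", "data.frame")
  inv
}

#' Vessel density of a region
#'
#' The percentage of region area not covered by qualifying non-perfused
#' components: `VD = 100 * (A_region - sum A_nonperfusion) / A_region`.
#' Dark areas at or below the minimum-area cutoff count as perfused.
#'
#' @inheritParams find_nonperfusion
#' @param region Logical matrix defining the region of interest (non-empty).
#' @return Vessel density in percent (0-100).
#' @export
vessel_density <- function(mask, region, min_area_mm2 = 0.02) {
  stopifnot(inherits(mask, "binary_image"), is.logical(region))
  n_region <- sum(region)
  if (n_region == 0L)
    stop(errorCondition("empty region has no vessel density",
                        class = c("octa_empty_region", "error", "condition")))
  inv <- find_nonperfusion(mask, region, min_area_mm2 = min_area_mm2)
  ps <- pixel_scale(mask$geometry)
  a_region <- n_region * ps$area
  100 * (a_region - sum(inv$area_mm2)) / a_region
}

#' Skeletonize a vessel mask
#'
#' Morphological thinning (Guo-Hall two-subiteration algorithm) to
#' one-pixel-wide, 8-connected centrelines. Thinning only removes pixels,
#' so the skeleton is a subset of the mask, and it preserves topology
#' (same number of connected components).
#'
#' @param mask A [binary_image()] vessel mask.
#' @return A [skeleton_image()].
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_image"))
  skeleton_image(cpp_thin(mask$pixels), mask$geometry)
}

#' Total skeleton length
#'
#' Sums the physical length of every undirected 8-neighbour link between
#' skeleton pixels, counting each link once: horizontal links contribute
#' the pixel width, vertical links the pixel height, diagonal links the
#' pixel diagonal. An isolated pixel contributes nothing.
#'
#' @param skeleton A [skeleton_image()].
#' @return Length in mm.
#' @export
skeleton_length <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_image"))
  s <- skeleton$pixels
  ps <- pixel_scale(skeleton$geometry)
  nr <- nrow(s); nc <- ncol(s)
  # count each undirected link once via E, S, SE, SW neighbours
  east <- sum(s[, -nc] & s[, -1])
  south <- sum(s[-nr, ] & s[-1, ])
  se <- sum(s[-nr, -nc] & s[-1, -1])
  sw <- sum(s[-nr, -1] & s[-1, -nc])
  diag_len <- sqrt(ps$x^2 + ps$y^2)
  east * ps$x + south * ps$y + (se + sw) * diag_len
}

#' Box-counting fractal dimension
#'
#' Covers the binary pattern with grids of boxes of side `s = 2, 4, 8, ...`
#' pixels (anchored at the image origin, no offset averaging) up to a
#' quarter of the smaller image dimension, counts the boxes `N(s)`
#' containing at least one foreground pixel, and returns the least-squares
#' slope of `log N(s)` against `log(1/s)` over all computed scales. A
#' straight line yields a dimension near 1, a filled plane near 2;
#' branching vessel networks fall in between, decreasing with capillary
#' dropout.
#'
#' @param skeleton A [skeleton_image()] (or [binary_image()] when the
#'   binary-mask reading of the metric is wanted).
#' @return The fractal dimension (numeric scalar) with attributes
#'   `box_sizes`, `counts` and `r_squared`.
#' @section Errors: `octa_fd_degenerate` if fewer than 2 foreground pixels
#'   or fewer than 3 box scales are available.
#' @export
fractal_dimension <- function(skeleton) {
  stopifnot(inherits(skeleton, "octa_image"), is.logical(skeleton$pixels))
  s <- skeleton$pixels
  npix <- sum(s)
  sizes <- 2^seq_len(30)
  sizes <- sizes[sizes <= min(dim(s)) / 4]
  if (npix < 2L || length(sizes) < 3L) {
    stop(errorCondition(
      "box-counting needs >= 2 foreground pixels and >= 3 box scales",
      class = c("octa_fd_degenerate", "error", "condition")))
  }
  idx <- which(s, arr.ind = TRUE)
  counts <- vapply(sizes, function(b) {
    boxes <- (idx[, 1] - 1L) %/% b * (ncol(s) %/% b + 2L) + (idx[, 2] - 1L) %/% b
    length(unique(boxes))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  fd <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(fd, box_sizes = sizes, counts = counts, r_squared = r2)
}

#' Vessel diameter index
#'
#' Mean vessel calibre: the area occupied by vessels in the binarized image
#' divided by the total centreline length from the skeletonized image.
#'
#' @param mask A [binary_image()] vessel mask.
#' @param skeleton The corresponding [skeleton_image()]; computed from
#'   `mask` when omitted.
#' @return VDI in mm.
#' @section Errors: `octa_zero_skeleton` when the skeleton has zero length.
#' @export
vessel_diameter_index <- function(mask, skeleton = NULL) {
  stopifnot(inherits(mask, "binary_image"))
  if (is.null(skeleton)) skeleton <- skeletonize_mask(mask)
  stopifnot(inherits(skeleton, "skeleton_image"))
  len <- skeleton_length(skeleton)
  if (len <= 0)
    stop(errorCondition("skeleton length is zero; VDI undefined",
                        class = c("octa_zero_skeleton", "error", "condition")))
  area <- sum(mask$pixels) * pixel_scale(mask$geometry)$area
  area / len
}
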