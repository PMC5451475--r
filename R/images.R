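#' Image containers
#'
#' The pipeline passes images through three states: a grayscale intensity
#' image (`gray_image`, values in \[0, 1\]), a binary vessel mask
#' (`binary_image`, `TRUE` = vessel/white) and a one-pixel-wide centreline
#' mask (`skeleton_image`). Each carries its [scan_geometry()] so that every
#' downstream measurement can convert pixels to millimetres. Matrices are
#' stored row-major in the display sense: row 1 is the top image row.
#'
#' @param pixels Numeric matrix in \[0, 1\] (`gray_image`) or logical matrix
#'   (`binary_image`, `skeleton_image`).
#' @param geometry A [scan_geometry()] matching the matrix dimensions.
#' @param quality_score Optional integer 0-100 device quality score.
#' @return An object of the corresponding class.
#' @name octa-images
NULL

#' @rdname octa-images
#' @export
gray_image <- function(pixels, geometry, quality_score = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            inherits(geometry, "scan_geometry"))
  check_dims(pixels, geometry)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("gray_image intensities must lie in [0, 1] and contain no NA")
  if (!is.null(quality_score)) {
    quality_score <- as.integer(quality_score)
    stopifnot(length(quality_score) == 1L, !is.na(quality_score),
              quality_score >= 0L, quality_score <= 100L)
  }
  structure(list(pixels = pixels, geometry = geometry,
                 quality_score = quality_score),
            class = c("gray_image", "octa_image"))
}

#' @rdname octa-images
#' @export
binary_image <- function(pixels, geometry) {
  stopifnot(is.matrix(pixels), is.logical(pixels),
            inherits(geometry, "scan_geometry"))
  check_dims(pixels, geometry, "mask")
  if (anyNA(pixels)) stop("binary mask must not contain NA")
  structure(list(pixels = pixels, geometry = geometry),
            class = c("binary_image", "octa_image"))
}

#' @rdname octa-images
#' @export
skeleton_image <- function(pixels, geometry) {
  stopifnot(is.matrix(pixels), is.logical(pixels),
            inherits(geometry, "scan_geometry"))
  check_dims(pixels, geometry, "skeleton")
  structure(list(pixels = pixels, geometry = geometry),
            class = c("skeleton_image", "octa_image"))
}

#' @export
print.octa_image <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("%s: %d x %d px, %g x %g mm", kind,
              nrow(x$pixels), ncol(x$pixels),
              x$geometry$width_mm, x$geometry$height_mm))
  if (kind == "gray_image") {
    cat(sprintf(", intensity [%.3f, %.3f]", min(x$pixels), max(x$pixels)))
    if (!is.null(x$quality_score))
      cat(sprintf(", quality %d", x$quality_score))
  } else {
    cat(sprintf(", %d foreground px", sum(x$pixels)))
  }
  cat("\n")
  invisible(x)
}
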