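#' Scan geometry of an en-face OCT-A image
#'
#' Describes the physical extent and pixel grid of an en-face angiogram.
#' All millimetre/pixel conversions in the package derive from this object.
#' The default clinical acquisition protocol for the superficial capillary
#' plexus covers 3 mm x 3 mm with 320 x 320 A-scans, giving a pixel pitch
#' of 9.375 um.
#'
#' @param width_mm Physical scan width in mm (> 0).
#' @param height_mm Physical scan height in mm (> 0); defaults to `width_mm`.
#' @param width_px Number of pixel columns (>= 16).
#' @param height_px Number of pixel rows (>= 16); defaults to `width_px`.
#'
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(3, 3, 320, 320)
#' pixel_scale(g)
#' @export
scan_geometry <- function(width_mm, height_mm = width_mm, width_px,
                          height_px = width_px) {
  stopifnot(is.numeric(width_mm), length(width_mm) == 1L, is.finite(width_mm),
            is.numeric(height_mm), length(height_mm) == 1L, is.finite(height_mm))
  if (width_mm <= 0 || height_mm <= 0)
    stop("scan width_mm and height_mm must be strictly positive")
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || is.na(height_px) || width_px < 16L || height_px < 16L)
    stop("width_px and height_px must be integers >= 16")
  structure(
    list(width_mm = as.numeric(width_mm), height_mm = as.numeric(height_mm),
         width_px = width_px, height_px = height_px),
    class = "scan_geometry"
  )
}

#' Pixel pitch and pixel area of a scan geometry
#'
#' @param geometry A [scan_geometry()] object.
#' @return A list with elements `x` (pixel width, mm), `y` (pixel height, mm)
#'   and `area` (pixel area, mm^2), computed as exact quotients.
#' @export
pixel_scale <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  px <- geometry$width_mm / geometry$width_px
  py <- geometry$height_mm / geometry$height_px
  list(x = px, y = py, area = px * py)
}

#' @export
print.scan_geometry <- function(x, ...) {
  ps <- pixel_scale(x)
  cat(sprintf("scan_geometry: %g x %g mm, %d x %d px (%.4g x %.4g um/px)\n",
              x$width_mm, x$height_mm, x$width_px, x$height_px,
              ps$x * 1000, ps$y * 1000))
  invisible(x)
}

# internal: check that a matrix matches a geometry
check_dims <- function(pixels, geometry, what = "image") {
  if (nrow(pixels) != geometry$height_px || ncol(pixels) != geometry$width_px) {
    stop(errorCondition(
      sprintf("%s is %d x %d px but geometry declares %d x %d px",
              what, nrow(pixels), ncol(pixels),
              geometry$height_px, geometry$width_px),
      class = c("octa_geometry_mismatch", "error", "condition")
    ))
  }
  invisible(TRUE)
}
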