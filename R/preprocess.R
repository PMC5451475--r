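#' Non-local means denoising parameters
#'
#' Defaults (5x5 patches compared over a 15x15 search window, filter
#' strength 0.08 of the dynamic range) are chosen for 320 x 320 angiograms:
#' strong enough to suppress decorrelation speckle in avascular areas while
#' preserving single-capillary strokes of 2-4 px calibre.
#'
#' @param patch_radius Patch half-width in pixels (>= 1; 2 means 5x5 patches).
#' @param search_radius Search-window half-width in pixels (>= patch_radius).
#' @param h Filter strength as a fraction of the \[0, 1\] dynamic range (> 0).
#'   Smaller values preserve more detail; larger values smooth more.
#' @return A list of class `nlm_params`.
#' @export
nlm_params <- function(patch_radius = 2, search_radius = 7, h = 0.08) {
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  stopifnot(patch_radius >= 1L, search_radius >= patch_radius,
            is.numeric(h), h > 0)
  structure(list(patch_radius = patch_radius, search_radius = search_radius,
                 h = as.numeric(h)),
            class = "nlm_params")
}

#' Non-local means denoising
#'
#' Each output pixel is a weight-normalized average of the pixels in its
#' search window, weighted by the similarity of the surrounding intensity
#' patches: `w = exp(-d2 / h^2)` where `d2` is the mean squared difference
#' over aligned patches. Weights sum to one, so the output never leaves the
#' convex hull of the input intensities. Borders use mirror-reflection
#' padding.
#'
#' @param image A [gray_image()].
#' @param params An [nlm_params()] object.
#' @return The denoised [gray_image()] (same dimensions, quality score
#'   carried over).
#' @export
denoise_nlm <- function(image, params = nlm_params()) {
  stopifnot(inherits(image, "gray_image"), inherits(params, "nlm_params"))
  win <- 2L * params$search_radius + 1L
  if (win > nrow(image$pixels) || win > ncol(image$pixels)) {
    stop(errorCondition(
      sprintf("NLM search window (%d px) larger than image (%d x %d px)",
              win, nrow(image$pixels), ncol(image$pixels)),
      class = c("octa_window_too_large", "error", "condition")))
  }
  out <- cpp_nlm(image$pixels, params$patch_radius, params$search_radius,
                 params$h)
  # weighted averages can step a hair outside [0,1] only by rounding
  out[out < 0] <- 0
  out[out > 1] <- 1
  gray_image(out, image$geometry, quality_score = image$quality_score)
}

#' Phansalkar adaptive local thresholding parameters
#'
#' Constants default to the original Phansalkar formulation (k = 0.25,
#' r = 0.5, p = 2, q = 10), with `r` defined on the \[0, 1\] intensity
#' scale (0.5 = half the dynamic range). The default window radius of 15 px
#' (about 0.28 mm at 9.375 um/px) spans the typical intercapillary spacing
#' next to the FAZ, so local statistics always mix vessel and background.
#'
#' @param window_radius Half-width of the local window in pixels (>= 1).
#' @param k Sensitivity constant.
#' @param r Normalization of the local standard deviation (> 0).
#' @param p Amplitude of the exponential low-mean correction.
#' @param q Decay rate of the exponential low-mean correction.
#' @return A list of class `phansalkar_params`.
#' @export
phansalkar_params <- function(window_radius = 15, k = 0.25, r = 0.5,
                              p = 2, q = 10) {
  window_radius <- as.integer(window_radius)
  stopifnot(window_radius >= 1L, is.numeric(r), r > 0)
  structure(list(window_radius = window_radius, k = as.numeric(k),
                 r = as.numeric(r), p = as.numeric(p), q = as.numeric(q)),
            class = "phansalkar_params")
}

#' Phansalkar adaptive local thresholding
#'
#' Binarizes an angiogram into white vessel and black background pixels.
#' A pixel is vessel iff its intensity strictly exceeds the local threshold
#' `t = m * (1 + p * exp(-q * m) + k * (s / r - 1))`, where `m` and `s` are
#' the mean and standard deviation over the local window. The exponential
#' term raises the threshold in dark regions, which suppresses the
#' background speckle that defeats plain mean/Niblack thresholds on OCT-A.
#' Border windows are mirror-reflected.
#'
#' @param image A [gray_image()] (normally the denoised image).
#' @param params A [phansalkar_params()] object.
#' @return A [binary_image()] vessel mask.
#' @export
binarize_phansalkar <- function(image, params = phansalkar_params()) {
  stopifnot(inherits(image, "gray_image"),
            inherits(params, "phansalkar_params"))
  win <- 2L * params$window_radius + 1L
  if (win > nrow(image$pixels) || win > ncol(image$pixels)) {
    stop(errorCondition(
      sprintf("threshold window (%d px) larger than image (%d x %d px)",
              win, nrow(image$pixels), ncol(image$pixels)),
      class = c("octa_window_too_large", "error", "condition")))
  }
  ms <- cpp_local_mean_sd(image$pixels, params$window_radius)
  thr <- ms$mean * (1 + params$p * exp(-params$q * ms$mean) +
                      params$k * (ms$sd / params$r - 1))
  binary_image(image$pixels > thr, image$geometry)
}
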