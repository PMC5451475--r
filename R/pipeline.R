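#' Pipeline configuration
#'
#' Bundles every tunable parameter of the quantification chain. Defaults
#' reproduce the standard analysis: NLM denoising, Phansalkar binarization,
#' centre-seeded FAZ region growing, ETDRS grid centred on the FAZ
#' centroid, the 0.02 mm^2 non-perfusion rule, and fractal dimension
#' computed on the skeleton.
#'
#' @param nlm [nlm_params()].
#' @param phansalkar [phansalkar_params()].
#' @param min_quality QC cutoff on the device quality score (default 40).
#' @param faz_seed Optional `c(row, col)` FAZ seed; default scan centre.
#' @param grid_center `"faz"` (ETDRS grid at the FAZ centroid, falling back
#'   to the image centre if the 3 mm circle does not fit) or `"image"`.
#' @param min_nonperfusion_mm2 Strict area cutoff for non-perfused regions.
#' @param fd_source `"skeleton"` (default) or `"binary"`: which image the
#'   box-counting dimension is computed on.
#' @param perimeter_method Passed to [faz_perimeter()].
#' @return A list of class `octa_config`.
#' @export
octa_config <- function(nlm = nlm_params(), phansalkar = phansalkar_params(),
                        min_quality = 40, faz_seed = NULL,
                        grid_center = c("faz", "image"),
                        min_nonperfusion_mm2 = 0.02,
                        fd_source = c("skeleton", "binary"),
                        perimeter_method = c("kulpa", "chain")) {
  structure(list(nlm = nlm, phansalkar = phansalkar,
                 min_quality = min_quality, faz_seed = faz_seed,
                 grid_center = match.arg(grid_center),
                 min_nonperfusion_mm2 = min_nonperfusion_mm2,
                 fd_source = match.arg(fd_source),
                 perimeter_method = match.arg(perimeter_method)),
            class = "octa_config")
}

#' Run the full quantification pipeline on one angiogram
#'
#' Executes the stages in their fixed order: QC gate, NLM denoising,
#' Phansalkar binarization, FAZ region growing and shape metrics, ETDRS
#' vessel densities, skeletonization, fractal dimension and vessel
#' diameter index. Returns one [metric_record()]. If the QC gate fails and
#' `force = FALSE`, the record carries `qc_pass = FALSE` and missing
#' metrics. Stage errors are re-raised with the failing stage named.
#'
#' @param image A [gray_image()].
#' @param config An [octa_config()].
#' @param image_id Identifier for the output record (default `"image"`).
#' @param force Process the image even if the QC gate fails.
#' @param save_intermediates Optional directory; when given, the denoised
#'   image, vessel mask, skeleton and FAZ mask are written there as PNG
#'   together with a JSON file of the parameters used.
#' @return A [metric_record()] with attribute `intermediates` (a list with
#'   the denoised image, mask, FAZ result, grid, skeleton and
#'   per-region vessel densities).
#' @export
compute_all <- function(image, config = octa_config(), image_id = "image",
                        force = FALSE, save_intermediates = NULL) {
  stopifnot(inherits(image, "gray_image"), inherits(config, "octa_config"))
  # absent score: the gate is metadata-driven, nothing to check
  qc <- if (is.null(image$quality_score)) TRUE else
    qc_gate(image, min_quality = config$min_quality)
  if (!qc && !force) {
    return(metric_record(image_id, qc_pass = FALSE))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("octa_stage_error", class(e))))
    })
  }
  den <- stage("denoise", denoise_nlm(image, config$nlm))
  mask <- stage("binarize", binarize_phansalkar(den, config$phansalkar))
  faz <- stage("faz", faz_analyze(mask, seed = config$faz_seed,
                                  method = config$perimeter_method))
  grid <- stage("etdrs", {
    center <- NULL
    if (config$grid_center == "faz") {
      idx <- which(faz$region_mask, arr.ind = TRUE)
      center <- round(colMeans(idx))
      fit <- tryCatch(build_etdrs_grid(image$geometry, center = center),
                      error = function(e) NULL)
      if (is.null(fit)) {
        warning("ETDRS grid at FAZ centroid does not fit; using image centre")
        center <- NULL
      }
    }
    build_etdrs_grid(image$geometry, center = center)
  })
  vd_total <- stage("vessel_density", vessel_density(
    mask, grid$total, min_area_mm2 = config$min_nonperfusion_mm2))
  vd_para <- stage("vessel_density", vessel_density(
    mask, grid$parafoveal, min_area_mm2 = config$min_nonperfusion_mm2))
  skel <- stage("skeletonize", skeletonize_mask(mask))
  fd <- stage("fractal_dimension", fractal_dimension(
    if (config$fd_source == "skeleton") skel else mask))
  vdi <- stage("vdi", vessel_diameter_index(mask, skel))
  rec <- metric_record(image_id,
                       faz_area_mm2 = faz$area_mm2,
                       faz_circularity = faz$circularity,
                       total_vd_pct = vd_total,
                       parafoveal_vd_pct = vd_para,
                       fractal_dimension = as.numeric(fd),
                       vdi_mm = vdi,
                       qc_pass = qc)
  inter <- list(denoised = den, mask = mask, faz = faz, grid = grid,
                skeleton = skel,
                vd = c(total = vd_total, parafoveal = vd_para))
  if (!is.null(save_intermediates)) {
    dir.create(save_intermediates, showWarnings = FALSE, recursive = TRUE)
    save_image(den, file.path(save_intermediates,
                              paste0(image_id, "_denoised.png")))
    save_image(mask, file.path(save_intermediates,
                               paste0(image_id, "_mask.png")))
    save_image(skel, file.path(save_intermediates,
                               paste0(image_id, "_skeleton.png")))
    save_image(binary_image(faz$region_mask, image$geometry),
               file.path(save_intermediates, paste0(image_id, "_faz.png")))
    params <- list(nlm = unclass(config$nlm),
                   phansalkar = unclass(config$phansalkar),
                   min_quality = config$min_quality,
                   min_nonperfusion_mm2 = config$min_nonperfusion_mm2,
                   fd_source = config$fd_source,
                   perimeter_method = config$perimeter_method,
                   faz_seed = faz$seed, grid_center = grid$center)
    jsonlite::write_json(params,
                         file.path(save_intermediates,
                                   paste0(image_id, "_params.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(rec, "intermediates") <- inter
  rec
}
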