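#' Load a grayscale en-face angiogram from PNG or TIFF
#'
#' Reads an 8- or 16-bit single-channel image and normalizes intensities to
#' \[0, 1\] by the bit-depth maximum (not per-image min/max), so that
#' thresholding behaves identically across images. Multi-channel files whose
#' colour channels are identical (grayscale stored as RGB) are collapsed to
#' one channel; an alpha channel is dropped. True-colour images are rejected.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param geometry [scan_geometry()] declaring the physical extent; its pixel
#'   dimensions must match the file.
#' @param quality_score Optional device quality score (integer 0-100).
#' @return A [gray_image()].
#' @section Errors: missing file (`octa_missing_file`), true-colour input
#'   (`octa_channel_mismatch`), dimension mismatch (`octa_geometry_mismatch`).
#' @export
load_angiogram <- function(path, geometry, quality_score = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("no such image file: %s", path),
                        class = c("octa_missing_file", "error", "condition")))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext))
  )
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    # channels 1..3 are colour, a 2nd or 4th channel is alpha
    col_ch <- if (nch %in% c(2L, 4L)) seq_len(nch - 1L) else seq_len(nch)
    if (length(col_ch) > 1L) {
      ref <- arr[, , col_ch[1]]
      same <- vapply(col_ch[-1], function(j) isTRUE(all.equal(arr[, , j], ref,
                                                              tolerance = 0)),
                     logical(1))
      if (!all(same)) {
        stop(errorCondition(
          "true-colour image: channels differ, cannot collapse to grayscale",
          class = c("octa_channel_mismatch", "error", "condition")))
      }
    }
    arr <- arr[, , col_ch[1]]
  }
  check_dims(arr, geometry)
  gray_image(arr, geometry, quality_score = quality_score)
}

#' Write an intensity image or mask as PNG
#'
#' Grayscale intensities are stored as 16-bit PNG to preserve precision;
#' masks are stored as 8-bit black/white.
#'
#' @param image A `gray_image`, `binary_image` or `skeleton_image`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "octa_image"))
  px <- image$pixels
  if (is.logical(px)) {
    png::writePNG(px * 1.0, path)
  } else {
    # quantize to 16 bit explicitly so load -> save -> load is idempotent
    png::writePNG(round(px * 65535) / 65535, path)
  }
  invisible(path)
}

#' Quality-score gate
#'
#' Scans with a device quality score below the cutoff are flagged for
#' exclusion; the default cutoff of 40 reflects standard reading-centre
#' practice for swept-source OCT-A. An image without a score passes with a
#' warning, since the score is metadata and its absence should never block
#' processing.
#'
#' @param image A [gray_image()].
#' @param min_quality Minimum acceptable quality score (default 40).
#' @return `TRUE` if the image passes, `FALSE` otherwise.
#' @export
qc_gate <- function(image, min_quality = 40) {
  stopifnot(inherits(image, "gray_image"))
  if (is.null(image$quality_score)) {
    warning("no quality score attached; passing QC gate by default")
    return(TRUE)
  }
  image$quality_score >= min_quality
}

metric_cols <- c("image_id", "faz_area_mm2", "faz_circularity",
                 "total_vd_pct", "parafoveal_vd_pct", "fractal_dimension",
                 "vdi_mm", "qc_pass")

#' Assemble a per-image metric record
#'
#' One row of the final results table: the six headline metrics plus the QC
#' flag. Metrics that could not be computed are stored as `NA`.
#'
#' @param image_id Identifier string.
#' @param faz_area_mm2,faz_circularity,total_vd_pct,parafoveal_vd_pct
#'   FAZ and vessel-density metrics.
#' @param fractal_dimension,vdi_mm Skeleton-derived metrics.
#' @param qc_pass Logical QC flag.
#' @return A one-row `data.frame` with class `metric_record`.
#' @export
metric_record <- function(image_id, faz_area_mm2 = NA_real_,
                          faz_circularity = NA_real_, total_vd_pct = NA_real_,
                          parafoveal_vd_pct = NA_real_,
                          fractal_dimension = NA_real_, vdi_mm = NA_real_,
                          qc_pass = TRUE) {
  rec <- data.frame(image_id = as.character(image_id),
                    faz_area_mm2 = as.numeric(faz_area_mm2),
                    faz_circularity = as.numeric(faz_circularity),
                    total_vd_pct = as.numeric(total_vd_pct),
                    parafoveal_vd_pct = as.numeric(parafoveal_vd_pct),
                    fractal_dimension = as.numeric(fractal_dimension),
                    vdi_mm = as.numeric(vdi_mm),
                    qc_pass = isTRUE(qc_pass),
                    stringsAsFactors = FALSE)
  class(rec) <- c("metric_record", "data.frame")
  rec
}

#' Write and read metric records
#'
#' Records round-trip losslessly: strings and booleans bit-identically,
#' floats to full double precision (17 significant digits in CSV; JSON is
#' written with unrestricted digits).
#'
#' @param records A `data.frame` of metric records (rows in [metric_record()]
#'   column order) or a list of such records.
#' @param path Output file path.
#' @param format `"csv"` (one row per image, fixed column order) or `"json"`
#'   (array of objects).
#' @return `path`, invisibly (`write_metrics`); a `data.frame`
#'   (`read_metrics`).
#' @export
write_metrics <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop(errorCondition("no metric records to write",
                        class = c("octa_empty_records", "error", "condition")))
  }
  stopifnot(all(metric_cols %in% names(records)))
  records <- as.data.frame(records)[, metric_cols]
  if (format == "csv") {
    out <- records
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]]))
        out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    }
    # quote only the string column: quoted numerics defeat read-back with
    # declared column classes
    utils::write.csv(out, path, row.names = FALSE,
                     quote = which(metric_cols == "image_id"))
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    cls <- c(image_id = "character", faz_area_mm2 = "numeric",
             faz_circularity = "numeric", total_vd_pct = "numeric",
             parafoveal_vd_pct = "numeric", fractal_dimension = "numeric",
             vdi_mm = "numeric", qc_pass = "logical")
    rec <- utils::read.csv(path, colClasses = cls, stringsAsFactors = FALSE)
  } else {
    rec <- jsonlite::fromJSON(path)
    rec$image_id <- as.character(rec$image_id)
    for (nm in setdiff(metric_cols, c("image_id", "qc_pass")))
      rec[[nm]] <- as.numeric(rec[[nm]])
    rec$qc_pass <- as.logical(rec$qc_pass)
  }
  rec[, metric_cols]
}
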