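#' Write a dose map as 16-bit TIFF plus JSON sidecar
#'
#' The dose matrix is stored as an uncompressed 16-bit grayscale TIFF,
#' linearly scaled so the map maximum hits 65535; the scale and all metadata
#' (plan id, plane, offset, spacing, beam label and parameters) go to a JSON
#' sidecar next to it. The written representation round-trips bit-exactly:
#' writing the result of [read_dose_map()] reproduces identical files.
#'
#' @param map A [dose_map()].
#' @param path Base path; `.tif` and `.json` are appended.
#' @param beam Optional [beam_model()] recorded in the sidecar.
#' @return Base path, invisibly.
#' @export
write_dose_map <- function(map, path, beam = NULL) {
  stopifnot(inherits(map, "dose_map"))
  mx <- max(map$values)
  scale <- if (mx > 0) mx else 1
  q <- round(map$values / scale * 65535)
  tiff::writeTIFF(q / 65535, paste0(path, ".tif"),
                  bits.per.sample = 16, compression = "none")
  meta <- list(plan_id = map$plan_id, plane = map$plane,
               offset_mm = map$offset_mm, spacing_mm = map$spacing_mm,
               coord0_mm = map$coords[1], site = map$site,
               beam_label = map$beam_label, scale = scale)
  if (!is.null(beam))
    meta$beam <- list(tf = beam$tf, dlg_mm = beam$dlg_mm,
                      penumbra_sigma_mm = beam$penumbra_sigma_mm,
                      mu_per_mm = beam$mu_per_mm)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dose map written by [write_dose_map()]
#'
#' @param path Base path used when writing (without extension).
#' @return A [dose_map()] (dose values quantized to the stored 16-bit
#'   precision).
#' @export
read_dose_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(paste0(path, ".tif"))
  if (length(dim(v)) == 3) v <- v[, , 1]
  values <- round(v * 65535) / 65535 * meta$scale
  n <- nrow(values)
  coords <- meta$coord0_mm + (seq_len(n) - 1) * meta$spacing_mm
  dose_map(values, meta$spacing_mm, meta$plane, meta$offset_mm, meta$plan_id,
           label = beam_label(meta$beam_label$error_type,
                              meta$beam_label$sign,
                              meta$beam_label$magnitude_pct),
           site = meta$site, coords = coords)
}
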