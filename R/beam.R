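#' Beam model with MLC transmission factor and dosimetric leaf gap
#'
#' The beam model couples the two adjustable MLC modeling parameters of a
#' clinical treatment planning system -- the transmission factor (TF, the
#' fraction of dose transmitted through closed leaves) and the dosimetric
#' leaf gap (DLG, the effective widening in mm of each leaf-pair opening that
#' models rounded-leaf-end transmission) -- with the two physics constants of
#' the simplified dose engine (lateral Gaussian penumbra and linear depth
#' attenuation).
#'
#' Nominal values follow a commissioned 6 MV beam: TF = 1.22% and
#' DLG = 0.88 mm. These are the parameters that are perturbed to create
#' MLC modeling error plans.
#'
#' @param tf Dimensionless leaf transmission fraction, `0 <= tf < 1`.
#' @param dlg_mm Dosimetric leaf gap in mm, `>= 0`.
#' @param penumbra_sigma_mm Standard deviation (mm) of the lateral Gaussian
#'   blur applied to each control-point fluence; models the finite source
#'   size and leaf-end penumbra. Must be `> 0`.
#' @param mu_per_mm Linear attenuation coefficient (1/mm) of the
#'   water-equivalent phantom material for the depth falloff of the engine.
#' @return An object of class `beam_model`.
#' @examples
#' b <- beam_model()
#' b$tf      # 0.0122
#' b$dlg_mm  # 0.88
#' @export
beam_model <- function(tf = 0.0122, dlg_mm = 0.88,
                       penumbra_sigma_mm = 3.0, mu_per_mm = 0.005) {
  if (!is.numeric(tf) || length(tf) != 1 || tf < 0 || tf >= 1)
    stop_named("vmatqa_invalid_beam", "tf must satisfy 0 <= tf < 1")
  if (!is.numeric(dlg_mm) || length(dlg_mm) != 1 || dlg_mm < 0)
    stop_named("vmatqa_invalid_beam", "dlg_mm must be >= 0")
  if (!is.numeric(penumbra_sigma_mm) || penumbra_sigma_mm <= 0)
    stop_named("vmatqa_invalid_beam", "penumbra_sigma_mm must be > 0")
  if (!is.numeric(mu_per_mm) || mu_per_mm < 0)
    stop_named("vmatqa_invalid_beam", "mu_per_mm must be >= 0")
  structure(list(tf = tf, dlg_mm = dlg_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 mu_per_mm = mu_per_mm),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> TF = %.4f%%, DLG = %.3f mm, penumbra sigma = %.2f mm, mu = %.4f /mm\n",
              100 * x$tf, x$dlg_mm, x$penumbra_sigma_mm, x$mu_per_mm))
  invisible(x)
}

#' Perturb one MLC modeling parameter of a beam model
#'
#' Creates the error beam models of the study: the named parameter (TF or
#' DLG) is scaled multiplicatively by `1 + delta_pct/100`; everything else is
#' untouched and the input object is not modified.
#'
#' @param beam A [beam_model()].
#' @param param `"TF"` or `"DLG"`.
#' @param delta_pct Percent perturbation, one of `0, -30, -20, -10, 10, 20, 30`.
#' @return A new `beam_model`.
#' @examples
#' perturb_beam(beam_model(), "TF", 10)$tf      # 0.01342
#' perturb_beam(beam_model(), "DLG", -20)$dlg_mm # 0.704
#' @export
perturb_beam <- function(beam, param = c("TF", "DLG"), delta_pct) {
  stopifnot(inherits(beam, "beam_model"))
  param <- match.arg(param)
  if (!delta_pct %in% c(0, -30, -20, -10, 10, 20, 30))
    stop_named("vmatqa_invalid_perturbation",
               "delta_pct must be one of 0, +/-10, +/-20, +/-30")
  f <- 1 + delta_pct / 100
  if (param == "TF") {
    tf <- beam$tf * f
    if (tf >= 1) stop_named("vmatqa_invalid_perturbation", "perturbed tf >= 1")
    beam_model(tf, beam$dlg_mm, beam$penumbra_sigma_mm, beam$mu_per_mm)
  } else {
    dlg <- beam$dlg_mm * f
    if (dlg < 0) stop_named("vmatqa_invalid_perturbation", "perturbed dlg < 0")
    beam_model(beam$tf, dlg, beam$penumbra_sigma_mm, beam$mu_per_mm)
  }
}

#' Beam label constructor (error class of a calculated dose distribution)
#' @keywords internal
#' @noRd
beam_label <- function(error_type = "error_free", sign = "n/a", magnitude_pct = 0) {
  stopifnot(error_type %in% c("error_free", "TF", "DLG"))
  list(error_type = error_type, sign = sign, magnitude_pct = magnitude_pct)
}
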