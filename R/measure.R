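#' Mimicked-measurement model
#'
#' The detector-independent measurement surrogate: a Gaussian blur of
#' standard deviation `sigma` followed by a median filter. `sigma` is given
#' in pixels of the dose calculation grid (the study values are 0.5 and 1.0,
#' i.e. 1.0 mm and 2.0 mm at the 2.0 mm grid; `sigma = 0` disables the blur
#' for raw difference-map inspection). The median filter is applied to all
#' dose distributions, measured and calculated alike.
#'
#' @param sigma Gaussian standard deviation, `>= 0`. Interpreted in grid
#'   pixels unless `sigma_units = "mm"`.
#' @param median_kernel Odd median window size (default 3; 1 disables).
#' @param sigma_units `"grid"` (pixels of the calculation grid) or `"mm"`.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(sigma = 0.5, median_kernel = 3,
                              sigma_units = c("grid", "mm")) {
  sigma_units <- match.arg(sigma_units)
  if (!is.numeric(sigma) || sigma < 0)
    stop_named("vmatqa_invalid_measurement", "sigma must be >= 0")
  if (median_kernel < 1 || median_kernel %% 2 == 0)
    stop_named("vmatqa_invalid_measurement", "median_kernel must be odd and >= 1")
  structure(list(sigma = sigma, median_kernel = median_kernel,
                 sigma_units = sigma_units),
            class = "measurement_model")
}

#' @keywords internal
#' @noRd
gaussian_filter_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  nv <- nrow(m)
  pad <- 2 * ceiling(3 * sigma_px) + 2
  f <- EBImage::gblur(reflect_pad(m, pad), sigma = sigma_px)
  f[(pad + 1):(pad + nv), (pad + 1):(pad + ncol(m))]
}

#' @keywords internal
#' @noRd
median_filter_matrix <- function(m, kernel) {
  if (kernel <= 1) return(m)
  .median_filter(m, (kernel - 1L) %/% 2L)
}

#' Turn a calculated dose map into a mimicked measured dose map
#'
#' Applies the Gaussian filter of the measurement model and then the median
#' filter, with reflective boundary padding. The output grid is identical to
#' the input grid; the applied `sigma` is recorded on the result.
#'
#' @param map A [dose_map()] (normally the error-free calculation: the
#'   machine is assumed to deliver the truth, and the modeling error lives in
#'   the calculated map it is compared against).
#' @param model A [measurement_model()].
#' @return A [dose_map()] with attribute `sigma`.
#' @export
mimic_measurement <- function(map, model = measurement_model()) {
  stopifnot(inherits(map, "dose_map"), inherits(model, "measurement_model"))
  sigma_px <- if (model$sigma_units == "mm") model$sigma / map$spacing_mm else model$sigma
  v <- gaussian_filter_matrix(map$values, sigma_px)
  v <- median_filter_matrix(v, model$median_kernel)
  out <- map
  out$values <- v
  attr(out, "sigma") <- model$sigma
  attr(out, "measured") <- TRUE
  out
}

#' Median-filter a calculated dose map
#'
#' The median filter of the measurement model is applied to all dose
#' distributions before subtraction; this applies it alone (no Gaussian) to
#' a calculated map.
#'
#' @inheritParams mimic_measurement
#' @return A [dose_map()].
#' @export
median_filter_map <- function(map, model = measurement_model()) {
  stopifnot(inherits(map, "dose_map"), inherits(model, "measurement_model"))
  out <- map
  out$values <- median_filter_matrix(map$values, model$median_kernel)
  out
}

#' Dose-difference grid between a measured and a calculated map
#'
#' Elementwise `measured - calculated` on the common grid. The result
#' inherits the error label of the calculated map (the error-free class uses
#' the error-free calculated map) and the `sigma` recorded on the measured
#' map.
#'
#' @param measured,calculated [dose_map()] objects on identical grids with
#'   matching plane and offset.
#' @return An object of class `dose_diff` (values may be negative).
#' @export
difference_map <- function(measured, calculated) {
  stopifnot(inherits(measured, "dose_map"), inherits(calculated, "dose_map"))
  if (!identical(dim(measured$values), dim(calculated$values)) ||
      measured$spacing_mm != calculated$spacing_mm ||
      measured$plane != calculated$plane ||
      measured$offset_mm != calculated$offset_mm)
    stop_named("vmatqa_grid_mismatch",
               "measured and calculated maps are not on the same grid/plane")
  structure(list(values = measured$values - calculated$values,
                 spacing_mm = measured$spacing_mm,
                 coords = measured$coords,
                 plane = measured$plane, offset_mm = measured$offset_mm,
                 plan_id = calculated$plan_id, site = calculated$site,
                 beam_label = calculated$beam_label,
                 sigma = attr(measured, "sigma")),
            class = "dose_diff")
}

#' Dose-difference histogram (DDH)
#'
#' Histogram of the pixelwise dose differences of one difference grid, on a
#' symmetric range about zero. Counts sum to the total pixel count.
#'
#' @param diff A `dose_diff` from [difference_map()], or a numeric matrix.
#' @param n_bins Number of bins (`>= 1`).
#' @param range_abs Optional half-range; defaults to `max(abs(values))`
#'   (1 if the grid is identically zero).
#' @return An object of class `ddh` with `breaks`, `counts` and `mids`.
#' @export
compute_ddh <- function(diff, n_bins = 101, range_abs = NULL) {
  v <- if (inherits(diff, "dose_diff")) diff$values else diff
  if (n_bins < 1)
    stop_named("vmatqa_invalid_ddh", "n_bins must be >= 1")
  if (is.null(range_abs)) range_abs <- max(abs(v))
  if (range_abs == 0) range_abs <- 1
  breaks <- seq(-range_abs, range_abs, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(breaks = breaks, counts = counts,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2),
            class = "ddh")
}

#' Overlap of two dose-difference histograms
#'
#' Intersection-over-union of the two count-normalized histograms, computed
#' on a common symmetric range. Near 1 when the distributions are
#' indistinguishable; used to quantify how measurement blur merges the TF
#' and DLG error signatures.
#'
#' @param a,b `dose_diff` objects or numeric matrices.
#' @param n_bins Number of bins.
#' @return Overlap in `[0, 1]`.
#' @export
ddh_overlap <- function(a, b, n_bins = 101) {
  va <- if (inherits(a, "dose_diff")) a$values else a
  vb <- if (inherits(b, "dose_diff")) b$values else b
  r <- max(abs(va), abs(vb), 1e-12)
  ha <- compute_ddh(va, n_bins, r)$counts / length(va)
  hb <- compute_ddh(vb, n_bins, r)$counts / length(vb)
  sum(pmin(ha, hb)) / sum(pmax(ha, hb))
}
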