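#' Convert a dose-difference grid to a 256 x 256 8-bit image
#'
#' The difference grid is resampled by bilinear interpolation onto a fixed
#' 256 x 256 lattice (0.391 mm pixels, 100.1 mm field of view centered on
#' the isocenter) and quantized with a symmetric linear window: zero dose
#' difference maps to mid-gray (128) and `+window` to 255;
#' values outside the window are clipped. The window is fixed per dataset so
#' cross-image magnitude information is preserved.
#'
#' @param diff A `dose_diff` from [difference_map()].
#' @param window Half-width of the quantization window in dose units
#'   (percent-of-maximum scale; default 5).
#' @param size Output image size (default 256).
#' @param pixel_spacing_mm Output pixel spacing (default 0.391 mm).
#' @return An object of class `dose_diff_image`: integer matrix `pixels`
#'   (0..255) plus the full label set.
#' @export
to_image <- function(diff, window = 5, size = 256, pixel_spacing_mm = 0.391) {
  stopifnot(inherits(diff, "dose_diff"))
  v <- diff$values
  if (length(v) == 0 || any(!is.finite(v)))
    stop_named("vmatqa_invalid_diff", "difference grid is empty or non-finite")
  samp <- resample_to_lattice(v, diff$coords[1], diff$spacing_mm, size,
                              pixel_spacing_mm)
  px <- matrix(as.integer(pmin(pmax(round(128 + samp * 127.5 / window), 0), 255)),
               size, size)
  structure(list(pixels = px, pixel_spacing_mm = pixel_spacing_mm,
                 window = window,
                 labels = list(error_type = diff$beam_label$error_type,
                               sign = diff$beam_label$sign,
                               magnitude_pct = diff$beam_label$magnitude_pct,
                               sigma = diff$sigma, plane = diff$plane,
                               offset_mm = diff$offset_mm,
                               plan_id = diff$plan_id, site = diff$site)),
            class = "dose_diff_image")
}

#' Map 8-bit pixel values back to dose-difference units
#'
#' Inverse of the [to_image()] quantization (up to the half-step rounding
#' error `window / 255` for in-window values).
#'
#' @param pixels Integer matrix or vector of 0..255 values, or a
#'   `dose_diff_image`.
#' @param window Quantization half-window (taken from the image if given one).
#' @return Numeric dose-difference values.
#' @export
dequantize_image <- function(pixels, window = 5) {
  if (inherits(pixels, "dose_diff_image")) {
    window <- pixels$window
    pixels <- pixels$pixels
  }
  (pixels - 128) * window / 127.5
}

#' Write a dose-difference image as an 8-bit grayscale PNG
#'
#' The PNG round-trip is lossless: [read_png_image()] returns the identical
#' integer pixel matrix.
#'
#' @param image A `dose_diff_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(image, path) {
  stopifnot(inherits(image, "dose_diff_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG written by [write_png_image()]
#'
#' @param path PNG file path.
#' @return Integer pixel matrix (0..255).
#' @export
read_png_image <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}
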