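# Augmentation operators for 8-bit dose-difference images. The error-free
# class is far smaller than the error classes (1 vs 2 x |magnitudes|
# variants per arc/plane), so its training images are expanded with a menu
# of label-preserving transforms: horizontal flip, resize + center crop, and
# random erasing (rectangle filled with the mid-gray zero-difference value).

#' Horizontal flip of an image matrix (involution).
#' @param px Integer pixel matrix.
#' @return Flipped matrix.
#' @export
img_flip <- function(px) px[nrow(px):1, , drop = FALSE]

#' Resize by a scale factor, then center-crop (or mid-gray-pad) back to the
#' original size.
#' @param px Integer pixel matrix (0..255).
#' @param scale Resize factor (e.g. 0.9 to 1.1).
#' @param fill Pad value for scales below 1 (default 128 = zero difference).
#' @return Integer matrix of the original size.
#' @export
img_resize_crop <- function(px, scale, fill = 128L) {
  n <- nrow(px)
  m <- max(2L, round(n * scale))
  r <- EBImage::resize(px / 255, w = m, h = m)
  r <- matrix(as.integer(pmin(pmax(round(r * 255), 0), 255)), m, m)
  out <- matrix(as.integer(fill), n, n)
  if (m >= n) {
    o <- (m - n) %/% 2
    out[, ] <- r[(o + 1):(o + n), (o + 1):(o + n)]
  } else {
    o <- (n - m) %/% 2
    out[(o + 1):(o + m), (o + 1):(o + m)] <- r
  }
  out
}

#' Erase one random rectangle (2-10% of the area) with a fill value.
#' @param px Integer pixel matrix.
#' @param area_range Fraction-of-area range of the erased rectangle.
#' @param fill Fill value (default 128 = zero difference).
#' @return Integer matrix with exactly one rectangular region replaced.
#' @export
img_random_erase <- function(px, area_range = c(0.02, 0.10), fill = 128L) {
  n <- nrow(px); m <- ncol(px)
  area <- stats::runif(1, area_range[1], area_range[2]) * n * m
  ar <- stats::runif(1, 0.5, 2)
  h <- max(1L, min(n, round(sqrt(area * ar))))
  w <- max(1L, min(m, round(sqrt(area / ar))))
  i <- sample.int(n - h + 1L, 1)
  j <- sample.int(m - w + 1L, 1)
  px[i:(i + h - 1L), j:(j + w - 1L)] <- as.integer(fill)
  px
}

#' Augment the error-free training images
#'
#' Expands a list of images by an integer `factor`: the first replicate of
#' each image is the original, the rest are drawn from the transform menu
#' (random flip, resize 0.9-1.1 + center crop, random erasing), each applied
#' with an independent seeded draw. Must only be applied to training images:
#' passing any test-split image is an error.
#'
#' @param images List of integer pixel matrices.
#' @param factor Expansion factor, `>= 1`.
#' @param seed Integer seed (deterministic output).
#' @param split Optional character vector of split labels parallel to
#'   `images`; any `"test"` entry raises an error.
#' @return List of `length(images) * factor` pixel matrices.
#' @export
augment_error_free <- function(images, factor, seed = 1, split = NULL) {
  if (factor < 1)
    stop_named("vmatqa_invalid_augmentation", "factor must be >= 1")
  if (!is.null(split) && any(split == "test"))
    stop_named("vmatqa_augment_test_split",
               "augmentation must not be applied to the test split")
  set.seed(seed)
  out <- vector("list", length(images) * factor)
  pos <- 1L
  for (img in images) {
    out[[pos]] <- img; pos <- pos + 1L
    if (factor > 1) for (k in seq_len(factor - 1)) {
      a <- img
      if (stats::runif(1) < 0.5) a <- img_flip(a)
      a <- img_resize_crop(a, stats::runif(1, 0.9, 1.1))
      if (stats::runif(1) < 0.5) a <- img_random_erase(a)
      out[[pos]] <- a; pos <- pos + 1L
    }
  }
  out
}
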