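# Internal numeric helpers shared by the dose engine, measurement pipeline
# and gamma analysis.

#' @keywords internal
#' @noRd
reflect_pad <- function(m, pad) {
  if (pad < 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(pad < nr, pad < nc)
  # symmetric (half-sample) reflection: edge row/col is duplicated
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1))
  m[ri, ci]
}

#' Bilinear sampling of a matrix on a uniform grid.
#'
#' `values` is indexed \[i, j\] with row coordinate `x0 + (i-1)*dx` and column
#' coordinate `y0 + (j-1)*dy`. Points outside the grid get `outside`.
#' @keywords internal
#' @noRd
bilinear_sample <- function(values, x, y, x0, y0, dx, dy, outside = NA_real_) {
  gi <- (x - x0) / dx + 1
  gj <- (y - y0) / dy + 1
  nr <- nrow(values); nc <- ncol(values)
  i0 <- floor(gi); j0 <- floor(gj)
  wi <- gi - i0;   wj <- gj - j0
  # clamp exact upper-edge hits into the last cell
  hit_i <- i0 == nr & wi == 0; i0[hit_i] <- nr - 1L; wi[hit_i] <- 1
  hit_j <- j0 == nc & wj == 0; j0[hit_j] <- nc - 1L; wj[hit_j] <- 1
  ok <- i0 >= 1 & i0 <= nr - 1 & j0 >= 1 & j0 <= nc - 1
  out <- rep(outside, length(gi))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; wik <- wi[ok]; wjk <- wj[ok]
    base <- (j0k - 1L) * nr + i0k
    v <- values
    out[ok] <- v[base]            * (1 - wik) * (1 - wjk) +
               v[base + 1L]       * wik       * (1 - wjk) +
               v[base + nr]       * (1 - wik) * wjk +
               v[base + nr + 1L]  * wik       * wjk
  }
  out
}

#' Mean-pool a square matrix by an integer factor.
#' @keywords internal
#' @noRd
pool_mean <- function(m, factor) {
  n <- nrow(m)
  stopifnot(n %% factor == 0, ncol(m) == n)
  nn <- n %/% factor
  out <- matrix(0, nn, nn)
  for (a in seq_len(factor)) {
    rows <- seq(a, n, by = factor)
    for (b in seq_len(factor)) {
      out <- out + m[rows, seq(b, n, by = factor)]
    }
  }
  out / (factor * factor)
}

# Bilinear resampling onto the fixed image lattice. The gather indices and
# weights depend only on the grid geometry, so they are cached across calls
# (every map of a dataset shares one geometry).
.resample_cache <- new.env(parent = emptyenv())

#' @keywords internal
#' @noRd
resample_to_lattice <- function(v, coord0, spacing, size, pixel_spacing) {
  key <- paste(nrow(v), ncol(v), coord0, spacing, size, pixel_spacing)
  cache <- .resample_cache[[key]]
  if (is.null(cache)) {
    target <- (seq_len(size) - (size + 1) / 2) * pixel_spacing
    xs <- rep(target, times = size)
    ys <- rep(target, each = size)
    gi <- (xs - coord0) / spacing + 1
    gj <- (ys - coord0) / spacing + 1
    i0 <- floor(gi); j0 <- floor(gj)
    wi <- gi - i0;   wj <- gj - j0
    nr <- nrow(v)
    ok <- i0 >= 1 & i0 <= nr - 1 & j0 >= 1 & j0 <= ncol(v) - 1
    base <- (j0 - 1L) * nr + i0
    cache <- list(ok = ok, base = base[ok],
                  w00 = ((1 - wi) * (1 - wj))[ok], w10 = (wi * (1 - wj))[ok],
                  w01 = ((1 - wi) * wj)[ok], w11 = (wi * wj)[ok], nr = nr)
    .resample_cache[[key]] <- cache
  }
  out <- numeric(size * size)
  b <- cache$base; nr <- cache$nr
  out[cache$ok] <- v[b] * cache$w00 + v[b + 1L] * cache$w10 +
    v[b + nr] * cache$w01 + v[b + nr + 1L] * cache$w11
  out
}

#' @keywords internal
#' @noRd
stop_named <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Smooth a vector (or each column of a matrix) with a periodic moving
#' Gaussian; used by the arc-plan generator for leaf trajectories.
#' @keywords internal
#' @noRd
smooth_periodic <- function(x, sigma) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (sigma <= 0 || n < 3) return(x)
  half <- min(floor(n / 2), ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  idx <- outer(seq_len(n), (-half):half, function(i, d) ((i + d - 1) %% n) + 1)
  if (is.matrix(x)) {
    apply(x, 2, function(col) {
      colSums(matrix(col[t(idx)], nrow = 2 * half + 1) * k)
    })
  } else {
    colSums(matrix(x[t(idx)], nrow = 2 * half + 1) * k)
  }
}
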