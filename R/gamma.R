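#' Gamma-analysis acceptance criteria
#'
#' Dose difference (DD, percent), distance to agreement (DTA, mm), DD
#' normalization (global: percent of the reference maximum; local: percent
#' of the reference dose at each point) and the lower dose cutoff (points
#' with reference dose below `dose_threshold_percent` of the maximum are
#' excluded from the analysis).
#'
#' @param dd_percent Dose-difference tolerance in percent (`> 0`).
#' @param dta_mm Distance-to-agreement tolerance in mm (`> 0`).
#' @param normalization `"global"` or `"local"`.
#' @param dose_threshold_percent Lower dose cutoff in percent of the
#'   reference maximum (default 10).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dd_percent, dta_mm,
                           normalization = c("global", "local"),
                           dose_threshold_percent = 10) {
  normalization <- match.arg(normalization)
  if (dd_percent <= 0 || dta_mm <= 0)
    stop_named("vmatqa_invalid_criteria", "dd_percent and dta_mm must be > 0")
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm,
                 normalization = normalization,
                 dose_threshold_percent = dose_threshold_percent),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %s %g%%/%g mm (threshold %g%%)\n",
              x$normalization, x$dd_percent, x$dta_mm,
              x$dose_threshold_percent))
  invisible(x)
}

#' The six study criteria: global and local 2%/2mm, 1%/1mm, 1%/0.5mm.
#' @return Named list of [gamma_criteria()].
#' @export
standard_gamma_criteria <- function() {
  out <- list()
  for (norm in c("global", "local"))
    for (c2 in list(c(2, 2), c(1, 1), c(1, 0.5)))
      out[[sprintf("%s_%g_%g", norm, c2[1], c2[2])]] <-
        gamma_criteria(c2[1], c2[2], norm)
  out
}

# Shared search core: one reference/evaluated pair, one DTA, several DD
# tolerances evaluated simultaneously. The evaluated map is sampled on a
# bilinear-interpolated lattice of pitch `step_mm` within `radius_mm` of each
# analyzed reference pixel; offsets are visited in order of increasing
# distance, and a pixel leaves the active set once its current best gamma^2
# (over all criteria) cannot be improved by any farther offset.
#' @keywords internal
#' @noRd
gamma_search <- function(ref, ev, spacing, mask_idx, dta, dd_abs_list,
                         step, radius) {
  nr <- nrow(ref); nc <- ncol(ref)
  ii <- ((mask_idx - 1L) %% nr) + 1L
  jj <- ((mask_idx - 1L) %/% nr) + 1L
  rv <- ref[mask_idx]
  ncrit <- length(dd_abs_list)

  ks <- seq(-floor(radius / step), floor(radius / step))
  off <- expand.grid(ox = ks * step, oy = ks * step)
  d2 <- off$ox^2 + off$oy^2
  keep <- d2 <= radius^2 + 1e-9
  off <- off[keep, ]; d2 <- d2[keep]
  ord <- order(d2)
  off <- off[ord, ]; d2n <- d2[ord] / dta^2

  g2 <- matrix(Inf, length(mask_idx), ncrit)
  gmax <- rep(Inf, length(mask_idx))
  for (k in seq_along(d2n)) {
    act <- which(gmax > d2n[k])
    if (!length(act)) break
    gi <- ii[act] + off$ox[k] / spacing
    gj <- jj[act] + off$oy[k] / spacing
    # absorb float fuzz at the grid edges, then fold exact upper-edge hits
    # into the last cell
    eps <- 1e-9
    gi[abs(gi - nr) < eps] <- nr; gi[abs(gi - 1) < eps] <- 1
    gj[abs(gj - nc) < eps] <- nc; gj[abs(gj - 1) < eps] <- 1
    i0 <- floor(gi); j0 <- floor(gj)
    wi <- gi - i0;   wj <- gj - j0
    hit_i <- i0 == nr & wi == 0; i0[hit_i] <- nr - 1L; wi[hit_i] <- 1
    hit_j <- j0 == nc & wj == 0; j0[hit_j] <- nc - 1L; wj[hit_j] <- 1
    ok <- i0 >= 1 & i0 <= nr - 1 & j0 >= 1 & j0 <= nc - 1
    if (!any(ok)) next
    a <- act[ok]
    base <- (j0[ok] - 1L) * nr + i0[ok]
    evv <- ev[base] * (1 - wi[ok]) * (1 - wj[ok]) +
           ev[base + 1L] * wi[ok] * (1 - wj[ok]) +
           ev[base + nr] * (1 - wi[ok]) * wj[ok] +
           ev[base + nr + 1L] * wi[ok] * wj[ok]
    dd <- evv - rv[a]
    for (c in seq_len(ncrit)) {
      tol <- dd_abs_list[[c]]
      tolv <- if (length(tol) == 1) tol else tol[a]
      g2[a, c] <- pmin(g2[a, c], d2n[k] + (dd / tolv)^2)
    }
    gmax[a] <- if (ncrit == 1) g2[a, 1] else do.call(pmax, lapply(seq_len(ncrit), function(c) g2[a, c]))
  }
  sqrt(g2)
}

#' 2D gamma index between a reference and an evaluated dose map
#'
#' For every analyzed reference point `p`,
#' `gamma(p) = min_r sqrt( (De(r) - Dr(p))^2 / DD^2 + |r - p|^2 / DTA^2 )`
#' over evaluated positions `r` on a sub-pixel bilinear lattice of pitch
#' `step_mm` (default `DTA/10`) within `radius_factor * DTA` of `p`. DD
#' normalization uses the reference global maximum (global) or the reference
#' dose at `p` (local). Points below the dose threshold are excluded from
#' the passing-rate denominator.
#'
#' @param reference,evaluated [dose_map()] objects on identical grids
#'   (typically: mimicked measured map as reference, calculated map with a
#'   candidate modeling error as evaluated).
#' @param criteria A [gamma_criteria()].
#' @param step_mm Search lattice pitch (default `dta_mm / 10`). Setting
#'   `step_mm = spacing_mm` restricts the search to the native grid.
#' @param radius_factor Search radius in units of DTA (default 3).
#' @return An object of class `gamma_result`: `gamma` matrix (NA outside the
#'   analyzed region), `passing_rate` in percent, `n_analyzed`, `criteria`.
#' @export
gamma_map <- function(reference, evaluated, criteria,
                      step_mm = NULL, radius_factor = 3) {
  res <- gamma_map_multi(reference, evaluated, list(criteria),
                         step_mm = step_mm, radius_factor = radius_factor)
  res[[1]]
}

#' Gamma index for several criteria sharing one map pair
#'
#' Criteria with equal DTA share one distance search; use this to evaluate
#' the full study criteria set efficiently.
#'
#' @inheritParams gamma_map
#' @param criteria_list List of [gamma_criteria()].
#' @return List of `gamma_result`, same order/names as `criteria_list`.
#' @export
gamma_map_multi <- function(reference, evaluated, criteria_list,
                            step_mm = NULL, radius_factor = 3) {
  stopifnot(inherits(reference, "dose_map"), inherits(evaluated, "dose_map"))
  if (!identical(dim(reference$values), dim(evaluated$values)) ||
      reference$spacing_mm != evaluated$spacing_mm)
    stop_named("vmatqa_grid_mismatch", "reference and evaluated grids differ")
  ref <- reference$values
  mx <- max(ref)
  if (mx <= 0)
    stop_named("vmatqa_zero_reference", "reference maximum must be > 0")

  n <- length(criteria_list)
  results <- vector("list", n)
  names(results) <- names(criteria_list)
  dtas <- vapply(criteria_list, `[[`, numeric(1), "dta_mm")
  for (dta in unique(dtas)) {
    sel <- which(dtas == dta)
    thr <- vapply(criteria_list[sel], `[[`, numeric(1), "dose_threshold_percent")
    if (length(unique(thr)) != 1)
      stop_named("vmatqa_invalid_criteria",
                 "criteria sharing a DTA must share the dose threshold")
    mask_idx <- which(ref >= thr[1] / 100 * mx)
    step <- if (is.null(step_mm)) dta / 10 else step_mm
    dd_abs <- lapply(criteria_list[sel], function(cr) {
      if (cr$normalization == "global") cr$dd_percent / 100 * mx
      else cr$dd_percent / 100 * ref[mask_idx]
    })
    g <- gamma_search(ref, evaluated$values, reference$spacing_mm, mask_idx,
                      dta, dd_abs, step, radius_factor * dta)
    for (k in seq_along(sel)) {
      gm <- matrix(NA_real_, nrow(ref), ncol(ref))
      gm[mask_idx] <- g[, k]
      results[[sel[k]]] <- structure(
        list(gamma = gm,
             passing_rate = 100 * mean(g[, k] <= 1),
             n_analyzed = length(mask_idx),
             criteria = criteria_list[[sel[k]]]),
        class = "gamma_result")
    }
  }
  results
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s %g%%/%g mm: passing rate %.2f%% (%d points)\n",
              x$criteria$normalization, x$criteria$dd_percent,
              x$criteria$dta_mm, x$passing_rate, x$n_analyzed))
  invisible(x)
}
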