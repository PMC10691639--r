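#' MLC control point
#'
#' One discrete machine state along a VMAT arc: the left and right leaf-bank
#' tip coordinates (mm, along the leaf-travel axis) for every leaf pair, the
#' gantry angle, and the fractional meterset weight delivered at that state.
#'
#' @param left_positions_mm,right_positions_mm Numeric vectors, one entry per
#'   leaf pair; `left <= right` pairwise.
#' @param gantry_angle_deg Gantry angle in degrees.
#' @param mu_weight Nonnegative fractional meterset.
#' @return An object of class `control_point`.
#' @export
control_point <- function(left_positions_mm, right_positions_mm,
                          gantry_angle_deg, mu_weight) {
  if (length(left_positions_mm) != length(right_positions_mm))
    stop_named("vmatqa_invalid_control_point", "leaf banks differ in length")
  if (any(left_positions_mm > right_positions_mm + 1e-9))
    stop_named("vmatqa_invalid_control_point",
               "left leaf positions must not exceed right leaf positions")
  if (!is.numeric(mu_weight) || length(mu_weight) != 1 || mu_weight < 0)
    stop_named("vmatqa_invalid_control_point", "mu_weight must be >= 0")
  structure(list(left_positions_mm = as.numeric(left_positions_mm),
                 right_positions_mm = as.numeric(right_positions_mm),
                 gantry_angle_deg = as.numeric(gantry_angle_deg),
                 mu_weight = as.numeric(mu_weight)),
            class = "control_point")
}

#' VMAT arc plan
#'
#' An ordered sequence of MLC control points for one arc, plus the leaf
#' geometry. Two site classes are modeled: `prostate_like` plans have
#' compact, low-modulation apertures; `head_neck_like` plans have larger,
#' concave, strongly modulated apertures with steep dose gradients.
#'
#' @param plan_id Character identifier.
#' @param site `"prostate_like"` or `"head_neck_like"`.
#' @param control_points List of [control_point()] objects, length `>= 2`.
#' @param leaf_width_mm Leaf width (mm) projected at isocenter.
#' @param seed Integer seed the plan was generated from (metadata).
#' @return An object of class `arc_plan`.
#' @export
arc_plan <- function(plan_id, site, control_points, leaf_width_mm = 5, seed = NA) {
  if (!site %in% c("prostate_like", "head_neck_like"))
    stop_named("vmatqa_unknown_site",
               sprintf("unknown site label '%s'", site))
  if (length(control_points) < 2)
    stop_named("vmatqa_invalid_plan", "an arc needs at least 2 control points")
  if (sum(vapply(control_points, `[[`, numeric(1), "mu_weight")) <= 0)
    stop_named("vmatqa_invalid_plan", "total meterset must be positive")
  structure(list(plan_id = plan_id, site = site,
                 control_points = control_points,
                 leaf_width_mm = leaf_width_mm, seed = seed),
            class = "arc_plan")
}

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf("<arc_plan> %s (%s): %d control points, %d leaf pairs, leaf width %.1f mm\n",
              x$plan_id, x$site, length(x$control_points),
              length(x$control_points[[1]]$left_positions_mm), x$leaf_width_mm))
  invisible(x)
}

#' Generate a synthetic VMAT-like arc plan
#'
#' Stand-in for a clinical plan cohort: leaf apertures follow a site-specific
#' target outline (an ellipse for `prostate_like`; a larger, concave
#' multi-lobe outline for `head_neck_like`) whose projected half-widths drive
#' each leaf pair, modulated by per-leaf smoothed random walks over the arc.
#' Head-and-neck-like plans receive stronger leaf modulation, producing a
#' strictly higher mean aperture irregularity (perimeter^2 / area) than
#' prostate-like plans at the same settings.
#'
#' The generator is fully reproducible for a fixed `seed`.
#'
#' @param site `"prostate_like"` or `"head_neck_like"`.
#' @param n_control_points Number of control points over the 360 degree arc
#'   (default 90).
#' @param seed Integer seed.
#' @param leaf_width_mm Leaf width (mm); the MLC geometry of the simulated
#'   machine is a free parameter of the generator, not a commissioning value.
#' @param n_leaf_pairs Number of leaf pairs; the bank is centered on the
#'   isocenter and must cover the dose grid.
#' @param plan_id Optional identifier (default derived from site and seed).
#' @return An [arc_plan()].
#' @examples
#' p <- generate_arc_plan("prostate_like", 90, seed = 7)
#' length(p$control_points)
#' @export
generate_arc_plan <- function(site = c("prostate_like", "head_neck_like"),
                              n_control_points = 90, seed = 1,
                              leaf_width_mm = 5, n_leaf_pairs = 33,
                              plan_id = NULL) {
  if (length(site) == 1 && !site %in% c("prostate_like", "head_neck_like"))
    stop_named("vmatqa_unknown_site", sprintf("unknown site label '%s'", site))
  site <- match.arg(site)
  if (n_control_points < 2)
    stop_named("vmatqa_invalid_plan", "n_control_points must be >= 2")
  if (is.null(plan_id))
    plan_id <- sprintf("%s_seed%03d", abbreviate(site, 4), seed)

  set.seed(seed)

  # leaf-pair band centers along the superior-inferior axis
  centers <- (seq_len(n_leaf_pairs) - (n_leaf_pairs + 1) / 2) * leaf_width_mm
  n <- n_control_points
  gantry <- seq(0, 360, length.out = n + 1)[seq_len(n)]

  # site-specific target outline: half-width w(v) of the aperture at height v
  if (site == "prostate_like") {
    rx <- runif(1, 22, 30)          # mm, lateral semi-axis
    ry <- runif(1, 16, 24)          # mm, superior-inferior semi-axis
    cy <- runif(1, -5, 5)
    half_width <- function(v) {
      rx * sqrt(pmax(1 - ((v - cy) / ry)^2, 0))
    }
    walk_sd <- 0.35                 # mm per control point, leaf modulation
    center_amp <- runif(1, 3, 8)    # aperture-center sway over the arc
  } else {
    r0 <- runif(1, 30, 42)
    ph <- runif(4, 0, 2 * pi)
    am <- runif(4, 4, 11)           # multi-lobe amplitudes -> concave outline
    cy <- runif(1, -8, 8)
    half_width <- function(v) {
      # widest lateral extent of the lobed polar outline near each leaf band:
      # outline point at polar angle phi is (r(phi) sin phi, r(phi) cos phi)
      phi <- seq(0, pi, length.out = 121)
      r_phi <- r0 + rowSums(do.call(cbind, lapply(seq_along(am), function(k)
        am[k] * cos((k + 1) * phi + ph[k]))))
      y_pts <- r_phi * cos(phi)
      x_pts <- abs(r_phi * sin(phi))
      vapply(v - cy, function(h) {
        sel <- abs(y_pts - h) <= 6
        if (!any(sel)) 0 else max(x_pts[sel])
      }, numeric(1))
    }
    walk_sd <- 2.2
    center_amp <- runif(1, 6, 14)
  }

  w0 <- half_width(centers)                       # static half-width per pair
  open <- w0 > 0.5                                # pairs that ever open
  cx <- center_amp * sin(2 * pi * seq_len(n) / n + runif(1, 0, 2 * pi))
  scale_t <- 1 + 0.15 * sin(4 * pi * seq_len(n) / n + runif(1, 0, 2 * pi))

  # per-leaf smoothed random walks (n x pairs), periodic over the arc
  noise_l <- smooth_periodic(apply(matrix(stats::rnorm(n * n_leaf_pairs, 0, walk_sd),
                                          n, n_leaf_pairs), 2, cumsum), 4)
  noise_r <- smooth_periodic(apply(matrix(stats::rnorm(n * n_leaf_pairs, 0, walk_sd),
                                          n, n_leaf_pairs), 2, cumsum), 4)
  noise_l <- sweep(noise_l, 2, colMeans(noise_l))
  noise_r <- sweep(noise_r, 2, colMeans(noise_r))

  mu_raw <- smooth_periodic(abs(stats::rnorm(n, 1, 0.3)) + 0.2, 3)
  mu_w <- mu_raw / sum(mu_raw)

  lim <- 60   # leaves never open beyond +/-60 mm (<= 12 cm field)
  park <- -70 # closed pairs park off-field so the DLG slit stays out of the target
  cps <- vector("list", n)
  for (t in seq_len(n)) {
    w_t <- w0 * scale_t[t]
    l <- ifelse(open, cx[t] - w_t + noise_l[t, ], park)
    r <- ifelse(open, cx[t] + w_t + noise_r[t, ], park)
    l[open] <- pmax(pmin(l[open], lim), -lim)
    r[open] <- pmax(pmin(r[open], lim), -lim)
    bad <- l > r
    if (any(bad)) { mid <- (l[bad] + r[bad]) / 2; l[bad] <- mid; r[bad] <- mid }
    cps[[t]] <- control_point(l, r, gantry[t], mu_w[t])
  }
  arc_plan(plan_id, site, cps, leaf_width_mm = leaf_width_mm, seed = seed)
}

#' Aperture irregularity of an arc plan
#'
#' Mean over control points of perimeter^2 / area of the beam aperture
#' (the union of open leaf-pair rectangles). Complex, concave apertures with
#' strong leaf-to-leaf modulation score high; compact elliptical apertures
#' score near the 4*pi*... rectangle baseline. Used to verify that the two
#' site classes of the generator are separated in modulation complexity.
#'
#' @param plan An [arc_plan()].
#' @param min_gap_mm Leaf gaps below this are treated as closed.
#' @return Mean aperture irregularity (dimensionless).
#' @export
aperture_irregularity <- function(plan, min_gap_mm = 0.5) {
  stopifnot(inherits(plan, "arc_plan"))
  lw <- plan$leaf_width_mm
  vals <- vapply(plan$control_points, function(cp) {
    w <- cp$right_positions_mm - cp$left_positions_mm
    open <- w > min_gap_mm
    if (!any(open)) return(NA_real_)
    area <- sum(w[open]) * lw
    l <- ifelse(open, cp$left_positions_mm, NA)
    r <- ifelse(open, cp$right_positions_mm, NA)
    per <- 0
    npair <- length(w)
    prev_l <- NA; prev_r <- NA
    for (i in seq_len(npair)) {
      if (open[i]) {
        per <- per + 2 * lw  # left and right vertical edges of this band
        if (!is.na(prev_l)) {
          per <- per + abs(l[i] - prev_l) + abs(r[i] - prev_r)
        } else {
          per <- per + w[i]  # bottom cap
        }
        prev_l <- l[i]; prev_r <- r[i]
      } else if (!is.na(prev_l)) {
        per <- per + (prev_r - prev_l)  # top cap of the finished block
        prev_l <- NA; prev_r <- NA
      }
    }
    if (!is.na(prev_l)) per <- per + (prev_r - prev_l)
    per^2 / area
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
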