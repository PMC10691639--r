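#' Phantom and dose-grid specification
#'
#' A homogeneous cylindrical phantom (axis along the superior-inferior
#' direction) with a voxel-centered cubic dose grid centered on the
#' isocenter. The default grid (81^3 voxels at 2.0 mm pitch, 161 mm extent)
#' covers all nine extraction planes and fields up to 12 cm; the odd voxel
#' count puts the isocenter exactly on a voxel center.
#'
#' @param diameter_mm Cylinder diameter (default 220 mm).
#' @param length_mm Cylinder length (default 400 mm; the grid is shorter).
#' @param grid_spacing_mm Voxel pitch (default 2.0 mm).
#' @param n_voxels Voxels per axis (odd; default 81).
#' @return An object of class `phantom_spec` with voxel-center coordinates in
#'   `$coords` (mm, isocenter at 0).
#' @export
phantom_spec <- function(diameter_mm = 220, length_mm = 400,
                         grid_spacing_mm = 2.0, n_voxels = 81) {
  if (grid_spacing_mm <= 0)
    stop_named("vmatqa_invalid_phantom", "grid spacing must be > 0")
  if (n_voxels %% 2 == 0)
    stop_named("vmatqa_invalid_phantom", "n_voxels must be odd")
  coords <- (seq_len(n_voxels) - (n_voxels + 1) / 2) * grid_spacing_mm
  if (max(coords) < 20)
    stop_named("vmatqa_invalid_phantom", "grid must cover all extraction planes")
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm,
                 grid_spacing_mm = grid_spacing_mm, n_voxels = n_voxels,
                 coords = coords),
            class = "phantom_spec")
}

#' @keywords internal
#' @noRd
dose_volume <- function(values, spacing_mm, coords, plan_id,
                        label = beam_label(), site = NA_character_) {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(values = values, spacing_mm = spacing_mm, coords = coords,
                 plan_id = plan_id, beam_label = label, site = site),
            class = "dose_volume")
}

#' Planar dose map constructor
#'
#' Scalar dose on a regular 2D grid with plane orientation and signed offset
#' from the isocenter (superior / anterior / patient-left positive).
#'
#' @param values Numeric matrix of nonnegative dose (percent-of-maximum
#'   units after normalization).
#' @param spacing_mm Grid pitch (mm).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param offset_mm Signed offset of the plane from the isocenter.
#' @param plan_id Plan identifier.
#' @param label Beam label (error class) of the calculation.
#' @param site Site class of the plan.
#' @param coords Voxel-center coordinates along both in-plane axes.
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(values, spacing_mm, plane, offset_mm, plan_id,
                     label = beam_label(), site = NA_character_,
                     coords = NULL) {
  stopifnot(plane %in% c("axial", "coronal", "sagittal"))
  if (!all(is.finite(values)) || any(values < 0))
    stop_named("vmatqa_invalid_dose", "dose values must be finite and >= 0")
  if (is.null(coords))
    coords <- (seq_len(nrow(values)) - (nrow(values) + 1) / 2) * spacing_mm
  structure(list(values = values, spacing_mm = spacing_mm, plane = plane,
                 offset_mm = offset_mm, plan_id = plan_id,
                 beam_label = label, site = site, coords = coords),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %s %+g mm, %dx%d @ %.1f mm, plan %s, class %s\n",
              x$plane, x$offset_mm, nrow(x$values), ncol(x$values),
              x$spacing_mm, x$plan_id, x$beam_label$error_type))
  invisible(x)
}

#' Fluence map of one control point
#'
#' The idealized in-air fluence behind the MLC: 1 inside the aperture, `tf`
#' under the leaves, with each leaf-pair opening widened by the dosimetric
#' leaf gap (`dlg_mm / 2` per leaf tip) along the leaf-travel axis before
#' rasterization. Aperture edges are anti-aliased by area-weighted coverage
#' of boundary cells, so sub-grid DLG changes alter the fluence.
#'
#' @param cp A [control_point()].
#' @param beam A [beam_model()].
#' @param grid List with `u` (leaf-travel axis cell centers, mm), `v`
#'   (leaf-stacking axis cell centers, mm) and `spacing_mm`; defaults to the
#'   grid of `phantom` if given.
#' @param leaf_width_mm Leaf width (mm).
#' @return Matrix indexed `[u, v]` with values in `[min(tf, 1), 1]`.
#' @export
control_point_fluence <- function(cp, beam, grid, leaf_width_mm = 5) {
  stopifnot(inherits(cp, "control_point"), inherits(beam, "beam_model"))
  if (grid$spacing_mm <= 0)
    stop_named("vmatqa_invalid_grid", "grid spacing must be > 0")
  u <- grid$u; v <- grid$v; h <- grid$spacing_mm
  npair <- length(cp$left_positions_mm)
  centers <- (seq_len(npair) - (npair + 1) / 2) * leaf_width_mm
  lo_u <- u - h / 2; hi_u <- u + h / 2
  lo_v <- v - h / 2; hi_v <- v + h / 2
  open_frac <- matrix(0, length(u), length(v))
  half_dlg <- beam$dlg_mm / 2
  for (i in seq_len(npair)) {
    l <- cp$left_positions_mm[i] - half_dlg
    r <- cp$right_positions_mm[i] + half_dlg
    if (r <= l) next
    cov_u <- pmax(0, pmin(r, hi_u) - pmax(l, lo_u)) / h
    if (all(cov_u == 0)) next
    b_lo <- centers[i] - leaf_width_mm / 2
    b_hi <- centers[i] + leaf_width_mm / 2
    cov_v <- pmax(0, pmin(b_hi, hi_v) - pmax(b_lo, lo_v)) / h
    sel <- which(cov_v > 0)
    if (length(sel))
      open_frac[, sel] <- open_frac[, sel] + outer(cov_u, cov_v[sel])
  }
  open_frac <- pmin(open_frac, 1)
  beam$tf + (1 - beam$tf) * open_frac
}

#' Accumulate the dose of one arc in the cylindrical phantom
#'
#' Simplified dose engine: per control point the MLC fluence (with TF and
#' DLG applied, blurred laterally by the penumbra Gaussian) is projected as a
#' parallel beam along the gantry direction with exponential attenuation
#' `exp(-mu * depth)` from the cylinder surface, weighted by the control
#' point's meterset, and summed over the arc. Dose is linear in the meterset
#' weights; voxels outside the cylinder receive zero.
#'
#' @param plan An [arc_plan()].
#' @param beam A [beam_model()].
#' @param phantom A [phantom_spec()].
#' @param scale Optional multiplicative normalization factor applied to the
#'   summed dose (use the error-free volume's `100 / max` so that error
#'   volumes share the error-free normalization).
#' @return A `dose_volume` with values indexed `[x, y, z]`
#'   (x = patient left, y = superior, z = anterior).
#' @export
accumulate_arc_dose <- function(plan, beam, phantom = phantom_spec(),
                                scale = NULL) {
  stopifnot(inherits(plan, "arc_plan"), inherits(beam, "beam_model"),
            inherits(phantom, "phantom_spec"))
  coords <- phantom$coords
  h <- phantom$grid_spacing_mm
  nv <- phantom$n_voxels
  R <- phantom$diameter_mm / 2

  # field containment: widened apertures must fit the fluence grid
  half_dlg <- beam$dlg_mm / 2
  ext <- range(coords) + c(-h, h) / 2
  for (cp in plan$control_points) {
    w <- cp$right_positions_mm - cp$left_positions_mm
    op <- w > 0 | half_dlg > 0
    if (any(op)) {
      if (min(cp$left_positions_mm[op]) - half_dlg < ext[1] ||
          max(cp$right_positions_mm[op]) + half_dlg > ext[2])
        stop_named("vmatqa_field_outside_grid",
                   "projected field extends beyond the dose grid")
    }
  }

  grid <- list(u = coords, v = coords, spacing_mm = h)
  sigma_px <- beam$penumbra_sigma_mm / h

  ncp <- length(plan$control_points)
  fstack <- array(0, c(nv, nv, ncp))
  for (k in seq_len(ncp)) {
    cp <- plan$control_points[[k]]
    if (cp$mu_weight == 0) next
    f <- control_point_fluence(cp, beam, grid, plan$leaf_width_mm)
    if (sigma_px > 1e-3) {
      pad <- 2 * ceiling(3 * sigma_px) + 2
      f <- EBImage::gblur(reflect_pad(f, pad), sigma = sigma_px)
      f <- f[(pad + 1):(pad + nv), (pad + 1):(pad + nv)]
    }
    fstack[, , k] <- f
  }
  angles <- vapply(plan$control_points, `[[`, numeric(1), "gantry_angle_deg") * pi / 180
  weights <- vapply(plan$control_points, `[[`, numeric(1), "mu_weight")
  vol <- .arc_dose_kernel(fstack, coords, angles, weights, R, beam$mu_per_mm)
  if (!is.null(scale)) vol <- vol * scale
  dose_volume(vol, h, coords, plan$plan_id, site = plan$site)
}

#' @keywords internal
#' @noRd
slice_volume <- function(volume, axis, offset_mm) {
  coords <- volume$coords
  pos <- (offset_mm - coords[1]) / volume$spacing_mm + 1
  n <- length(coords)
  if (pos < 1 || pos > n)
    stop_named("vmatqa_offset_outside_grid",
               sprintf("plane offset %g mm outside the dose grid", offset_mm))
  i0 <- floor(pos); w <- pos - i0
  take <- function(i) switch(axis,
    x = volume$values[i, , ],
    y = volume$values[, i, ],
    z = volume$values[, , i])
  if (w < 1e-9) take(i0) else (1 - w) * take(i0) + w * take(min(i0 + 1, n))
}

#' Extract the nine planar dose maps of an arc
#'
#' Three axial planes (isocenter, 10 mm superior and inferior), three
#' coronal planes (isocenter, 15 mm anterior and posterior) and three
#' sagittal planes (isocenter, 15 mm left and right). The isocenter planes
#' equal the central slices of the volume; off-lattice offsets are linearly
#' interpolated between adjacent slices.
#'
#' @param volume A `dose_volume` from [accumulate_arc_dose()].
#' @param plan_id Plan identifier recorded in the maps (default: from the
#'   volume).
#' @param label Beam label recorded in the maps.
#' @return List of 9 [dose_map()] objects, named `axial_0`, `axial_+10`, ...
#' @export
extract_planes <- function(volume, plan_id = volume$plan_id,
                           label = volume$beam_label) {
  stopifnot(inherits(volume, "dose_volume"))
  spec <- list(
    axial    = c(0, +10, -10),   # perpendicular to superior-inferior (y)
    coronal  = c(0, +15, -15),   # perpendicular to anterior-posterior (z)
    sagittal = c(0, +15, -15)    # perpendicular to left-right (x)
  )
  axis_of <- c(axial = "y", coronal = "z", sagittal = "x")
  out <- list()
  for (plane in names(spec)) {
    for (off in spec[[plane]]) {
      vals <- slice_volume(volume, axis_of[[plane]], off)
      nm <- sprintf("%s_%+g", plane, off)
      out[[nm]] <- dose_map(vals, volume$spacing_mm, plane, off, plan_id,
                            label = label, site = volume$site,
                            coords = volume$coords)
    }
  }
  out
}
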