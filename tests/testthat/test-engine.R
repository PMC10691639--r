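test_that("control-point fluence handles the degenerate DLG and TF cases", {
  ph <- phantom_spec()
  grid <- list(u = ph$coords, v = ph$coords, spacing_mm = ph$grid_spacing_mm)
  cp <- square_plan(half_mm = 20)$control_points[[1]]

  b0 <- beam_model(dlg_mm = 0)
  f <- control_point_fluence(cp, b0, grid)
  inside <- abs(grid$u) <= 19 # cell centers strictly inside the aperture
  band <- abs(grid$v) <= 80   # leaf bank covers the grid
  expect_true(all(f[inside, band] == 1))
  outside <- abs(grid$u) >= 22
  expect_true(all(abs(f[outside, band] - b0$tf) < 1e-12))
  expect_true(all(f >= min(b0$tf, 1) & f <= 1))

  # closed leaves, zero transmission, zero DLG -> zero fluence
  bz <- beam_model(tf = 0, dlg_mm = 0)
  cpc <- closed_plan()$control_points[[1]]
  expect_true(all(control_point_fluence(cpc, bz, grid) == 0))
})

test_that("DLG widening adds the predicted integrated fluence", {
  ph <- phantom_spec()
  grid <- list(u = ph$coords, v = ph$coords, spacing_mm = ph$grid_spacing_mm)
  cp <- square_plan(half_mm = 20)$control_points[[1]]
  lw <- 5
  delta <- 1.2 # mm
  f0 <- control_point_fluence(cp, beam_model(dlg_mm = 0), grid, lw)
  f1 <- control_point_fluence(cp, beam_model(dlg_mm = delta), grid, lw)
  cell <- ph$grid_spacing_mm^2
  gained <- (sum(f1) - sum(f0)) * cell
  expected <- delta * 33 * lw * (1 - 0.0122)
  # tolerance: one grid cell of fluence per leaf tip
  expect_lt(abs(gained - expected), 2 * 33 * cell)
})

test_that("arc dose is linear in meterset and zero outside the cylinder", {
  ph <- phantom_spec()
  b <- beam_model()
  p0 <- square_plan(half_mm = 15, n_cp = 2, mu = c(0.4, 0.6))
  v1 <- accumulate_arc_dose(p0, b, ph)
  expect_true(all(v1$values >= 0))
  # corners of the grid lie outside the 110 mm cylinder radius
  expect_equal(v1$values[1, 41, 1], 0)
  expect_equal(v1$values[81, 41, 81], 0)

  p2 <- p0
  for (i in seq_along(p2$control_points))
    p2$control_points[[i]]$mu_weight <- 2 * p2$control_points[[i]]$mu_weight
  v2 <- accumulate_arc_dose(p2, b, ph)
  expect_equal(v2$values, 2 * v1$values, tolerance = 1e-12)

  # zero meterset everywhere -> all-zero volume (mutated past the constructor,
  # which rejects such plans up front)
  pz <- square_plan(n_cp = 2, mu = c(1, 1))
  for (i in 1:2) pz$control_points[[i]]$mu_weight <- 0
  expect_true(all(accumulate_arc_dose(pz, b, ph)$values == 0))
})

test_that("central-axis depth profile matches the closed form without blur", {
  ph <- phantom_spec()
  nb <- beam_model(penumbra_sigma_mm = 1e-7)
  vs <- accumulate_arc_dose(square_plan(half_mm = 20, gantry = 0), nb, ph)
  prof <- vs$values[41, 41, ] # central axis: x = y = 0, depth along z
  z <- ph$coords
  cf <- exp(-nb$mu_per_mm * (z + 110))
  expect_lt(max(abs(prof / prof[1] - cf / cf[1])), 1e-6)
})

test_that("oversized fields are rejected", {
  ph <- phantom_spec()
  big <- square_plan(half_mm = 85)
  expect_error(accumulate_arc_dose(big, beam_model(), ph),
               class = "vmatqa_field_outside_grid")
})

test_that("nine planes are extracted with the study's offsets", {
  ph <- phantom_spec()
  v <- accumulate_arc_dose(square_plan(half_mm = 20), beam_model(), ph)
  planes <- extract_planes(v)
  expect_length(planes, 9)
  got <- data.frame(plane = vapply(planes, `[[`, character(1), "plane"),
                    offset = vapply(planes, `[[`, numeric(1), "offset_mm"))
  expect_setequal(got$offset[got$plane == "axial"], c(0, 10, -10))
  expect_setequal(got$offset[got$plane == "coronal"], c(0, 15, -15))
  expect_setequal(got$offset[got$plane == "sagittal"], c(0, 15, -15))
  # isocenter planes equal the central slices
  expect_equal(planes[["axial_+0"]]$values, v$values[, 41, ])
  expect_equal(planes[["coronal_+0"]]$values, v$values[, , 41])
  expect_equal(planes[["sagittal_+0"]]$values, v$values[41, , ])
  small <- vmatqa:::dose_volume(array(1, c(11, 11, 11)), 2,
                                seq(-10, 10, by = 2), "t")
  expect_error(extract_planes(small), class = "vmatqa_offset_outside_grid")
})

test_that("dose responds monotonically (and where expected, linearly) to TF and DLG", {
  ph <- phantom_spec()
  # fully blocked plan: dose is pure transmission, linear in tf
  pc <- closed_plan()
  v1 <- accumulate_arc_dose(pc, beam_model(tf = 0.0122, dlg_mm = 0), ph)
  v2 <- accumulate_arc_dose(pc, beam_model(tf = 0.0244, dlg_mm = 0), ph)
  expect_equal(v2$values, 2 * v1$values, tolerance = 1e-9)

  # open plan: every blocked voxel's dose non-decreasing in tf
  p <- generate_arc_plan("prostate_like", 12, seed = 3)
  va <- accumulate_arc_dose(p, beam_model(tf = 0.0122), ph)
  vb <- accumulate_arc_dose(p, beam_model(tf = 0.0183), ph)
  expect_true(all(vb$values - va$values >= -1e-12))

  # integrated dose non-decreasing in DLG
  d1 <- accumulate_arc_dose(p, beam_model(dlg_mm = 0.704), ph)
  d2 <- accumulate_arc_dose(p, beam_model(dlg_mm = 0.88), ph)
  d3 <- accumulate_arc_dose(p, beam_model(dlg_mm = 1.144), ph)
  expect_lt(sum(d1$values), sum(d2$values))
  expect_lt(sum(d2$values), sum(d3$values))
})

test_that("a 0% perturbation reproduces the unperturbed volume bit-identically", {
  ph <- phantom_spec()
  p <- generate_arc_plan("head_neck_like", 8, seed = 5)
  b <- beam_model()
  v1 <- accumulate_arc_dose(p, b, ph)
  v2 <- accumulate_arc_dose(p, perturb_beam(b, "TF", 0), ph)
  expect_identical(v1$values, v2$values)
})
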