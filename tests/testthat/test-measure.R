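test_that("the measurement filters reduce to identity when disabled", {
  ph <- phantom_spec()
  m <- extract_planes(accumulate_arc_dose(
    generate_arc_plan("prostate_like", 8, seed = 1), beam_model(), ph))[["axial_+0"]]
  out <- mimic_measurement(m, measurement_model(sigma = 0, median_kernel = 1))
  expect_equal(out$values, m$values)
  # a spatially uniform map is a fixed point of both filters
  u <- flat_map(50, n = 41)
  for (s in c(0.5, 1.0)) {
    mu <- mimic_measurement(u, measurement_model(sigma = s))
    expect_equal(mu$values, u$values, tolerance = 1e-9)
  }
})

test_that("Gaussian filtering conserves dose away from the boundary", {
  # compact dose blob well inside the grid: total dose preserved to 0.1%
  n <- 61
  v <- matrix(0, n, n)
  v[25:37, 25:37] <- 100
  m <- dose_map(v, 2, "axial", 0, "blob")
  out <- mimic_measurement(m, measurement_model(sigma = 1.0, median_kernel = 1))
  expect_lt(abs(sum(out$values) - sum(v)) / sum(v), 0.001)
})

test_that("difference maps subtract elementwise and carry the error label", {
  ph <- phantom_spec()
  plan <- generate_arc_plan("prostate_like", 8, seed = 2)
  b <- beam_model()
  vol <- accumulate_arc_dose(plan, b, ph)
  vol$values <- vol$values * (100 / max(vol$values))
  planes <- extract_planes(vol)
  model <- measurement_model(sigma = 0.5)
  meas <- mimic_measurement(planes[["axial_+0"]], model)
  calc <- median_filter_map(planes[["axial_+0"]], model)

  d <- difference_map(meas, calc)
  expect_equal(d$values, meas$values - calc$values)
  expect_equal(d$beam_label$error_type, "error_free")
  expect_equal(d$sigma, 0.5)

  # measured == calculated -> all-zero difference
  d0 <- difference_map(calc, calc)
  expect_true(all(d0$values == 0))
  # antisymmetry
  d1 <- difference_map(meas, calc)
  d2 <- difference_map(calc, meas)
  expect_equal(d1$values, -d2$values)
  # grid mismatch rejected
  other <- extract_planes(vol)[["coronal_+0"]]
  expect_error(difference_map(meas, other), class = "vmatqa_grid_mismatch")
})

test_that("a positive TF error lowers the difference map under blocked regions", {
  ph <- phantom_spec()
  plan <- square_plan(half_mm = 15, gantry = 0)
  b <- beam_model()
  vol_ef <- accumulate_arc_dose(plan, b, ph)
  scale <- 100 / max(vol_ef$values)
  vol_ef$values <- vol_ef$values * scale
  vol_tf <- accumulate_arc_dose(plan, perturb_beam(b, "TF", 30), ph)
  vol_tf$values <- vol_tf$values * scale

  model <- measurement_model(sigma = 0.5)
  pk <- "coronal_+0" # beam at gantry 0 -> aperture projects onto x-y planes
  meas <- mimic_measurement(extract_planes(vol_ef)[[pk]], model)
  calc <- median_filter_map(extract_planes(vol_tf)[[pk]], model)
  d <- difference_map(meas, calc)
  blocked <- abs(ph$coords) > 30 # fully outside the 15 mm aperture + penumbra
  expect_lt(mean(d$values[blocked, ]), 0)
})

test_that("dose-difference histograms conserve counts and center on zero", {
  z <- matrix(0, 10, 10)
  h <- compute_ddh(z, n_bins = 11)
  expect_equal(sum(h$counts), 100)
  expect_equal(h$counts[6], 100) # all mass in the bin containing zero
  set.seed(1)
  r <- matrix(rnorm(400), 20, 20)
  h2 <- compute_ddh(r, n_bins = 51)
  expect_equal(sum(h2$counts), 400)
  expect_equal(h2$breaks[1], -h2$breaks[52])
  expect_error(compute_ddh(r, n_bins = 0), class = "vmatqa_invalid_ddh")
})

test_that("stronger blur contracts difference extremes and merges TF/DLG signatures", {
  ph <- phantom_spec()
  plan <- generate_arc_plan("head_neck_like", 16, seed = 4)
  b <- beam_model()
  vol_ef <- accumulate_arc_dose(plan, b, ph)
  scale <- 100 / max(vol_ef$values)
  vol_ef$values <- vol_ef$values * scale
  mk_planes <- function(bm) {
    v <- accumulate_arc_dose(plan, bm, ph); v$values <- v$values * scale
    extract_planes(v)
  }
  pl_ef <- extract_planes(vol_ef)
  pl_tf <- mk_planes(perturb_beam(b, "TF", 30))
  pl_dlg <- mk_planes(perturb_beam(b, "DLG", 30))

  diffs <- function(sigma) {
    model <- measurement_model(sigma = sigma)
    meas <- mimic_measurement(pl_ef[["axial_+0"]], model)
    list(tf = difference_map(meas, median_filter_map(pl_tf[["axial_+0"]], model)),
         dlg = difference_map(meas, median_filter_map(pl_dlg[["axial_+0"]], model)))
  }
  d05 <- diffs(0.5); d10 <- diffs(1.0)

  # smoothing contracts the extremes of the filtered map itself
  m05 <- mimic_measurement(pl_ef[["axial_+0"]], measurement_model(sigma = 0.5))
  m10 <- mimic_measurement(pl_ef[["axial_+0"]], measurement_model(sigma = 1.0))
  expect_lt(max(m10$values), max(m05$values))
  # smoothing a signed difference grid contracts its extremes too
  g <- vmatqa:::gaussian_filter_matrix
  expect_lt(max(abs(g(d05$tf$values, 1.0))), max(abs(d05$tf$values)))
  # and stronger measurement blur makes the TF and DLG histograms overlap more
  expect_gt(ddh_overlap(d10$tf, d10$dlg), ddh_overlap(d05$tf, d05$dlg))
})
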