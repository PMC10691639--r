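test_that("identical maps give zero gamma and a 100% passing rate", {
  pair <- random_map_pair(seed = 11)
  res <- gamma_map(pair$ref, pair$ref, gamma_criteria(2, 2, "global"))
  expect_true(all(res$gamma[!is.na(res$gamma)] == 0))
  expect_equal(res$passing_rate, 100)
  expect_error(gamma_map(flat_map(0), flat_map(0), gamma_criteria(2, 2)),
               class = "vmatqa_zero_reference")
  small <- flat_map(100, n = 11)
  expect_error(gamma_map(flat_map(100, n = 21), small, gamma_criteria(2, 2)),
               class = "vmatqa_grid_mismatch")
})

test_that("the single-hot-pixel case hits the dose-difference boundary", {
  ref <- flat_map(100, n = 21)
  evv <- ref
  evv$values[11, 11] <- 102
  cr <- gamma_criteria(2, 2, "global")
  # native-lattice search: the best candidates are the pixel itself
  # (dose term exactly at tolerance) and its neighbours (distance at
  # tolerance), both giving gamma exactly 1 -> passes at the boundary
  g_native <- gamma_map(ref, evv, cr, step_mm = 2)
  expect_equal(g_native$gamma[11, 11], 1.0, tolerance = 1e-12)
  expect_equal(g_native$passing_rate, 100)
  # sub-pixel interpolation finds the true 2D minimum of the interpolated
  # surface gamma^2(s,t) = (1-s)^2 (1-t)^2 + s^2 + t^2 (diagonal descent
  # toward a neighbouring pixel beats the pixel itself and the axis paths)
  cont <- optim(c(0.3, 0.3), function(p)
    (1 - p[1])^2 * (1 - p[2])^2 + p[1]^2 + p[2]^2,
    method = "L-BFGS-B", lower = 0, upper = 1)
  g_sub <- gamma_map(ref, evv, cr, step_mm = 0.2)
  expect_equal(g_sub$gamma[11, 11], sqrt(cont$value), tolerance = 3e-3)
  expect_lt(g_sub$gamma[11, 11], 1)
  expect_equal(g_sub$passing_rate, 100)
})

test_that("gamma equals an exhaustive brute-force search on random map pairs", {
  # 1%/1mm so that the implementation's DTA/10 search pitch coincides with
  # the oracle's 0.1 mm fine lattice
  for (seed in 1:3) {
    pair <- random_map_pair(n = 24, seed = seed, noise = 1.5)
    for (norm in c("global", "local")) {
      cr <- gamma_criteria(1, 1, norm)
      res <- gamma_map(pair$ref, pair$ev, cr)
      orc <- gamma_oracle(pair$ref, pair$ev, cr, step_mm = 0.1, radius_mm = 3)
      sel <- !is.na(orc)
      expect_lt(max(abs(res$gamma[sel] - orc[sel])), 1e-3)
    }
  }
})

test_that("passing rates respond monotonically to the criteria", {
  pair <- random_map_pair(n = 32, seed = 21, noise = 2.5)
  rate <- function(dd, dta, norm)
    gamma_map(pair$ref, pair$ev, gamma_criteria(dd, dta, norm))$passing_rate
  # loosening DD or DTA cannot lower the passing rate
  expect_gte(rate(2, 1, "global"), rate(1, 1, "global"))
  expect_gte(rate(1, 2, "global"), rate(1, 1, "global"))
  expect_gte(rate(2, 2, "local"), rate(1, 2, "local"))
  # local normalization is never more permissive than global
  for (cr in list(c(2, 2), c(1, 1), c(1, 0.5)))
    expect_lte(rate(cr[1], cr[2], "local"), rate(cr[1], cr[2], "global"))
})

test_that("global gamma is invariant under joint rescaling of both maps", {
  pair <- random_map_pair(n = 24, seed = 31)
  cr <- gamma_criteria(2, 2, "global")
  g1 <- gamma_map(pair$ref, pair$ev, cr)
  ref2 <- pair$ref; ref2$values <- ref2$values * 3.7
  ev2 <- pair$ev;   ev2$values <- ev2$values * 3.7
  g2 <- gamma_map(ref2, ev2, cr)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-12)
  expect_equal(g1$passing_rate, g2$passing_rate)
})

test_that("criteria sharing a DTA produce the same result fused or separate", {
  pair <- random_map_pair(n = 24, seed = 41)
  crs <- list(g = gamma_criteria(2, 2, "global"), l = gamma_criteria(2, 2, "local"))
  fused <- gamma_map_multi(pair$ref, pair$ev, crs)
  expect_equal(fused$g$gamma, gamma_map(pair$ref, pair$ev, crs$g)$gamma)
  expect_equal(fused$l$gamma, gamma_map(pair$ref, pair$ev, crs$l)$gamma)
})
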