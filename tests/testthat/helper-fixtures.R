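# Shared fixtures: tiny plans, static-aperture arcs and toy image datasets.
# Everything is built in code at test time; nothing is stored on disk.

# a static "arc": the same rectangular aperture at every control point
square_plan <- function(half_mm = 20, n_cp = 2, gantry = 0, n_pairs = 33,
                        mu = NULL) {
  if (is.null(mu)) mu <- rep(1 / n_cp, n_cp)
  cps <- lapply(seq_len(n_cp), function(k)
    control_point(rep(-half_mm, n_pairs), rep(half_mm, n_pairs),
                  if (length(gantry) > 1) gantry[k] else gantry, mu[k]))
  arc_plan("square", "prostate_like", cps)
}

# all leaf pairs closed (parked off-axis), for transmission-only dose
closed_plan <- function(n_cp = 2, park = -70) {
  cps <- lapply(seq_len(n_cp), function(k)
    control_point(rep(park, 33), rep(park, 33), 0, 1 / n_cp))
  arc_plan("closed", "prostate_like", cps)
}

small_phantom <- function() phantom_spec()

# uniform-dose map helper for gamma tests
flat_map <- function(value = 100, n = 21, spacing = 2) {
  dose_map(matrix(value, n, n), spacing, "axial", 0, "flat")
}

# random smooth dose maps for gamma oracle comparisons
random_map_pair <- function(n = 32, spacing = 2, seed = 1, noise = 2) {
  set.seed(seed)
  base <- matrix(0, n, n)
  cx <- runif(1, n / 3, 2 * n / 3); cy <- runif(1, n / 3, 2 * n / 3)
  w <- runif(1, n / 6, n / 3)
  for (i in seq_len(n)) for (j in seq_len(n))
    base[i, j] <- 100 * exp(-((i - cx)^2 + (j - cy)^2) / (2 * w^2))
  pert <- base * (1 + noise / 100 * matrix(rnorm(n * n), n, n))
  pert <- pmax(pert + rnorm(1, 0, 1), 0)
  list(ref = dose_map(base, spacing, "axial", 0, "rand"),
       ev  = dose_map(pert, spacing, "axial", 0, "rand"))
}

# independent brute-force gamma oracle: plain full search over every offset
# of a fine lattice (no early termination, no shared code with the package
# implementation), vectorized over the analyzed pixels per offset
gamma_oracle <- function(ref_map, ev_map, criteria, step_mm, radius_mm) {
  ref <- ref_map$values; ev <- ev_map$values
  h <- ref_map$spacing_mm
  mx <- max(ref)
  mask <- which(ref >= criteria$dose_threshold_percent / 100 * mx)
  nr <- nrow(ref); nc <- ncol(ev)
  ii <- ((mask - 1) %% nr) + 1
  jj <- ((mask - 1) %/% nr) + 1
  rv <- ref[mask]
  tol <- if (criteria$normalization == "global")
    criteria$dd_percent / 100 * mx else criteria$dd_percent / 100 * rv
  ks <- seq(-floor(radius_mm / step_mm), floor(radius_mm / step_mm)) * step_mm
  offs <- expand.grid(ox = ks, oy = ks)
  offs <- offs[offs$ox^2 + offs$oy^2 <= radius_mm^2 + 1e-9, ]
  eps <- 1e-9
  best <- rep(Inf, length(mask))
  for (k in seq_len(nrow(offs))) {
    gi <- ii + offs$ox[k] / h
    gj <- jj + offs$oy[k] / h
    ok <- gi >= 1 - eps & gi <= nr + eps & gj >= 1 - eps & gj <= nc + eps
    if (!any(ok)) next
    gi <- pmin(pmax(gi[ok], 1), nr); gj <- pmin(pmax(gj[ok], 1), nc)
    i0 <- pmin(floor(gi), nr - 1); j0 <- pmin(floor(gj), nc - 1)
    wi <- gi - i0; wj <- gj - j0
    de <- ev[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
      ev[cbind(i0 + 1, j0)] * wi * (1 - wj) +
      ev[cbind(i0, j0 + 1)] * (1 - wi) * wj +
      ev[cbind(i0 + 1, j0 + 1)] * wi * wj
    tolk <- if (length(tol) == 1) tol else tol[ok]
    g2 <- (offs$ox[k]^2 + offs$oy[k]^2) / criteria$dta_mm^2 +
      ((de - rv[ok]) / tolk)^2
    best[ok] <- pmin(best[ok], g2)
  }
  g <- matrix(NA_real_, nr, ncol(ref))
  g[mask] <- sqrt(best)
  g
}

# toy image dataset: class 0 = dark-ish images, class 1 = bright-ish images
make_toy_manifest <- function(dir, n_per_class = 12, img_size = 64,
                              seed = 1, sigma = 0.5) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0
  for (cls in c("error_free", "TF")) {
    mu <- if (cls == "TF") 150 else 106
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      px <- matrix(as.integer(pmin(pmax(round(rnorm(img_size^2, mu, 12)), 0), 255)),
                   img_size, img_size)
      path <- file.path(dir, sprintf("toy_%03d.png", k))
      png::writePNG(px / 255, target = path)
      rows[[k]] <- data.frame(
        path = path, plan_id = sprintf("plan%02d", (i - 1) %/% 3 + 1),
        site = "prostate_like", plane = "axial", offset_mm = 0,
        plane_key = "axial_+0", error_type = cls,
        sign = if (cls == "TF") "+" else "n/a",
        magnitude_pct = if (cls == "TF") 10 else 0, sigma = sigma,
        split = "train", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

toy_config <- function(epochs = 5, seed = 1)
  train_config(epochs = epochs, batch_size = 8, learning_rate = 0.01,
               input_size = 32, augment_factor = 1, seed = seed)
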