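#' Generate a cohort of synthetic VMAT arcs
#'
#' Half prostate-like, half head-and-neck-like (the extra arc goes to the
#' prostate group when `n_arcs` is odd), with per-arc seeds derived from
#' `seed`.
#'
#' @param n_arcs Number of arcs.
#' @param seed Base integer seed.
#' @param n_control_points Control points per arc (default 90).
#' @param leaf_width_mm Leaf width passed to the generator.
#' @return List of [arc_plan()] objects.
#' @export
generate_cohort <- function(n_arcs, seed = 1, n_control_points = 90,
                            leaf_width_mm = 5) {
  n_pro <- ceiling(n_arcs / 2)
  sites <- c(rep("prostate_like", n_pro),
             rep("head_neck_like", n_arcs - n_pro))
  lapply(seq_len(n_arcs), function(i)
    generate_arc_plan(sites[i], n_control_points, seed = seed + i,
                      leaf_width_mm = leaf_width_mm,
                      plan_id = sprintf("arc%02d_%s", i,
                                        substr(sites[i], 1, 4))))
}

#' @keywords internal
#' @noRd
label_string <- function(label) {
  if (label$error_type == "error_free") "EF"
  else sprintf("%s%s%d", label$error_type, label$sign, label$magnitude_pct)
}

#' @keywords internal
#' @noRd
error_labels <- function(magnitudes, signs) {
  out <- list(beam_label())
  for (type in c("TF", "DLG"))
    for (sg in signs)
      for (mag in magnitudes)
        out[[length(out) + 1]] <- beam_label(type, sg, mag)
  out
}

#' Build the labeled dose-difference image dataset
#'
#' The full simulation chain for a cohort of arcs: per arc the error-free
#' dose volume is computed and normalized to maximum 100, all TF/DLG error
#' volumes are computed with the same beam perturbations and normalization,
#' nine planar maps are extracted per volume, the mimicked measured maps are
#' produced per Gaussian sigma from the error-free planes, all calculated
#' maps are median-filtered, and every (measured, calculated) pair is
#' subtracted, resampled to 256 x 256 and quantized to an 8-bit PNG.
#'
#' Per sigma setting this yields `n_arcs * 9` error-free images and
#' `n_arcs * 9 * length(magnitudes)` images per (error type, sign).
#'
#' @param plans List of [arc_plan()] (e.g. from [generate_cohort()]).
#' @param beam Nominal [beam_model()].
#' @param phantom A [phantom_spec()].
#' @param sigmas Gaussian sigmas of the measurement model (grid pixels).
#' @param magnitudes Error magnitudes in percent (default `c(10, 20, 30)`).
#' @param signs Error signs (default both).
#' @param out_dir Directory for the PNG images and the JSON manifest.
#' @param window Quantization half-window in dose units (default 5).
#' @param median_kernel Median filter window (default 3).
#' @param filter_target Which side of the comparison the Gaussian is applied
#'   to: `"error_free"` (default; the machine delivers the truth and the
#'   calculated map carries the modeling error) or `"error"` (the
#'   alternative reading; sign-flipped difference maps).
#' @param keep_maps Keep the filtered dose maps in memory (needed by
#'   [compute_gamma_rates()]).
#' @return An object of class `vmat_dataset`: `manifest` (data frame),
#'   `dir`, configuration, and optionally `maps`.
#' @export
build_dataset <- function(plans, beam = beam_model(),
                          phantom = phantom_spec(),
                          sigmas = c(0.5, 1.0),
                          magnitudes = c(10, 20, 30),
                          signs = c("+", "-"),
                          out_dir = tempfile("vmatqa_dataset_"),
                          window = 5, median_kernel = 3,
                          filter_target = c("error_free", "error"),
                          keep_maps = FALSE) {
  filter_target <- match.arg(filter_target)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- error_labels(magnitudes, signs)
  rows <- list()
  maps <- if (keep_maps) list() else NULL

  for (plan in plans) {
    vol_ef <- accumulate_arc_dose(plan, beam, phantom)
    scale <- 100 / max(vol_ef$values)
    planes_by_label <- list()
    for (label in labels) {
      b <- if (label$error_type == "error_free") beam
           else perturb_beam(beam, label$error_type,
                             as.numeric(paste0(label$sign, label$magnitude_pct)))
      vol <- if (label$error_type == "error_free") vol_ef
             else accumulate_arc_dose(plan, b, phantom)
      vol$values <- vol$values * scale
      vol$beam_label <- label
      planes_by_label[[label_string(label)]] <- extract_planes(vol)
    }
    if (keep_maps) maps[[plan$plan_id]] <- list(measured = list(), calc = list())

    # the median filter is sigma-independent: apply it to every calculated
    # map once, before the per-sigma measurement loop
    med_model <- measurement_model(sigma = 0, median_kernel = median_kernel)
    ef_planes <- planes_by_label[["EF"]]
    calc <- lapply(planes_by_label, function(pl)
      lapply(pl, median_filter_map, model = med_model))
    if (keep_maps && filter_target == "error_free")
      maps[[plan$plan_id]]$calc <- calc

    for (sg in sigmas) {
      model <- measurement_model(sigma = sg, median_kernel = median_kernel)
      if (filter_target == "error_free") {
        measured <- lapply(ef_planes, mimic_measurement, model = model)
      } else {
        # alternative reading: the Gaussian is applied to each error plan
        measured_by_label <- lapply(planes_by_label, function(pl)
          lapply(pl, mimic_measurement, model = model))
        calc_ef <- calc[["EF"]]
      }
      if (keep_maps && filter_target == "error_free")
        maps[[plan$plan_id]]$measured[[as.character(sg)]] <- measured
      for (lname in names(planes_by_label)) {
        label <- planes_by_label[[lname]][[1]]$beam_label
        for (pk in names(planes_by_label[[lname]])) {
          if (filter_target == "error_free") {
            dmap <- difference_map(measured[[pk]], calc[[lname]][[pk]])
          } else {
            dmap <- difference_map(measured_by_label[[lname]][[pk]], calc_ef[[pk]])
          }
          img <- to_image(dmap, window = window)
          fname <- sprintf("%s_%s_%s_s%s.png", plan$plan_id, pk, lname,
                           gsub("[.]", "p", format(sg)))
          write_png_image(img, file.path(out_dir, fname))
          rows[[length(rows) + 1]] <- data.frame(
            path = file.path(out_dir, fname), plan_id = plan$plan_id,
            site = plan$site, plane = dmap$plane, offset_mm = dmap$offset_mm,
            plane_key = pk, error_type = label$error_type, sign = label$sign,
            magnitude_pct = label$magnitude_pct, sigma = sg,
            split = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  config <- list(window = window, sigmas = sigmas, magnitudes = magnitudes,
                 signs = signs, median_kernel = median_kernel,
                 filter_target = filter_target,
                 beam = list(tf = beam$tf, dlg_mm = beam$dlg_mm,
                             penumbra_sigma_mm = beam$penumbra_sigma_mm,
                             mu_per_mm = beam$mu_per_mm),
                 n_arcs = length(plans))
  jsonlite::write_json(list(config = config, entries = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, dir = out_dir, config = config,
                 maps = maps),
            class = "vmat_dataset")
}

#' @export
print.vmat_dataset <- function(x, ...) {
  cat(sprintf("<vmat_dataset> %d images, %d arcs, sigmas {%s}, dir %s\n",
              nrow(x$manifest), x$config$n_arcs,
              paste(x$config$sigmas, collapse = ", "), x$dir))
  invisible(x)
}

#' Per-class image counts of a dataset manifest
#'
#' @param manifest Manifest data frame (or `vmat_dataset`).
#' @param sigma Restrict to one sigma setting (default: first).
#' @return List with `error_free` and a `type_sign` table.
#' @export
dataset_counts <- function(manifest, sigma = NULL) {
  if (inherits(manifest, "vmat_dataset")) manifest <- manifest$manifest
  if (is.null(sigma)) sigma <- manifest$sigma[1]
  m <- manifest[manifest$sigma == sigma, ]
  err <- m[m$error_type != "error_free", ]
  list(error_free = sum(m$error_type == "error_free"),
       type_sign = table(err$error_type, err$sign)[c("TF", "DLG"), , drop = FALSE])
}

#' Plan-level train/test split
#'
#' Assigns whole arcs to train or test so that no plan contributes images to
#' both sets; the test arcs are drawn evenly from the two site classes (both
#' classes are always represented).
#'
#' @param manifest Manifest data frame (or `vmat_dataset`).
#' @param n_test_arcs Number of test arcs (default 8, as in a 40-arc cohort
#'   with a 32/8 split).
#' @param seed Integer seed (identical seeds give identical splits).
#' @return List with `train` and `test` manifest data frames (the `split`
#'   column is filled in) and `test_plan_ids`.
#' @export
split_by_plan <- function(manifest, n_test_arcs = 8, seed = 1) {
  if (inherits(manifest, "vmat_dataset")) manifest <- manifest$manifest
  plans <- unique(manifest[, c("plan_id", "site")])
  if (n_test_arcs >= nrow(plans))
    stop_named("vmatqa_invalid_split",
               "n_test_arcs must be smaller than the number of arcs")
  set.seed(seed)
  sites <- split(plans$plan_id, plans$site)
  n_sites <- length(sites)
  base <- n_test_arcs %/% n_sites
  extra <- n_test_arcs %% n_sites
  test_ids <- character(0)
  for (k in seq_along(sites)) {
    nk <- min(base + as.integer(k <= extra), length(sites[[k]]))
    test_ids <- c(test_ids, sample(sites[[k]], nk))
  }
  manifest$split <- ifelse(manifest$plan_id %in% test_ids, "test", "train")
  list(train = manifest[manifest$split == "train", ],
       test = manifest[manifest$split == "test", ],
       test_plan_ids = sort(test_ids))
}

#' Gamma passing rates for every (measured, calculated) pair of a dataset
#'
#' Computes the 2D gamma index of each mimicked measured map against each
#' calculated map (error-free and all error variants) for the given
#' criteria; criteria with equal DTA share one distance search. Requires a
#' dataset built with `keep_maps = TRUE`.
#'
#' @param dataset A `vmat_dataset` with kept maps.
#' @param criteria Named list of [gamma_criteria()] (default: the six study
#'   criteria).
#' @param plan_ids Restrict to these arcs (default: all kept).
#' @param sigmas Restrict to these sigma settings (default: all).
#' @param step_mm Search pitch passed to [gamma_map_multi()].
#' @return Data frame: one row per (arc, plane, error variant, sigma,
#'   criteria) with the passing rate.
#' @export
compute_gamma_rates <- function(dataset, criteria = standard_gamma_criteria(),
                                plan_ids = NULL, sigmas = NULL,
                                step_mm = NULL) {
  stopifnot(inherits(dataset, "vmat_dataset"))
  if (is.null(dataset$maps))
    stop_named("vmatqa_no_maps", "dataset was built without keep_maps = TRUE")
  if (is.null(plan_ids)) plan_ids <- names(dataset$maps)
  if (is.null(sigmas)) sigmas <- dataset$config$sigmas
  rows <- list()
  for (pid in plan_ids) {
    entry <- dataset$maps[[pid]]
    for (sg in sigmas) {
      measured <- entry$measured[[as.character(sg)]]
      for (lname in names(entry$calc)) {
        label <- entry$calc[[lname]][[1]]$beam_label
        for (pk in names(measured)) {
          res <- gamma_map_multi(measured[[pk]], entry$calc[[lname]][[pk]],
                                 criteria, step_mm = step_mm)
          for (cn in names(res)) {
            cr <- res[[cn]]$criteria
            rows[[length(rows) + 1]] <- data.frame(
              plan_id = pid, plane_key = pk, sigma = sg,
              error_type = label$error_type, sign = label$sign,
              magnitude_pct = label$magnitude_pct,
              criteria = cn, normalization = cr$normalization,
              dd_percent = cr$dd_percent, dta_mm = cr$dta_mm,
              passing_rate = res[[cn]]$passing_rate,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' ROC/Wilcoxon detection summary of gamma passing rates
#'
#' For each (criteria, sigma, error type) the error-free passing rates are
#' compared with the error passing rates: Wilcoxon signed-rank p (each error
#' map paired with the error-free map of the same arc and plane), ROC AUC,
#' Youden threshold and the accuracy at that threshold.
#'
#' @param rates Data frame from [compute_gamma_rates()].
#' @return Data frame with one row per (criteria, sigma, error type).
#' @export
summarize_gamma_detection <- function(rates) {
  out <- list()
  key <- function(d) paste(d$plan_id, d$plane_key, d$sigma, d$criteria)
  for (cn in unique(rates$criteria)) {
    for (sg in unique(rates$sigma)) {
      sub <- rates[rates$criteria == cn & rates$sigma == sg, ]
      ef <- sub[sub$error_type == "error_free", ]
      for (type in c("TF", "DLG")) {
        err <- sub[sub$error_type == type, ]
        if (!nrow(err) || !nrow(ef)) next
        idx <- match(key(err), key(ef))
        det <- roc_detect(ef$passing_rate, err$passing_rate, ef_index = idx)
        out[[length(out) + 1]] <- data.frame(
          criteria = cn, normalization = err$normalization[1],
          dd_percent = err$dd_percent[1], dta_mm = err$dta_mm[1],
          sigma = sg, error_type = type, p_value = det$p_value,
          auc = det$auc, threshold = det$threshold,
          accuracy = det$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
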