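# Small-cohort instances of the dataset design formulas; the full-size
# counts are exercised in the acceptance suite.

build_small_dataset <- function(n_arcs = 4, magnitudes = 10, sigmas = 0.5,
                                n_cp = 10, seed = 11, ...) {
  plans <- generate_cohort(n_arcs, seed = seed, n_control_points = n_cp)
  build_dataset(plans, sigmas = sigmas, magnitudes = magnitudes, ...)
}

test_that("manifest counts follow the design formula and labels match the config", {
  ds <- build_small_dataset(n_arcs = 4, magnitudes = 10)
  cnt <- dataset_counts(ds)
  expect_equal(cnt$error_free, 4 * 9)            # arcs x 9 planes
  expect_true(all(cnt$type_sign == 4 * 9 * 1))   # x |magnitudes| per (type, sign)
  expect_equal(nrow(ds$manifest), 4 * 9 * (1 + 4))

  m <- ds$manifest
  expect_setequal(unique(m$error_type), c("error_free", "TF", "DLG"))
  expect_setequal(unique(m$sign[m$error_type != "error_free"]), c("+", "-"))
  expect_true(all(m$magnitude_pct[m$error_type == "error_free"] == 0))
  expect_true(all(file.exists(m$path)))

  # every image decodes to 256 x 256
  px <- read_png_image(m$path[1])
  expect_equal(dim(px), c(256, 256))

  # the manifest JSON records the builder configuration
  man <- jsonlite::read_json(file.path(ds$dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$config$window, 5)
  expect_equal(man$config$beam$tf, 0.0122)
  expect_equal(nrow(man$entries), nrow(m))
  unlink(ds$dir, recursive = TRUE)
})

test_that("plan-level splits are arc-disjoint, stratified and seeded", {
  ds <- build_small_dataset(n_arcs = 6, magnitudes = 10)
  sp <- split_by_plan(ds, n_test_arcs = 2, seed = 3)
  expect_length(intersect(unique(sp$train$plan_id), unique(sp$test$plan_id)), 0)
  expect_length(unique(sp$test$plan_id), 2)
  expect_length(unique(sp$train$plan_id), 4)
  # both site classes in the test set
  expect_setequal(unique(sp$test$site), c("prostate_like", "head_neck_like"))
  # all images of a test arc are in the test set
  m <- ds$manifest
  expect_equal(sum(m$plan_id %in% sp$test_plan_ids), nrow(sp$test))
  # reproducible
  sp2 <- split_by_plan(ds, n_test_arcs = 2, seed = 3)
  expect_identical(sp$test_plan_ids, sp2$test_plan_ids)
  sp3 <- split_by_plan(ds, n_test_arcs = 2, seed = 4)
  expect_false(identical(sp$test_plan_ids, sp3$test_plan_ids))

  expect_error(split_by_plan(ds, n_test_arcs = 6),
               class = "vmatqa_invalid_split")
  unlink(ds$dir, recursive = TRUE)
})

test_that("augmentation expands by the requested factor with the declared menu", {
  set.seed(5)
  imgs <- replicate(4, matrix(as.integer(sample(0:255, 64 * 64, TRUE)), 64, 64),
                    simplify = FALSE)
  aug <- augment_error_free(imgs, factor = 6, seed = 9)
  expect_length(aug, 24)
  expect_identical(aug[[1]], imgs[[1]])  # first replicate keeps the original
  # deterministic under the seed
  aug2 <- augment_error_free(imgs, factor = 6, seed = 9)
  expect_identical(aug, aug2)
  # refuses test-split images
  expect_error(augment_error_free(imgs, 2, split = c("train", "test", "train", "train")),
               class = "vmatqa_augment_test_split")
  # flip is an involution
  expect_identical(img_flip(img_flip(imgs[[1]])), imgs[[1]])
  # random erasing changes exactly one rectangular region
  set.seed(1)
  er <- img_random_erase(imgs[[1]])
  changed <- which(er != imgs[[1]], arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  rows <- range(changed[, 1]); cols <- range(changed[, 2])
  expect_true(all(er[rows[1]:rows[2], cols[1]:cols[2]] == 128L))
})

test_that("the alternative filter-target reading flips the difference sign", {
  plans <- generate_cohort(1, seed = 21, n_control_points = 8)
  ds_a <- build_dataset(plans, sigmas = 0.5, magnitudes = 30,
                        filter_target = "error_free")
  ds_b <- build_dataset(plans, sigmas = 0.5, magnitudes = 30,
                        filter_target = "error")
  pick <- function(ds) {
    m <- ds$manifest
    r <- m[m$error_type == "TF" & m$sign == "+" & m$plane_key == "coronal_+0", ]
    mean(read_png_image(r$path[1]))
  }
  # +TF: extra transmission in the calculated map -> dark image under the
  # default reading, bright under the alternative
  expect_lt(pick(ds_a), 128)
  expect_gt(pick(ds_b), 128)
  unlink(ds_a$dir, recursive = TRUE); unlink(ds_b$dir, recursive = TRUE)
})
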