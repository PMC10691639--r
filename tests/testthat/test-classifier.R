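test_that("the small CNN separates a trivially separable image set", {
  dir <- tempfile("toy_")
  manifest <- make_toy_manifest(dir, n_per_class = 12)
  cfg <- toy_config(epochs = 5)
  model <- train_classifier("TF_DETECT", manifest, cfg,
                            test_manifest = manifest)
  expect_equal(nrow(model$curves), 5)
  rep <- evaluate_classifier(model, manifest)
  expect_gte(rep$accuracy, 95)
  expect_gte(rep$auc, 0.99)
  unlink(dir, recursive = TRUE)
})

test_that("training is deterministic and models round-trip through disk", {
  dir <- tempfile("toy_")
  manifest <- make_toy_manifest(dir, n_per_class = 6)
  cfg <- toy_config(epochs = 2)
  m1 <- train_classifier("TF_DETECT", manifest, cfg)
  m2 <- train_classifier("TF_DETECT", manifest, cfg)
  expect_identical(m1$net, m2$net)
  m3 <- train_classifier("TF_DETECT", manifest, toy_config(epochs = 2, seed = 2))
  expect_false(identical(m1$net, m3$net))

  path <- tempfile(fileext = ".rds")
  save_classifier(m1, path)
  m1b <- load_classifier(path)
  expect_identical(as.numeric(predict(m1, manifest)),
                   as.numeric(predict(m1b, manifest)))

  # single-class training set rejected
  ef_only <- manifest[manifest$error_type == "error_free", ]
  expect_error(train_classifier("TF_DETECT", ef_only, cfg),
               class = "vmatqa_single_class")
  unlink(dir, recursive = TRUE)
})

test_that("evaluation metrics equal a brute-force recomputation", {
  dir <- tempfile("toy_")
  manifest <- make_toy_manifest(dir, n_per_class = 10, seed = 3)
  cfg <- toy_config(epochs = 3)
  model <- train_classifier("TF_DETECT", manifest, cfg)
  rep <- evaluate_classifier(model, manifest)

  scores <- as.numeric(predict(model, manifest))
  y <- attr(predict(model, manifest), "y")
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  expect_equal(rep$accuracy, 100 * (tp + tn) / length(y))
  expect_equal(rep$sensitivity, 100 * tp / (tp + fn))
  expect_equal(rep$specificity, 100 * tn / (tn + fp))
  cmp <- outer(scores[y == 0], scores[y == 1],
               function(a, b) (b > a) + 0.5 * (a == b))
  expect_equal(rep$auc, mean(cmp), tolerance = 1e-12)
  expect_equal(sum(rep$confusion), length(y))
  expect_error(evaluate_classifier(model, manifest[0, ]),
               class = "vmatqa_empty_dataset")
  unlink(dir, recursive = TRUE)
})

test_that("oracle and constant scorers give the degenerate AUC values", {
  # evaluation path with hand-made scores, bypassing training
  y <- c(0, 0, 0, 1, 1, 1)
  m <- vmatqa:::metrics_from_scores(c(.1, .2, .3, .7, .8, .9), y)
  expect_equal(m$accuracy, 100)
  expect_equal(m$auc, 1.0)
  mc <- vmatqa:::metrics_from_scores(rep(0.5, 6), y)
  expect_equal(mc$auc, 0.5)
})

test_that("the grid produces one row per configuration combination", {
  dir <- tempfile("toy_")
  manifest <- make_toy_manifest(dir, n_per_class = 8)
  splits <- list(`0.5` = list(train = manifest, test = manifest),
                 `1`   = list(train = manifest, test = manifest))
  grid <- grid_evaluate(splits, tasks = c("TF_DETECT", "TF_DETECT"),
                        batch_sizes = c(8, 16),
                        learning_rates = c(0.001, 0.0001),
                        epochs = 1, input_size = 32, augment_factor = 1)
  expect_equal(nrow(grid), 2 * 2 * 2 * 2)
  expect_setequal(names(grid),
                  c("task", "sigma", "batch_size", "learning_rate", "backbone",
                    "train_accuracy", "test_accuracy", "test_sensitivity",
                    "test_specificity", "test_auc"))
  unlink(dir, recursive = TRUE)
})

test_that("task specifications define disjoint, exhaustive classes", {
  m <- data.frame(error_type = c("error_free", "TF", "TF", "DLG", "DLG"),
                  sign = c("n/a", "+", "-", "+", "-"))
  for (t in c("TF_DETECT", "DLG_DETECT", "TF_VS_DLG", "TF_SIGN", "DLG_SIGN")) {
    ts <- task_spec(t)
    inc <- ts$include(m)
    pos <- ts$positive(m[inc, ])
    expect_true(all(pos %in% c(TRUE, FALSE)))
    expect_gt(sum(inc), 0)
  }
  # TF_VS_DLG excludes the error-free class
  expect_false(task_spec("TF_VS_DLG")$include(m)[1])
  # sign tasks restrict to their error type
  expect_equal(sum(task_spec("TF_SIGN")$include(m)), 2)
})
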