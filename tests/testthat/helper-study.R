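# The desk-scale study shared by the acceptance suite: 12 arcs (6 per site
# class, 90 control points), both measurement blurs, 4 held-out test arcs,
# all five classification tasks (15 epochs, batch 8, lr 0.01 with cosine
# decay, 64 px inputs), and the six-criteria gamma ROC baseline on the test
# arcs at sigma = 0.5. Built lazily once and cached for all test blocks.

.study_env <- new.env()

acceptance_study <- function() {
  if (!is.null(.study_env$study)) return(.study_env$study)

  plans <- generate_cohort(12, seed = 101, n_control_points = 90)
  ds <- build_dataset(plans, sigmas = c(0.5, 1.0), keep_maps = TRUE,
                      out_dir = tempfile("vmatqa_study_"))
  sp <- split_by_plan(ds, n_test_arcs = 4, seed = 202)

  tasks <- c("TF_DETECT", "DLG_DETECT", "TF_VS_DLG", "TF_SIGN", "DLG_SIGN")
  cnn <- list()
  for (task in tasks) {
    for (sg in c(0.5, 1.0)) {
      cfg <- train_config(epochs = 15, batch_size = 8, learning_rate = 0.01,
                          input_size = 64, augment_factor = 6, seed = 303)
      model <- train_classifier(task, sp$train[sp$train$sigma == sg, ], cfg)
      te <- sp$test[sp$test$sigma == sg, ]
      rep <- evaluate_classifier(model, te)
      key <- sprintf("%s_s%g", task, sg)
      cnn[[key]] <- list(report = rep)
      if (grepl("DETECT", task))
        cnn[[key]]$magnitude <- evaluate_breakdown(model, te, by = "magnitude")
    }
  }

  rates <- compute_gamma_rates(ds, plan_ids = sp$test_plan_ids, sigmas = 0.5)
  gamma_pooled <- vapply(unique(rates$criteria), function(cn) {
    sub <- rates[rates$criteria == cn, ]
    roc_detect(sub$passing_rate[sub$error_type == "error_free"],
               sub$passing_rate[sub$error_type != "error_free"])$auc
  }, numeric(1))

  .study_env$study <- list(dataset = ds, split = sp, cnn = cnn,
                           gamma_rates = rates, gamma_pooled = gamma_pooled,
                           gamma_by_type = summarize_gamma_detection(rates))
  .study_env$study
}
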