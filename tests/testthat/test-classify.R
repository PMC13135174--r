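# Class mapping, participant-wise splitting, classifier tuning, evaluation.

test_that("stenosis maps to severity classes with inclusive 50-75 moderate", {
  expect_equal(stenosis_to_class(c(0, 30, 49.9)), rep("mild", 3))
  expect_equal(stenosis_to_class(c(50, 60, 75)), rep("moderate", 3))
  expect_equal(stenosis_to_class(c(75.1, 95)), rep("severe", 2))
  expect_error(stenosis_to_class(101), "\\[0, 100\\]")
})

test_that("participant_split is leak-free, stratified and reproducible", {
  man <- test_manifest()
  sp <- participant_split(man, 60, 15, seed = 5,
                          test_class_counts = c(mild = 5, moderate = 4, severe = 6))
  expect_length(sp$train_ids, 60)
  expect_length(sp$test_ids, 15)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  lab <- man$label[match(sp$test_ids, man$participant_id)]
  expect_equal(as.vector(table(factor(lab, c("mild", "moderate", "severe")))),
               c(5, 4, 6))
  sp2 <- participant_split(man, 60, 15, seed = 5,
                           test_class_counts = c(mild = 5, moderate = 4, severe = 6))
  expect_identical(sp, sp2)

  # proportional default allocation sums to test_n
  sp3 <- participant_split(man, 60, 15, seed = 6)
  expect_length(sp3$test_ids, 15)
  expect_error(participant_split(man, 70, 15, seed = 1), "exceeds")
  expect_error(participant_split(man, 40, 15, seed = 1,
                                 test_class_counts = c(mild = 40, moderate = 4, severe = 6)),
               "infeasible")
})

test_that("confusion_metrics agrees with longhand arithmetic", {
  cm <- rbind(c(40, 8, 2), c(5, 30, 5), c(1, 4, 55))
  rownames(cm) <- colnames(cm) <- c("mild", "moderate", "severe")
  m <- confusion_metrics(cm)
  # longhand for class "mild": tp 40, fp 6, fn 10, tn 94
  expect_equal(m$per_class$precision[1], 40 / 46)
  expect_equal(m$per_class$recall[1], 40 / 50)
  expect_equal(m$per_class$specificity[1], 94 / 100)
  expect_equal(m$per_class$f1[1], 2 * (40 / 46) * (40 / 50) / ((40 / 46) + (40 / 50)))
  expect_equal(m$accuracy, 125 / 150)
  expect_equal(m$balanced_accuracy, mean(c(40 / 50, 30 / 40, 55 / 60)))
})

test_that("the SVM grid covers the stated ranges and separable data is learned", {
  expect_true(1.0 %in% default_config()$classify$svm_C_grid)
  expect_true(0.01 %in% default_config()$classify$svm_gamma_grid)

  df <- separable_features()
  x <- as.matrix(df[c("f1", "f2")])
  svm <- tune_svm(x, df$label, df$participant_id, C_grid = 1, gamma_grid = 0.1,
                  seed = 8)
  expect_equal(svm$C, 1)          # one-candidate grid -> that candidate
  expect_equal(svm$gamma, 0.1)
  expect_equal(max(svm$cv$cv_accuracy), 1)  # separable -> perfect CV accuracy
  expect_equal(unname(predict(svm, x)), df$label)

  rep <- evaluate_model(svm, x, df$label)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$auc$auc == 1))
  expect_error(tune_svm(x[df$label == "mild", ], df$label[df$label == "mild"],
                        df$participant_id[df$label == "mild"]), "single class")
})

test_that("boosted trees: grid coverage, determinism, above-chance learning", {
  cfg <- default_config()$classify
  expect_true(300 %in% cfg$xgb_n_grid && 0.05 %in% cfg$xgb_lr_grid &&
              5 %in% cfg$xgb_depth_grid && 0.8 %in% cfg$xgb_subsample_grid)

  df <- separable_features()
  x <- as.matrix(df[c("f1", "f2")])
  fit1 <- tune_xgb(x, df$label, df$participant_id, n_grid = c(20L, 50L),
                   lr_grid = 0.1, depth_grid = 3L, subsample_grid = 0.8, seed = 9)
  fit2 <- tune_xgb(x, df$label, df$participant_id, n_grid = c(20L, 50L),
                   lr_grid = 0.1, depth_grid = 3L, subsample_grid = 0.8, seed = 9)
  expect_identical(fit1$n_estimators, fit2$n_estimators)
  expect_identical(predict(fit1, x, type = "prob"), predict(fit2, x, type = "prob"))

  acc <- mean(predict(fit1, x) == df$label)
  expect_gte(acc, 1 / 3 + 0.3)   # well above the 3-class chance level
  rep <- evaluate_model(fit1, x, df$label)
  expect_gte(min(rep$auc$auc), 0.95)
})

test_that("evaluation is invariant to test-row permutation (no leakage)", {
  df <- separable_features(n_part_per_class = 4L, rows_per_part = 4L, seed = 12)
  x <- as.matrix(df[c("f1", "f2")])
  svm <- tune_svm(x, df$label, df$participant_id, C_grid = 1, gamma_grid = 0.1)
  set.seed(99)
  perm <- sample.int(nrow(x))
  r1 <- evaluate_model(svm, x, df$label)
  r2 <- evaluate_model(svm, x[perm, ], df$label[perm])
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$confusion, r2$confusion)
  expect_equal(r1$auc$auc, r2$auc$auc)
})

test_that("a small end-to-end pipeline run is deterministic", {
  spec <- data.frame(name = c("a", "b", "c"), n = c(4L, 4L, 4L),
                     lo = c(0, 55, 85), hi = c(30, 70, 95))
  cfg <- default_config(
    seed = 101L,
    classify = list(train_n = 9L, test_n = 3L, test_class_counts = NULL,
                    cv_folds = 3L,
                    svm_C_grid = 1, svm_gamma_grid = 0.01,
                    xgb_n_grid = 30L, xgb_lr_grid = 0.1,
                    xgb_depth_grid = 3L, xgb_subsample_grid = 0.8))
  out1 <- run_pipeline(cfg, cohort_spec = spec)
  out2 <- run_pipeline(cfg, cohort_spec = spec)
  expect_identical(out1$report_svm$confusion, out2$report_svm$confusion)
  expect_identical(out1$report_xgb$scores, out2$report_xgb$scores)
  expect_identical(out1$features, out2$features)
  expect_equal(out1$counts$segments, 120)
  expect_s3_class(out1$delong, "data.frame")
})
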