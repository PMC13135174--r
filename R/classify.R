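# Participant-wise splitting, classifier tuning and evaluation.

PCG_CLASSES <- c("mild", "moderate", "severe")

#' Map stenosis percent to a severity class
#'
#' `< 50` is mild (normal participants included), `50-75` inclusive is
#' moderate, `> 75` is severe.
#'
#' @param stenosis_pct stenosis percent in `[0, 100]` (vectorized).
#' @return character vector of classes.
#' @export
stenosis_to_class <- function(stenosis_pct) {
  if (any(stenosis_pct < 0 | stenosis_pct > 100)) stop("stenosis_pct must lie in [0, 100]")
  ifelse(stenosis_pct < 50, "mild", ifelse(stenosis_pct <= 75, "moderate", "severe"))
}

#' Participant-wise train/test split
#'
#' Splits at the participant level so that no participant contributes
#' segments to both sides. By default the test set is stratified
#' proportionally by class (largest-remainder rounding); an explicit
#' per-class participant count can be supplied instead.
#'
#' @param manifest a cohort manifest with `participant_id` and either `label`
#'   or `stenosis_pct`.
#' @param train_n,test_n participant counts for each side.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @param test_class_counts optional named vector, e.g.
#'   `c(mild = 5, moderate = 4, severe = 6)`, fixing the test-set class
#'   composition.
#' @return list with `train_ids` and `test_ids`.
#' @export
participant_split <- function(manifest, train_n = 60L, test_n = 15L, seed = 1L,
                              test_class_counts = NULL) {
  if (is.null(manifest$label)) manifest$label <- stenosis_to_class(manifest$stenosis_pct)
  n <- nrow(manifest)
  if (train_n + test_n > n) stop("train_n + test_n exceeds participant count")
  set.seed(as.integer(seed))
  by_class <- split(manifest$participant_id, factor(manifest$label, levels = PCG_CLASSES))
  by_class <- by_class[lengths(by_class) > 0L]

  if (is.null(test_class_counts)) {
    raw <- test_n * lengths(by_class) / n
    cnt <- floor(raw)
    rem <- test_n - sum(cnt)
    if (rem > 0) {
      order_rem <- order(raw - cnt, decreasing = TRUE)
      cnt[order_rem[seq_len(rem)]] <- cnt[order_rem[seq_len(rem)]] + 1L
    }
    test_class_counts <- cnt
  } else {
    test_class_counts <- test_class_counts[names(by_class)]
  }
  if (any(test_class_counts > lengths(by_class)))
    stop("infeasible stratification: not enough participants in some class")

  test_ids <- unlist(lapply(names(by_class), function(cl) {
    ids <- by_class[[cl]]
    ids[sample.int(length(ids), test_class_counts[[cl]])]
  }), use.names = FALSE)
  rest <- setdiff(manifest$participant_id, test_ids)
  if (length(rest) > train_n) {
    # trim proportionally at random, keeping determinism
    rest <- rest[sample.int(length(rest), train_n)]
  }
  pcg_log("participant_split: %d train / %d test participants", length(rest), length(test_ids))
  list(train_ids = sort(rest), test_ids = sort(test_ids))
}

# participant-grouped, class-stratified CV fold assignment
make_cv_folds <- function(participants, labels, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(participants))
  names(fold) <- participants
  for (cl in unique(labels)) {
    ids <- participants[labels == cl]
    ids <- ids[sample.int(length(ids))]
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

dist_sq <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

rbf_kernel <- function(A, B, gamma) exp(-gamma * dist_sq(A, B))

train_svm_ovr <- function(K, y_factor, C) {
  classes <- levels(y_factor)
  lapply(classes, function(cl) {
    yy <- ifelse(y_factor == cl, 1L, -1L)
    fit <- svm_smo_cpp(K, yy, C)
    list(class = cl, y = yy, alpha = fit$alpha, b = fit$b)
  })
}

svm_decision <- function(binaries, K_test) {
  vapply(binaries, function(bfit) {
    as.numeric(K_test %*% (bfit$alpha * bfit$y) + bfit$b)
  }, numeric(nrow(K_test)))
}

#' Tune and fit the RBF-kernel SVM
#'
#' Grid search over `C` and `gamma` (one-vs-rest binary SVMs trained by a
#' derandomized SMO solver), scored by five-fold cross-validated accuracy.
#' Folds are stratified by class and grouped by participant, so no
#' participant straddles a fold boundary. Ties prefer the earliest grid
#' point (smaller `C`, then smaller `gamma`).
#'
#' @param x numeric feature matrix (standardized), one row per segment.
#' @param y class labels (character or factor over mild/moderate/severe).
#' @param groups participant id per row (for grouped folds).
#' @param C_grid,gamma_grid hyperparameter grids; the defaults span 0.1-10
#'   and 0.001-0.1 and include C = 1, gamma = 0.01.
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment only; fitting is deterministic).
#' @return object of class `pcg_svm` with the refit model and a `cv` table.
#' @export
tune_svm <- function(x, y, groups, C_grid = c(0.1, 0.32, 1, 3.2, 10),
                     gamma_grid = c(0.001, 0.0032, 0.01, 0.032, 0.1),
                     folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = intersect(PCG_CLASSES, unique(as.character(y))))
  if (nlevels(y) < 2L) stop("training data contains a single class")
  part <- unique(groups)
  part_lab <- vapply(part, function(p) as.character(y[groups == p][1]), character(1))
  fold_of_part <- make_cv_folds(part, part_lab, folds, seed)
  fold <- fold_of_part[groups]

  grid <- expand.grid(C = C_grid, gamma = gamma_grid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  acc <- matrix(NA_real_, nrow(grid), folds)
  D2 <- dist_sq(x, x)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) next
    for (gi in seq_len(nrow(grid))) {
      K <- exp(-grid$gamma[gi] * D2[tr, tr, drop = FALSE])
      Kt <- exp(-grid$gamma[gi] * D2[te, tr, drop = FALSE])
      bins <- train_svm_ovr(K, droplevels(y[tr]), grid$C[gi])
      dec <- svm_decision(bins, Kt)
      pred <- vapply(bins, function(b) b$class, character(1))[max.col(dec, ties.method = "first")]
      acc[gi, f] <- mean(pred == as.character(y[te]))
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- which.max(mean_acc)  # first max wins ties
  K_full <- exp(-grid$gamma[best] * D2)
  bins <- train_svm_ovr(K_full, y, grid$C[best])
  out <- list(x_train = x, classes = levels(y), binaries = bins,
              C = grid$C[best], gamma = grid$gamma[best],
              cv = cbind(grid, cv_accuracy = mean_acc))
  class(out) <- "pcg_svm"
  pcg_log("tune_svm: C = %g, gamma = %g (cv acc %.3f)", out$C, out$gamma, mean_acc[best])
  out
}

#' @export
predict.pcg_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  Kt <- rbf_kernel(as.matrix(newdata), object$x_train, object$gamma)
  dec <- svm_decision(object$binaries, Kt)
  colnames(dec) <- object$classes
  if (type == "decision") return(dec)
  object$classes[max.col(dec, ties.method = "first")]
}

#' Tune and fit the gradient-boosted tree classifier
#'
#' Softmax (multiclass) boosting with second-order leaf weights, shrinkage
#' and per-round row subsampling, tuned by grid search over estimator count,
#' learning rate, depth and subsample ratio under the same grouped,
#' stratified five-fold CV as [tune_svm()]. Estimator counts are evaluated
#' as staged checkpoints of a single boosting run per configuration.
#'
#' @param x numeric feature matrix, one row per segment.
#' @param y class labels.
#' @param groups participant id per row.
#' @param n_grid,lr_grid,depth_grid,subsample_grid hyperparameter grids; the
#'   defaults cover 100-500 estimators, learning rate 0.01-0.1, depth 3-7
#'   and subsample 0.7-1.0.
#' @param folds number of CV folds.
#' @param seed integer seed controlling fold assignment and subsampling.
#' @return object of class `pcg_xgb` with the refit model and a `cv` table.
#' @export
tune_xgb <- function(x, y, groups, n_grid = c(100L, 300L, 500L),
                     lr_grid = c(0.01, 0.05, 0.1), depth_grid = c(3L, 5L, 7L),
                     subsample_grid = c(0.7, 0.8, 1.0), folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = intersect(PCG_CLASSES, unique(as.character(y))))
  if (nlevels(y) < 2L) stop("training data contains a single class")
  part <- unique(groups)
  part_lab <- vapply(part, function(p) as.character(y[groups == p][1]), character(1))
  fold_of_part <- make_cv_folds(part, part_lab, folds, seed)
  fold <- fold_of_part[groups]
  yi <- as.integer(y) - 1L

  cfg <- expand.grid(lr = lr_grid, depth = depth_grid, subsample = subsample_grid,
                     KEEP.OUT.ATTRS = FALSE)
  cfg <- cfg[order(cfg$lr, cfg$depth, cfg$subsample), , drop = FALSE]
  n_max <- max(n_grid)
  cv_rows <- list()
  for (ci in seq_len(nrow(cfg))) {
    acc <- matrix(NA_real_, length(n_grid), folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      if (!any(te)) next
      fit <- gbt_train_cpp(x[tr, , drop = FALSE], yi[tr], nlevels(y), n_max,
                           cfg$lr[ci], cfg$depth[ci], cfg$subsample[ci],
                           1.0, 1.0, as.integer(seed) + 7919L * f + ci)
      for (ni in seq_along(n_grid)) {
        F <- gbt_predict_cpp(fit, x[te, , drop = FALSE], n_grid[ni])
        pred <- levels(y)[max.col(F, ties.method = "first")]
        acc[ni, f] <- mean(pred == as.character(y[te]))
      }
    }
    cv_rows[[ci]] <- data.frame(n_estimators = n_grid, lr = cfg$lr[ci],
                                depth = cfg$depth[ci], subsample = cfg$subsample[ci],
                                cv_accuracy = rowMeans(acc, na.rm = TRUE))
  }
  cv <- do.call(rbind, cv_rows)
  cv <- cv[order(cv$n_estimators, cv$lr, cv$depth, cv$subsample), , drop = FALSE]
  best <- cv[which.max(cv$cv_accuracy), ]
  fit <- gbt_train_cpp(x, yi, nlevels(y), best$n_estimators, best$lr, best$depth,
                       best$subsample, 1.0, 1.0, as.integer(seed))
  out <- list(model = fit, classes = levels(y),
              n_estimators = best$n_estimators, lr = best$lr,
              depth = best$depth, subsample = best$subsample, cv = cv)
  class(out) <- "pcg_xgb"
  pcg_log("tune_xgb: n = %d, lr = %g, depth = %d, subsample = %g (cv acc %.3f)",
          best$n_estimators, best$lr, best$depth, best$subsample, best$cv_accuracy)
  out
}

#' @export
predict.pcg_xgb <- function(object, newdata, type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  F <- gbt_predict_cpp(object$model, as.matrix(newdata))
  colnames(F) <- object$classes
  if (type == "score") return(F)
  P <- exp(F - apply(F, 1, max))
  P <- P / rowSums(P)
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Metrics from a confusion matrix
#'
#' Rows are truth, columns are prediction. Returns per-class precision,
#' recall, specificity and F1, plus accuracy, balanced accuracy and macro-F1.
#'
#' @param cm square confusion matrix with identical row/column class order.
#' @return list with `per_class` (`data.frame`) and scalar summary metrics.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  list(per_class = data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                              precision = precision, recall = recall,
                              specificity = specificity, f1 = f1, row.names = NULL),
       accuracy = sum(tp) / total,
       balanced_accuracy = mean(recall, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted classifier on held-out segments
#'
#' Builds the confusion matrix, per-class precision/recall/specificity/F1,
#' and one-vs-rest AUCs with DeLong 95% confidence intervals from the
#' class-membership scores (decision values for the SVM, softmax
#' probabilities for the boosted trees).
#'
#' @param model a `pcg_svm` or `pcg_xgb`.
#' @param x test feature matrix.
#' @param y true test labels.
#' @return object of class `pcg_report`.
#' @export
evaluate_model <- function(model, x, y) {
  if (!length(y)) stop("empty test set")
  scores <- if (inherits(model, "pcg_svm")) predict(model, x, type = "decision")
            else predict(model, x, type = "prob")
  classes <- colnames(scores)
  pred <- classes[max.col(scores, ties.method = "first")]
  y <- factor(as.character(y), levels = classes)
  cm <- table(truth = y, prediction = factor(pred, levels = classes))
  met <- confusion_metrics(cm)
  aucs <- lapply(classes, function(cl) {
    pos <- y == cl
    if (!any(pos) || all(pos)) {
      warning("class '", cl, "' missing from test labels: AUC undefined")
      return(list(auc = NA_real_, lower = NA_real_, upper = NA_real_, se = NA_real_))
    }
    delong_auc_ci(scores[, cl], pos)
  })
  names(aucs) <- classes
  out <- list(confusion = cm, per_class = met$per_class,
              accuracy = met$accuracy, balanced_accuracy = met$balanced_accuracy,
              macro_f1 = met$macro_f1,
              auc = data.frame(class = classes,
                               auc = vapply(aucs, `[[`, numeric(1), "auc"),
                               ci_lower = vapply(aucs, `[[`, numeric(1), "lower"),
                               ci_upper = vapply(aucs, `[[`, numeric(1), "upper"),
                               row.names = NULL),
              scores = scores, predictions = pred, truth = as.character(y))
  class(out) <- "pcg_report"
  out
}

#' @export
print.pcg_report <- function(x, ...) {
  cat(sprintf("<pcg_report> accuracy %.4f, balanced %.4f, macro-F1 %.4f\n",
              x$accuracy, x$balanced_accuracy, x$macro_f1))
  print(x$confusion)
  print(cbind(x$per_class, auc = x$auc$auc))
  invisible(x)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate, preprocess (resample/normalize/denoise), detect S2, extract
#' diastoles, decompose with the EWT, compute features, split by
#' participant, standardize on the training side only, tune SVM and boosted
#' trees, and evaluate both on the held-out participants, including a
#' per-class DeLong comparison of the two models. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [default_config()] list.
#' @param models which classifiers to run (default both).
#' @param cohort_spec cohort composition passed to [simulate_cohort()].
#' @param cohort optionally, an existing cohort (as from [simulate_cohort()])
#'   to analyze instead of simulating one.
#' @return list with `features` (per-segment table), `split`, per-model
#'   `pcg_report`s, `delong` comparison table, and segment counts.
#' @export
run_pipeline <- function(config = default_config(), models = c("svm", "xgb"),
                         cohort_spec = default_cohort_spec(), cohort = NULL) {
  seed <- as.integer(config$seed)
  if (is.null(cohort))
    cohort <- simulate_cohort(spec = cohort_spec, params = config$sim, seed = seed)
  feats <- extract_cohort_features(cohort, config)
  counts <- list(participants = nrow(cohort$manifest), segments = nrow(feats))

  sc <- config$classify
  split <- participant_split(cohort$manifest, sc$train_n, sc$test_n, seed = seed + 1L,
                             test_class_counts = sc$test_class_counts)
  tr <- feats[feats$participant_id %in% split$train_ids, ]
  te <- feats[feats$participant_id %in% split$test_ids, ]
  counts$train_segments <- nrow(tr); counts$test_segments <- nrow(te)

  feat_cols <- c("e1", "e2", "e3", "P1", "P2")
  std <- fit_standardizer(tr, feat_cols)
  trs <- apply_standardizer(std, tr)
  tes <- apply_standardizer(std, te)
  x_tr <- as.matrix(trs[feat_cols]); x_te <- as.matrix(tes[feat_cols])

  out <- list(features = feats, split = split, counts = counts, standardizer = std)
  if ("svm" %in% models) {
    svm <- tune_svm(x_tr, trs$label, trs$participant_id, sc$svm_C_grid,
                    sc$svm_gamma_grid, sc$cv_folds, seed = seed + 2L)
    out$svm <- svm
    out$report_svm <- evaluate_model(svm, x_te, tes$label)
  }
  if ("xgb" %in% models) {
    xgb <- tune_xgb(x_tr, trs$label, trs$participant_id, sc$xgb_n_grid,
                    sc$xgb_lr_grid, sc$xgb_depth_grid, sc$xgb_subsample_grid,
                    sc$cv_folds, seed = seed + 3L)
    out$xgb <- xgb
    out$report_xgb <- evaluate_model(xgb, x_te, tes$label)
  }
  if (all(c("svm", "xgb") %in% models)) {
    classes <- out$report_svm$auc$class
    out$delong <- do.call(rbind, lapply(classes, function(cl) {
      pos <- out$report_svm$truth == cl
      if (!any(pos) || all(pos)) return(NULL)
      t <- delong_auc_test(out$report_svm$scores[, cl], out$report_xgb$scores[, cl], pos)
      data.frame(class = cl, auc_svm = t$auc_a, auc_xgb = t$auc_b,
                 z = t$statistic, p_value = t$p_value)
    }))
  }
  out
}

#' Extract the per-segment feature table for a whole cohort
#'
#' The preprocessing + segmentation + EWT + feature stages of the pipeline,
#' applied record by record.
#'
#' @param cohort result of [simulate_cohort()] (or a compatible list with
#'   `manifest` and `records`).
#' @param config a [default_config()] list.
#' @return `data.frame` with one row per retained diastole: provenance,
#'   `e1`, `e2`, `e3`, `P1`, `P2`, `stenosis_pct`, `label`.
#' @export
extract_cohort_features <- function(cohort, config = default_config()) {
  sc <- config$segmentation
  bank <- ewt_filter_bank(config$preprocess$target_fs, config$ewt$boundaries_hz,
                          config$ewt$tau_over_pi * pi, config$ewt$nfft)
  rows <- list()
  for (i in seq_len(nrow(cohort$manifest))) {
    id <- cohort$manifest$participant_id[i]
    rec <- preprocess_pcg(cohort$records[[id]], config)
    r_times <- if (isTRUE(sc$use_r_times)) rec$r_times else NULL
    s2 <- detect_s2(rec, r_times, config)
    segs <- extract_diastoles(rec, s2, n_keep = sc$n_keep,
                              offset = sc$diastole_offset_s,
                              duration = sc$diastole_duration_s)
    if (!ncol(segs$segments)) next
    fr <- do.call(rbind, lapply(seq_len(ncol(segs$segments)), function(k) {
      compute_features(ewt_decompose(segs$segments[, k], bank),
                       participant_id = id, cycle_index = segs$meta$cycle_index[k])
    }))
    fr$stenosis_pct <- cohort$manifest$stenosis_pct[i]
    fr$label <- cohort$manifest$label[i]
    rows[[length(rows) + 1L]] <- fr
  }
  out <- do.call(rbind, rows)
  pcg_log("extract_cohort_features: %d segments from %d records",
          nrow(out), nrow(cohort$manifest))
  out
}
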