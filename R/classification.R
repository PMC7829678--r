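#' Pipeline configuration
#'
#' Tunable parameters of the nested selection + classification pipeline.
#' The SVM grids are the conventional powers-of-two grids of the underlying
#' libsvm toolkit.
#'
#' @param k_anchors number of impaired subregions anchoring the candidate
#'   pool, default 15.
#' @param anchor_alpha significance level of the anchor-selection tests.
#' @param lambda1,lambda2,n_components sparse CCA parameters, see
#'   [l1_scca_fit()].
#' @param svm_C_grid,svm_gamma_grid RBF-SVM grid-search values.
#' @param inner_folds inner cross-validation folds of the grid search.
#' @param inner_seed seed of the stratified inner splits (recorded in the
#'   report).
#' @param band ALFF band in Hz.
#' @param slr_a0 relevance hyperprior shape of the per-fold sparse logistic
#'   stage; 0 (the plain evidence update) leaves every connection with
#'   genuine evidence in the fold's survivor set, so the across-fold
#'   repeat-time ranking separates recurrent signal from sporadic noise.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_anchors = 15, anchor_alpha = 0.05,
                            lambda1 = 1, lambda2 = NULL, n_components = 3,
                            svm_C_grid = 2^seq(-5, 15, 2),
                            svm_gamma_grid = 2^seq(-15, 3, 2),
                            inner_folds = 5, inner_seed = 42,
                            band = c(0.01, 0.08), slr_a0 = 0) {
  structure(list(k_anchors = k_anchors, anchor_alpha = anchor_alpha,
                 lambda1 = lambda1, lambda2 = lambda2,
                 n_components = n_components, svm_C_grid = svm_C_grid,
                 svm_gamma_grid = svm_gamma_grid, inner_folds = inner_folds,
                 inner_seed = inner_seed, band = band, slr_a0 = slr_a0),
            class = "pipeline_config")
}

# Stratified fold assignment: within each class, shuffled cyclic fold ids.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

# Decision score oriented so larger values favour the positive class.
svm_decision_score <- function(model, X, positive = "1") {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sides <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  s <- as.vector(dv[, 1])
  if (sides[1] == positive) s else -s
}

#' RBF-SVM with grid search over (C, gamma)
#'
#' Fits a radial-basis-function SVM at every grid point, scores each by
#' stratified `inner_folds`-fold cross-validated accuracy on the training
#' set, and refits the best point on the full training set. Ties go to the
#' smallest C, then the smallest gamma. When a class has fewer members than
#' `inner_folds`, the inner fold count is reduced (with a warning).
#'
#' @param X training feature matrix.
#' @param y binary 0/1 labels.
#' @param C_grid,gamma_grid grids of cost and kernel-width values.
#' @param inner_folds inner CV folds, default 5.
#' @param seed seed of the stratified inner splits.
#' @return list with `model` (e1071 svm fit), `C`, `gamma`, `cv_accuracy`.
#' @export
grid_search_svm <- function(X, y, C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            inner_folds = 5, seed = 42) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(0, 1))
  if (length(unique(y)) < 2) stop("training set has a single class",
                                  call. = FALSE)
  min_class <- min(table(y))
  k <- inner_folds
  if (min_class < k) {
    k <- max(2, min_class)
    warning(sprintf("inner folds reduced to %d (smallest class has %d)",
                    k, min_class), call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  C_grid <- sort(C_grid); gamma_grid <- sort(gamma_grid)
  best <- list(acc = -Inf, C = NA, gamma = NA)
  for (C in C_grid) for (g in gamma_grid) {
    correct <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = C, gamma = g, scale = FALSE)
      pr <- predict(m, X[!tr, , drop = FALSE])
      correct <- correct + sum(pr == yf[!tr])
    }
    acc <- correct / length(y)
    if (acc > best$acc) best <- list(acc = acc, C = C, gamma = g)
  }
  model <- e1071::svm(X, yf, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
  list(model = model, C = best$C, gamma = best$gamma,
       cv_accuracy = best$acc)
}

#' Per-subject inputs shared by all folds
#'
#' Standardized regional ALFF and the functional connectivity matrix for
#' every subject. Both are single-subject transforms, so computing them once
#' before the outer loop leaks no category information across folds.
#'
#' @param dataset region-level `study_dataset`.
#' @param band ALFF band, Hz.
#' @return list with `alff` (R x N) and `fc` (list of R x R matrices).
#' @export
precompute_pipeline_inputs <- function(dataset, band = c(0.01, 0.08)) {
  list(alff = dataset_alff(dataset, band = band),
       fc = lapply(dataset$signals, build_fc_matrix))
}

#' One outer fold of the nested selection pipeline
#'
#' Runs every data-dependent stage on the training subjects only: anchor
#' selection from regional ALFF, candidate-connection extraction,
#' standardization (training mean/SD), sparse CCA, ARD sparse logistic
#' regression, and SVM grid search; then predicts the held-out subject.
#' Exposed so the anti-leakage perturbation probe can re-run a single fold.
#'
#' @param pre output of [precompute_pipeline_inputs()] for the comparison
#'   subset.
#' @param subjects participants table of the comparison subset.
#' @param y binary labels (1 = patient side of the comparison).
#' @param train_idx,test_idx row indices of training and held-out subjects.
#' @param config a [pipeline_config()].
#' @return list with `anchors`, `selected_ids`, `weights`, `pred`, `score`,
#'   `C`, `gamma`, `failed`, `failure_reason`.
#' @export
run_selection_fold <- function(pre, subjects, y, train_idx, test_idx,
                               config = pipeline_config()) {
  fail <- function(reason) list(anchors = integer(), selected_ids = character(),
                                weights = numeric(), pred = NA, score = NA,
                                C = NA, gamma = NA, failed = TRUE,
                                failure_reason = reason)
  groups <- ifelse(y == 1, "patient", "control")
  anchors <- select_anchors_regional(pre$alff[, train_idx, drop = FALSE],
                                     groups[train_idx],
                                     k = config$k_anchors,
                                     alpha = config$anchor_alpha)
  if (length(anchors) == 0) return(fail("no significant anchor regions"))
  cf <- extract_candidate_features(pre$fc, anchors)
  X2 <- cf$X
  mu <- colMeans(X2[train_idx, , drop = FALSE])
  sg <- apply(X2[train_idx, , drop = FALSE], 2, sd)
  sg[sg == 0] <- 1
  X2s <- sweep(sweep(X2, 2, mu), 2, sg, "/")
  X1 <- cbind(diagnosis = y, age = subjects$age, sex = subjects$sex)
  sols <- l1_scca_fit(X1[train_idx, , drop = FALSE],
                      X2s[train_idx, , drop = FALSE],
                      lambda1 = config$lambda1, lambda2 = config$lambda2,
                      n_components = config$n_components)
  pick <- choose_diagnosis_component(sols)
  if (length(pick$selected) == 0) return(fail("SCCA selected no connections"))
  scca_cols <- pick$selected
  slr <- slr_fit(X2s[train_idx, scca_cols, drop = FALSE], y[train_idx],
                 a0 = config$slr_a0)
  if (length(slr$selected) == 0 && config$slr_a0 > 0) {
    # the sparsity-promoting update found no evidence for any connection;
    # retry with the plain evidence update before declaring the fold empty
    slr <- slr_fit(X2s[train_idx, scca_cols, drop = FALSE], y[train_idx],
                   a0 = 0)
  }
  if (length(slr$selected) == 0) return(fail("SLR pruned every connection"))
  final_cols <- scca_cols[slr$selected]
  ids <- cf$pairs$id[final_cols]
  w <- setNames(slr$weights[slr$selected], ids)
  gs <- grid_search_svm(X2s[train_idx, final_cols, drop = FALSE],
                        y[train_idx],
                        C_grid = config$svm_C_grid,
                        gamma_grid = config$svm_gamma_grid,
                        inner_folds = config$inner_folds,
                        seed = config$inner_seed)
  Xte <- X2s[test_idx, final_cols, drop = FALSE]
  pred <- as.integer(as.character(
    predict(gs$model, Xte)))
  score <- svm_decision_score(gs$model, Xte)
  list(anchors = anchors, selected_ids = ids, weights = w,
       pred = pred, score = score, C = gs$C, gamma = gs$gamma,
       failed = FALSE, failure_reason = NA_character_)
}

#' Nested leave-one-out evaluation of the full selection pipeline
#'
#' One outer fold per subject of the comparison: all data-dependent stages
#' (anchor selection, candidate extraction, standardization, sparse CCA,
#' ARD logistic regression, SVM grid search) are recomputed on the
#' remaining subjects, and the held-out subject is predicted. A fold whose
#' selection comes back empty is marked failed and excluded from the
#' metrics (with a warning). Selected sets across folds feed the
#' repeat-time ranking.
#'
#' @param dataset region-level `study_dataset`.
#' @param comparison two group labels; the first is the patient (positive)
#'   class.
#' @param config a [pipeline_config()].
#' @return list of class `loocv_result`: `report` (a
#'   `classification_report`), `ranking` (a `selection_ranking`), `folds`
#'   (per-fold results), `comparison`, `subject_idx` (positions in the full
#'   dataset).
#' @export
loocv_run <- function(dataset, comparison, config = pipeline_config()) {
  stopifnot(inherits(dataset, "study_dataset"), length(comparison) == 2)
  sub_idx <- which(dataset$subjects$group %in% comparison)
  if (length(unique(dataset$subjects$group[sub_idx])) != 2 ||
      min(table(dataset$subjects$group[sub_idx])) < 2) {
    stop("both comparison groups need >= 2 subjects", call. = FALSE)
  }
  subjects <- dataset$subjects[sub_idx, , drop = FALSE]
  y <- as.integer(subjects$group == comparison[1])
  sub_data <- study_dataset(subjects, dataset$signals[sub_idx],
                            tr = dataset$tr)
  pre <- precompute_pipeline_inputs(sub_data, band = config$band)
  n <- length(sub_idx)
  folds <- vector("list", n)
  for (f in seq_len(n)) {
    folds[[f]] <- run_selection_fold(pre, subjects, y,
                                     train_idx = setdiff(seq_len(n), f),
                                     test_idx = f, config = config)
    folds[[f]]$held_out <- f
  }
  failed <- vapply(folds, function(fr) fr$failed, logical(1))
  if (any(failed)) {
    warning(sprintf("%d of %d folds failed and were excluded from metrics",
                    sum(failed), n), call. = FALSE)
  }
  ok <- !failed
  pred <- vapply(folds, function(fr) as.numeric(fr$pred[1]), numeric(1))
  score <- vapply(folds, function(fr) as.numeric(fr$score[1]), numeric(1))
  report <- classification_report(y[ok], pred[ok], score[ok])
  report$n_failed_folds <- sum(failed)
  report$inner_seed <- config$inner_seed
  ranking <- rank_by_repeat_times(
    lapply(folds[ok], function(fr) fr$selected_ids),
    lapply(folds[ok], function(fr) fr$weights))
  structure(list(report = report, ranking = ranking, folds = folds,
                 comparison = comparison, subject_idx = sub_idx),
            class = "loocv_result")
}

#' Leave-one-out evaluation with a fixed connection set
#'
#' Evaluation protocol for a predetermined feature set: the connections are
#' fixed in advance, and only standardization and SVM training are redone
#' per fold.
#'
#' @param dataset region-level `study_dataset`.
#' @param pairs data.frame with columns `i`, `j` (or a character vector of
#'   pair ids like "5-12").
#' @param comparison two group labels, patient class first.
#' @param config a [pipeline_config()].
#' @return a `classification_report`.
#' @export
fixed_feature_evaluate <- function(dataset, pairs, comparison,
                                   config = pipeline_config()) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.character(pairs)) {
    ij <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
    pairs <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
  }
  if (nrow(pairs) == 0) stop("connection set is empty", call. = FALSE)
  sub_idx <- which(dataset$subjects$group %in% comparison)
  subjects <- dataset$subjects[sub_idx, , drop = FALSE]
  y <- as.integer(subjects$group == comparison[1])
  fc <- lapply(dataset$signals[sub_idx], build_fc_matrix)
  R <- nrow(fc[[1]])
  lin <- (pmax(pairs$i, pairs$j) - 1L) * R + pmin(pairs$i, pairs$j)
  X <- t(vapply(fc, function(C) C[lin], numeric(length(lin))))
  if (length(lin) == 1) X <- matrix(X, ncol = 1)
  n <- length(y)
  pred <- numeric(n); score <- numeric(n)
  for (f in seq_len(n)) {
    tr <- setdiff(seq_len(n), f)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd); sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    gs <- grid_search_svm(Xs[tr, , drop = FALSE], y[tr],
                          C_grid = config$svm_C_grid,
                          gamma_grid = config$svm_gamma_grid,
                          inner_folds = config$inner_folds,
                          seed = config$inner_seed)
    Xte <- Xs[f, , drop = FALSE]
    pred[f] <- as.integer(as.character(predict(gs$model, Xte)))
    score[f] <- svm_decision_score(gs$model, Xte)
  }
  classification_report(y, pred, score)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic over the decision scores (ties counted half).
#'
#' @param scores decision scores, larger favouring the positive class.
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`, NA when a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve from pooled decision scores.
roc_points <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

#' Classification metrics from confusion counts and scores
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from the
#' confusion counts, plus rank-statistic AUC and ROC points when pooled
#' decision scores are supplied. A rate with a zero denominator is reported
#' as NA (undefined), never 0. `as_percent()` on the result formats the
#' rates to one decimal.
#'
#' @param tp,fn,fp,tn confusion counts (positive class = patient group).
#' @param scores optional pooled decision scores.
#' @param labels optional 0/1 labels parallel to `scores`.
#' @return list of class `classification_report`.
#' @export
compute_metrics <- function(tp, fn, fp, tn, scores = NULL, labels = NULL) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  n <- tp + fn + fp + tn
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rate(tp, tp + fp)
  recall <- rate(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(tp = tp, fn = fn, fp = fp, tn = tn, n = n,
              accuracy = (tp + tn) / n,
              precision = precision, recall = recall,
              specificity = rate(tn, tn + fp), f1 = f1,
              auc = if (!is.null(scores)) auc_rank(scores, labels) else NA,
              roc = if (!is.null(scores)) roc_points(scores, labels) else
                NULL)
  class(out) <- "classification_report"
  out
}

# Report from pooled held-out predictions and scores.
classification_report <- function(y, pred, scores) {
  compute_metrics(tp = sum(pred == 1 & y == 1),
                  fn = sum(pred == 0 & y == 1),
                  fp = sum(pred == 1 & y == 0),
                  tn = sum(pred == 0 & y == 0),
                  scores = scores, labels = y)
}

#' Percent-formatted metrics
#' @param report a `classification_report`.
#' @return named numeric vector of percentages rounded to 1 decimal.
#' @export
as_percent <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  v <- c(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, specificity = report$specificity,
         f1 = report$f1)
  round(100 * v, 1)
}

#' @export
print.classification_report <- function(x, ...) {
  pc <- as_percent(x)
  cat(sprintf("<classification_report> n = %d | TP %d FN %d FP %d TN %d\n",
              x$n, x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  accuracy %.1f%% precision %.1f%% recall %.1f%% ",
              pc["accuracy"], pc["precision"], pc["recall"]))
  cat(sprintf("specificity %.1f%% F1 %.1f%% AUC %.3f\n",
              pc["specificity"], pc["f1"], x$auc))
  invisible(x)
}
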