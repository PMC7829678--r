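test_that("the SVM grid search is deterministic and fits separable data", {
  set.seed(1)
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  g1 <- grid_search_svm(x, y, C_grid = 2^seq(-3, 7, 2),
                        gamma_grid = 2^seq(-7, 1, 2))
  g2 <- grid_search_svm(x, y, C_grid = 2^seq(-3, 7, 2),
                        gamma_grid = 2^seq(-7, 1, 2))
  expect_equal(g1$cv_accuracy, 1)
  expect_identical(c(g1$C, g1$gamma), c(g2$C, g2$gamma))
  expect_error(grid_search_svm(x, rep(1, 40)), "single class")
})

test_that("permuted labels give chance-level inner CV accuracy", {
  set.seed(5)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(40 * 3), 40)
    y <- sample(rep(c(0, 1), each = 20))
    grid_search_svm(x, y, C_grid = 2^c(-1, 3), gamma_grid = 2^c(-3, 0),
                    seed = s)$cv_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.72)
})

test_that("confusion metrics reproduce the published worked examples", {
  # patient-vs-control comparison with 19 patients and 39 controls
  r1 <- compute_metrics(tp = 16, fn = 3, fp = 1, tn = 38)
  expect_equal(unname(as_percent(r1)),
               c(93.1, 94.1, 84.2, 97.4, 88.9))
  # 31 patients vs 39 controls
  r2 <- compute_metrics(tp = 28, fn = 3, fp = 5, tn = 34)
  p2 <- as_percent(r2)
  expect_equal(unname(p2[c("accuracy", "precision", "recall",
                           "specificity", "f1")]),
               c(88.6, 84.8, 90.3, 87.2, 87.5))
})

test_that("undefined rates are NA rather than zero", {
  r <- compute_metrics(tp = 0, fn = 0, fp = 0, tn = 10)
  expect_true(is.na(r$precision))
  expect_true(is.na(r$recall))
  expect_equal(r$accuracy, 1)
})

test_that("rank AUC matches the exhaustive pair oracle and pROC", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # rounding forces occasional ties
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels))
  }
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.7, 0.2)
  labels <- c(1, 1, 0, 0, 1, 0)
  expect_equal(auc_rank(scores, labels), 1)
  expect_equal(auc_rank(-scores, labels), 0)
  p <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(auc_rank(scores, labels), as.numeric(p))
})

test_that("outer folds equal the comparison sample size and stay leak-free", {
  ds <- planted_small_dataset(seed = 5)
  res <- suppressWarnings(loocv_run(ds, c("T2DM-CI", "HC"), fast_config()))
  expect_length(res$folds, 16)
  expect_equal(res$report$n, 16 - res$report$n_failed_folds)
  # perturbing only the held-out subject leaves each fold's selection alone
  y <- as.integer(ds$subjects$group == "T2DM-CI")
  pre <- precompute_pipeline_inputs(ds)
  for (f in c(1, 9, 16)) {
    ds2 <- ds
    set.seed(100 + f)
    ds2$signals[[f]] <- ds2$signals[[f]] +
      matrix(rnorm(length(ds2$signals[[f]]), sd = 2),
             nrow = nrow(ds2$signals[[f]]))
    pre2 <- precompute_pipeline_inputs(ds2)
    tr <- setdiff(1:16, f)
    r1 <- suppressWarnings(run_selection_fold(pre, ds$subjects, y, tr, f,
                                              fast_config()))
    r2 <- suppressWarnings(run_selection_fold(pre2, ds2$subjects, y, tr, f,
                                              fast_config()))
    expect_identical(r1$selected_ids, r2$selected_ids)
    expect_identical(r1$anchors, r2$anchors)
    expect_identical(c(r1$C, r1$gamma), c(r2$C, r2$gamma))
  }
})

test_that("fixed planted connections classify strongly; null stays at chance", {
  ds <- planted_small_dataset(seed = 5)
  rep1 <- fixed_feature_evaluate(ds, "3-22", c("T2DM-CI", "HC"),
                                 fast_config())
  expect_gte(rep1$auc, 0.95)
  aucs <- vapply(c(21, 22), function(s) {
    dn <- null_small_dataset(seed = s)
    fixed_feature_evaluate(dn, c("1-5", "2-9"), c("T2DM-CI", "HC"),
                           fast_config())$auc
  }, numeric(1))
  expect_true(all(aucs >= 0.15 & aucs <= 0.85))
  expect_error(fixed_feature_evaluate(ds, character(0),
                                      c("T2DM-CI", "HC")), "empty")
})

test_that("group subsets too small for LOOCV are rejected", {
  ds <- planted_small_dataset(seed = 5)
  ds$subjects$group[16] <- "T2DM-NC"  # a single NC subject
  expect_error(loocv_run(ds, c("T2DM-CI", "T2DM-NC")), ">= 2 subjects")
})
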