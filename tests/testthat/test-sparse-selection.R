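test_that("SCCA solutions satisfy all four constraints", {
  set.seed(1)
  for (i in 1:5) {
    X1 <- cbind(rbinom(30, 1, 0.5), rnorm(30, 60, 7), rbinom(30, 1, 0.5))
    X2 <- matrix(rnorm(30 * 40), 30)
    l1 <- 1 + runif(1); l2 <- 1 + 4 * runif(1)
    sols <- l1_scca_fit(X1, X2, lambda1 = l1, lambda2 = l2,
                        n_components = 3)
    for (s in sols) {
      expect_lte(sqrt(sum(s$v1^2)), 1 + 1e-8)
      expect_lte(sqrt(sum(s$v2^2)), 1 + 1e-8)
      expect_lte(sum(abs(s$v1)), l1 + 1e-8)
      expect_lte(sum(abs(s$v2)), l2 + 1e-8)
    }
  }
})

test_that("with inactive constraints SCCA matches the closed-form CCA pair", {
  set.seed(2)
  N <- 40
  X1 <- qr.Q(qr(matrix(rnorm(N * 2), N)))
  raw <- matrix(rnorm(N * 2), N)
  raw[, 1] <- raw[, 1] + 2 * X1[, 1]
  X2 <- qr.Q(qr(raw))
  sol <- l1_scca_fit(X1, X2, lambda1 = 2, lambda2 = 2,
                     n_components = 1)[[1]]
  # eigen-decomposition oracle on the same centered/scaled cross-product
  s1 <- apply(X1, 2, sd); s2 <- apply(X2, 2, sd)
  Z <- crossprod(scale(X1, scale = s1), scale(X2, scale = s2))
  e1 <- eigen(Z %*% t(Z))$vectors[, 1]
  e2 <- eigen(t(Z) %*% Z)$vectors[, 1]
  expect_equal(abs(sum(sol$v1 * e1)), 1, tolerance = 1e-6)
  expect_equal(abs(sum(sol$v2 * e2)), 1, tolerance = 1e-6)
  expect_equal(sol$objective, svd(Z)$d[1], tolerance = 1e-6)
})

test_that("a single diagnosis-correlated column is found one-hot", {
  set.seed(3)
  y <- rep(c(0, 1), each = 25)
  X2 <- matrix(rnorm(50 * 30), 50)
  X2[, 17] <- X2[, 17] + 3 * y
  X1 <- cbind(y, rnorm(50, 60, 7), rbinom(50, 1, 0.5))
  sols <- l1_scca_fit(X1, X2, lambda1 = 1, lambda2 = 1, n_components = 3)
  pick <- choose_diagnosis_component(sols)
  expect_equal(pick$selected, 17L)
  expect_equal(which(abs(pick$solution$v1) > 1e-8), 1L)
})

test_that("a zero cross-product is flagged degenerate", {
  X1 <- matrix(rep(c(0, 1), 10), ncol = 1)
  X2 <- matrix(0, 20, 5)
  s <- l1_scca_fit(X1, X2, lambda1 = 1, lambda2 = 1, n_components = 1)[[1]]
  expect_true(s$degenerate)
  expect_equal(s$objective, 0)
})

test_that("the SCCA objective trace is non-decreasing", {
  set.seed(4)
  X1 <- cbind(rbinom(25, 1, 0.5), rnorm(25), rbinom(25, 1, 0.5))
  X2 <- matrix(rnorm(25 * 60), 25)
  sols <- l1_scca_fit(X1, X2, lambda1 = 1.2, lambda2 = 3,
                      n_components = 2)
  for (s in sols) {
    expect_true(all(diff(s$trace) >= -1e-8))
  }
})

test_that("the diagnosis-only component is chosen by its v1 support", {
  mk <- function(v1, comp) structure(
    list(v1 = v1, v2 = c(0.5, 0.5), objective = 1, lambda1 = 1,
         lambda2 = 1, component = comp, iterations = 1, converged = TRUE,
         degenerate = FALSE, trace = 1), class = "scca_solution")
  # {Diagnosis}, {age}: first chosen
  p1 <- choose_diagnosis_component(list(mk(c(1, 0, 0), 1),
                                        mk(c(0, 1, 0), 2)))
  expect_equal(p1$solution$component, 1)
  # {Diagnosis, age}, {Diagnosis}: second chosen
  p2 <- choose_diagnosis_component(list(mk(c(0.7, 0.3, 0), 1),
                                        mk(c(1, 0, 0), 2)))
  expect_equal(p2$solution$component, 2)
  # none qualifying: fallback fires with a warning
  expect_warning(
    p3 <- choose_diagnosis_component(list(mk(c(0.9, 0.1, 0), 1),
                                          mk(c(0.2, 0.8, 0), 2))),
    "falling back")
  expect_equal(p3$solution$component, 1)
})

test_that("ARD retains a planted feature and prunes the noise", {
  kept <- 0L; pruned_enough <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- scale(matrix(rnorm(100 * 50), 100))
    y <- rbinom(100, 1, plogis(2.5 * X[, 13]))  # single-feature t >> 5
    m <- slr_fit(X, y)
    if (13 %in% m$selected) kept <- kept + 1L
    if (length(setdiff(m$selected, 13)) <= 5) pruned_enough <- pruned_enough + 1L
  }
  expect_gte(kept, 18)           # >= 90% of runs
  expect_gte(pruned_enough, 18)  # >= 45 of 50 noise features pruned
})

test_that("ARD selects nothing when labels are independent of features", {
  near_empty <- 0L
  for (s in 1:20) {
    set.seed(200 + s)
    X <- scale(matrix(rnorm(100 * 50), 100))
    y <- rbinom(100, 1, 0.5)
    m <- slr_fit(X, y)
    if (length(m$selected) <= 2) near_empty <- near_empty + 1L
  }
  expect_gte(near_empty, 18)
})

test_that("planted multi-feature support is recovered as a superset", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    X <- scale(matrix(rnorm(100 * 40), 100))
    y <- rbinom(100, 1, plogis(2 * X[, 5] + 2 * X[, 9] - 2 * X[, 30]))
    m <- slr_fit(X, y)
    if (all(c(5, 9, 30) %in% m$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("degenerate SLR inputs are handled by the prior", {
  # all-zero features: everything pruned, bias carries the class rate
  m0 <- slr_fit(matrix(0, 30, 4), rep(c(0, 1), 15))
  expect_length(m0$selected, 0)
  expect_equal(unname(m0$weights), rep(0, 4))
  expect_equal(plogis(m0$bias), 0.5, tolerance = 0.05)
  # complete separation on one feature stays bounded
  x <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  ms <- slr_fit(x, c(rep(0, 10), rep(1, 10)))
  expect_true(all(is.finite(ms$weights)))
  expect_lt(max(abs(ms$weights)), 100)
  expect_error(slr_fit(matrix(c(1, NaN), 2, 1), c(0, 1)), "NaN")
})

test_that("SLR predictions follow the logistic closed form", {
  m <- structure(list(weights = 1, bias = 0), class = "slr_model")
  expect_equal(slr_predict(m, log(3)), 0.75)
  m0 <- structure(list(weights = c(0, 0), bias = 0), class = "slr_model")
  expect_equal(slr_predict(m0, c(5, -2)), 0.5)
  # monotone in the linear score, saturating at 1
  mbig <- structure(list(weights = 2, bias = 0), class = "slr_model")
  ps <- slr_predict(mbig, matrix(seq(-5, 40, by = 5), ncol = 1))
  expect_true(all(diff(ps) >= 0))
  expect_gt(ps[length(ps)], 1 - 1e-10)
  expect_error(slr_predict(m0, c(1, 2, 3)), "dimension mismatch")
})

test_that("repeat-time ranking orders by count, weight, then pair", {
  folds <- c(rep(list(c("3-22", "5-9")), 37), rep(list("3-22"), 21))
  r <- rank_by_repeat_times(folds)
  expect_equal(r$id, c("3-22", "5-9"))
  expect_equal(r$repeat_times, c(58L, 37L))
  # tie on count: higher mean |weight| first
  w <- list(c("1-2" = 0.1, "1-3" = 0.9), c("1-2" = 0.1, "1-3" = 0.9))
  f <- list(c("1-2", "1-3"), c("1-2", "1-3"))
  expect_equal(rank_by_repeat_times(f, w)$id, c("1-3", "1-2"))
  # tie on both: lexicographic pair order
  f2 <- list(c("10-12", "2-3"))
  expect_equal(rank_by_repeat_times(f2)$id, c("2-3", "10-12"))
  expect_equal(nrow(rank_by_repeat_times(list(character(0)))), 0)
})

test_that("the connection-count sweep picks the smallest best k", {
  ranking <- rank_by_repeat_times(list(paste0(1:6, "-", 7:12)))
  acc <- c(0.6, 0.7, 0.9, 0.9, 0.85, 0.9)
  ev <- function(ids) acc[length(ids)]
  sw <- sweep_num_connections(ranking, 6, ev)
  expect_equal(sw$chosen_k, 3)  # ties at k = 3, 4, 6 resolve to 3
  expect_equal(sw$best_accuracy, 0.9)
  # evaluator failure invalidates the entry but the sweep continues
  ev2 <- function(ids) if (length(ids) == 2) stop("boom") else
    acc[length(ids)]
  sw2 <- sweep_num_connections(ranking, 6, ev2)
  expect_false(sw2$curve$valid[2])
  expect_equal(sw2$chosen_k, 3)
  sw1 <- sweep_num_connections(ranking, 1, ev)
  expect_equal(nrow(sw1$curve), 1)
})

test_that("accuracy plateaus at the planted connection count", {
  ds <- planted_small_dataset(seed = 31, n_per_group = 10)
  res <- suppressWarnings(loocv_run(ds, c("T2DM-CI", "HC"), fast_config()))
  expect_gte(nrow(res$ranking), 1)
  k_max <- min(4, nrow(res$ranking))
  ev <- function(ids) {
    suppressWarnings(
      fixed_feature_evaluate(ds, ids, c("T2DM-CI", "HC"),
                             fast_config())$accuracy)
  }
  sw <- sweep_num_connections(res$ranking, k_max, ev)
  expect_gte(sw$best_accuracy, 0.9)
  expect_lte(sw$chosen_k, 3)
})

test_that("the PCA baseline sweeps principal-component scores", {
  set.seed(12)
  X <- matrix(rnorm(30 * 20), 30)
  ev <- function(S) 0.5 + 0.01 * ncol(S)
  sw <- sweep_pca_baseline(X, 5, ev)
  expect_equal(sw$chosen_k, 5)
  expect_equal(nrow(sw$curve), 5)
})
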