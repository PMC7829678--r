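# Project a vector onto {v : ||v||_2 <= 1, ||v||_1 <= c} in the penalized
# matrix decomposition sense: v = S(a, delta) / ||S(a, delta)||_2 with the
# smallest soft threshold delta >= 0 meeting the L1 bound (bisection).
soft_threshold <- function(a, delta) sign(a) * pmax(abs(a) - delta, 0)

l1_l2_project <- function(a, c) {
  if (all(a == 0)) return(a)
  v <- a / sqrt(sum(a^2))
  if (sum(abs(v)) <= c) return(v)
  lo <- 0; hi <- max(abs(a))
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    sv <- soft_threshold(a, mid)
    if (all(sv == 0)) { hi <- mid; next }
    sv <- sv / sqrt(sum(sv^2))
    if (sum(abs(sv)) > c) lo <- mid else hi <- mid
  }
  sv <- soft_threshold(a, hi)
  sv / sqrt(sum(sv^2))
}

#' Sparse canonical correlation analysis with L1 constraints
#'
#' Maximizes `v1' X1' X2 v2` subject to `||v1||_2 <= 1`, `||v2||_2 <= 1`,
#' `||v1||_1 <= lambda1`, `||v2||_1 <= lambda2`, by alternating
#' soft-threshold updates of the two projection vectors (penalized matrix
#' decomposition with bisection on the threshold); successive components are
#' obtained by rank-one deflation of the cross-product matrix. Both blocks
#' are centered and variance-scaled before fitting (the L1 constraints are
#' scale-sensitive; without scaling, a wide-ranged nuisance column such as
#' age dominates every component). Initialization is the leading right
#' singular vector, so the fit is deterministic.
#'
#' @param X1 N x p1 attribute matrix (column 1 = diagnosis 0/1, then age,
#'   sex).
#' @param X2 N x p2 connection feature matrix.
#' @param lambda1 L1 bound for v1 (>= 1), default 1.2 so that v1 is
#'   near-one-hot on a single attribute.
#' @param lambda2 L1 bound for v2 (>= 1); NULL tunes it with
#'   [scca_tune_lambda2()].
#' @param n_components number of canonical components, default 3 (one per
#'   attribute column).
#' @param tol convergence tolerance on the objective change.
#' @param max_iter maximum alternating iterations per component.
#' @return list of `scca_solution` objects, each with `v1`, `v2`,
#'   `objective`, `lambda1`, `lambda2`, `component`, `iterations`,
#'   `converged`, `degenerate`, `trace`.
#' @export
l1_scca_fit <- function(X1, X2, lambda1 = 1.2, lambda2 = NULL,
                        n_components = 3, tol = 1e-6, max_iter = 200) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  stopifnot(nrow(X1) == nrow(X2), lambda1 >= 1)
  sds1 <- apply(X1, 2, sd); sds1[sds1 == 0] <- 1
  X1c <- scale(X1, center = TRUE, scale = sds1)
  sds <- apply(X2, 2, sd); sds[sds == 0] <- 1
  X2c <- scale(X2, center = TRUE, scale = sds)
  if (is.null(lambda2)) lambda2 <- scca_tune_lambda2(X1, X2)
  stopifnot(lambda2 >= 1)
  Z <- crossprod(X1c, X2c)
  n_components <- min(n_components, ncol(X1))
  solutions <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    if (max(abs(Z)) < 1e-12) {
      solutions[[comp]] <- structure(
        list(v1 = numeric(ncol(X1)), v2 = numeric(ncol(X2)), objective = 0,
             lambda1 = lambda1, lambda2 = lambda2, component = comp,
             iterations = 0, converged = TRUE, degenerate = TRUE,
             trace = numeric(0)),
        class = "scca_solution")
      next
    }
    # alternating updates are locally convergent; restart from the leading
    # singular vector and from each row of Z, keep the best objective
    sv <- svd(Z, nu = 1, nv = 1)
    inits <- c(list(sv$v[, 1] * sign(sv$v[which.max(abs(sv$v[, 1])), 1])),
               lapply(seq_len(nrow(Z)), function(r)
                 l1_l2_project(Z[r, ], lambda2)))
    best <- NULL
    for (v2_init in inits) {
      if (all(v2_init == 0)) next
      v2 <- v2_init
      v1 <- numeric(ncol(X1))
      obj <- -Inf; trace <- numeric(0); converged <- FALSE
      for (it in seq_len(max_iter)) {
        v1 <- l1_l2_project(as.vector(Z %*% v2), lambda1)
        v2 <- l1_l2_project(as.vector(crossprod(Z, v1)), lambda2)
        new_obj <- as.numeric(t(v1) %*% Z %*% v2)
        trace <- c(trace, new_obj)
        if (is.finite(obj) && abs(new_obj - obj) < tol) {
          obj <- new_obj; converged <- TRUE; break
        }
        obj <- new_obj
      }
      if (is.null(best) || obj > best$objective) {
        best <- list(v1 = v1, v2 = v2, objective = obj,
                     iterations = length(trace), converged = converged,
                     trace = trace)
      }
    }
    if (!best$converged) {
      warning(sprintf("SCCA component %d did not converge in %d iterations",
                      comp, max_iter), call. = FALSE)
    }
    solutions[[comp]] <- structure(
      list(v1 = best$v1, v2 = best$v2, objective = best$objective,
           lambda1 = lambda1, lambda2 = lambda2, component = comp,
           iterations = best$iterations, converged = best$converged,
           degenerate = FALSE, trace = best$trace),
      class = "scca_solution")
    Z <- Z - best$objective * best$v1 %*% t(best$v2)
  }
  solutions
}

#' Pick the L1 bound of the feature projection by target support size
#'
#' Bisects the sparseness bound so that the leading component's feature
#' projection keeps roughly `target_nnz` connections: small enough for the
#' logistic stage to prune, large enough not to lose true signal. The
#' relationship between the bound and the support size is monotone (an
#' L1/L2 ratio of `sqrt(k)` admits about k comparable entries).
#'
#' @param X1,X2 as in [l1_scca_fit()].
#' @param target_nnz desired number of nonzero feature loadings, default 50
#'   (capped at p2).
#' @param lambda1 attribute-side bound used during tuning.
#' @return chosen lambda2.
#' @export
scca_tune_lambda2 <- function(X1, X2, target_nnz = 50, lambda1 = 1) {
  p2 <- ncol(X2)
  target_nnz <- min(target_nnz, p2)
  lo <- 1; hi <- max(1, sqrt(p2))
  nnz_at <- function(l2) {
    s <- l1_scca_fit(X1, X2, lambda1 = lambda1, lambda2 = l2,
                     n_components = 1)[[1]]
    if (s$degenerate) return(0L)
    sum(abs(s$v2) > 1e-8)
  }
  if (nnz_at(hi) <= target_nnz) return(hi)
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (nnz_at(mid) < target_nnz) lo <- mid else hi <- mid
  }
  hi
}

#' Choose the diagnosis-only canonical component
#'
#' Returns the component whose attribute projection v1 is supported exactly
#' on the diagnosis column (column 1), so the selected connections are
#' associated with diagnosis and the nuisance effect of age and sex is
#' reduced. When no component qualifies, falls back (with a warning) to the
#' component maximizing `|v1_diagnosis| / ||v1||_1`.
#'
#' @param solutions list from [l1_scca_fit()].
#' @param tol zero tolerance on v1 entries.
#' @return list with `solution` (the chosen `scca_solution`) and `selected`
#'   (integer indices of the nonzero entries of its v2).
#' @export
choose_diagnosis_component <- function(solutions, tol = 1e-8) {
  stopifnot(length(solutions) >= 1)
  supports <- lapply(solutions, function(s) which(abs(s$v1) > tol))
  hit <- which(vapply(supports, function(sp) identical(sp, 1L), logical(1)))
  if (length(hit) >= 1) {
    sol <- solutions[[hit[1]]]
  } else {
    frac <- vapply(solutions, function(s) {
      l1 <- sum(abs(s$v1))
      if (l1 == 0) -Inf else abs(s$v1[1]) / l1
    }, numeric(1))
    warning("no diagnosis-only canonical component; falling back to the ",
            "component with the largest diagnosis fraction of ||v1||_1",
            call. = FALSE)
    sol <- solutions[[which.max(frac)]]
  }
  list(solution = sol, selected = which(abs(sol$v2) > tol))
}

#' Sparse logistic regression with automatic relevance determination
#'
#' Maximum-likelihood logistic regression with a zero-mean Gaussian prior of
#' inverse variance `alpha_d` on each weight. Iterates (i) Newton updates of
#' the weights given the relevance parameters (maximizing the penalized
#' log-likelihood, bias unpenalized) and (ii) evidence updates
#' `alpha_d <- (gamma_d + 2 a0) / theta_d^2` with
#' `gamma_d = 1 - alpha_d * Sigma_dd` from the posterior covariance — the
#' MacKay update under a Gamma(shape a0, rate 0) hyperprior on the
#' relevance parameters. The hyperprior (default a0 = 1) makes irrelevant
#' relevance parameters diverge decisively, so that features merely
#' chance-correlated with the labels are pruned rather than lingering at
#' small weights; a0 = 0 recovers the plain evidence update. Most `alpha_d`
#' diverge to infinity and the corresponding weights are pruned (at
#' `alpha_d > prune_threshold`), leaving a sparse classifier.
#'
#' @param X N x D feature matrix (standardized by the caller).
#' @param y binary 0/1 labels.
#' @param max_outer maximum outer (relevance) iterations, default 500.
#' @param tol convergence on the maximum weight change, default 1e-6.
#' @param prune_threshold relevance value above which a feature is pruned,
#'   default 1e8.
#' @param alpha_min floor on the relevance parameters (keeps the weights
#'   bounded by the prior under complete separation), default 1e-3.
#' @param a0 shape of the sparsity-promoting hyperprior on the relevance
#'   parameters, default 1.
#' @return object of class `slr_model`: `weights` (length D, zeros for
#'   pruned), `bias`, `alpha`, `selected` (indices of surviving features),
#'   `loglik_trace`, `converged`, `feature_names`.
#' @export
slr_fit <- function(X, y, max_outer = 500, tol = 1e-6,
                    prune_threshold = 1e8, alpha_min = 1e-3, a0 = 1) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("NaN/Inf in features",
                                           call. = FALSE)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y), ncol(X) >= 1)
  N <- nrow(X); D <- ncol(X)
  active <- seq_len(D)
  alpha <- rep(1, D)
  theta <- numeric(D)
  bias <- 0
  loglik <- function(eta) sum(y * eta - log1p(exp(eta)))
  trace <- numeric(0)
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    theta_prev <- theta
    if (length(active) > 0) {
      A <- cbind(1, X[, active, drop = FALSE])
      pen <- c(1e-8, alpha[active])  # near-flat prior on the bias
      beta <- c(bias, theta[active])
      for (nr in 1:50) {
        eta <- as.vector(A %*% beta)
        p <- plogis(eta)
        w <- pmax(p * (1 - p), 1e-10)
        g <- crossprod(A, y - p) - pen * beta
        Hm <- crossprod(A * w, A) + diag(pen, length(pen))
        step <- solve(Hm, g)
        beta <- beta + step
        if (max(abs(step)) < 1e-9) break
      }
      bias <- beta[1]
      theta[active] <- beta[-1]
      eta <- as.vector(A %*% beta)
      p <- plogis(eta)
      w <- pmax(p * (1 - p), 1e-10)
      Hm <- crossprod(A * w, A) + diag(pen, length(pen))
      Sigma <- solve(Hm)
      sdiag <- diag(Sigma)[-1]
      gam <- pmin(pmax(1 - alpha[active] * sdiag, 1e-12), 1)
      th2 <- theta[active]^2
      anew <- ifelse(th2 < 1e-20, prune_threshold * 10,
                     pmax(alpha_min, (gam + 2 * a0) / th2))
      alpha[active] <- pmin(anew, prune_threshold * 10)
      drop_idx <- active[alpha[active] > prune_threshold]
      if (length(drop_idx) > 0) {
        theta[drop_idx] <- 0
        active <- setdiff(active, drop_idx)
      }
    } else {
      # all features pruned: bias-only model
      mb <- mean(y)
      bias <- qlogis(min(max(mb, 1 / (2 * N)), 1 - 1 / (2 * N)))
    }
    trace <- c(trace, loglik(as.vector(X %*% theta + bias)))
    if (max(abs(theta - theta_prev)) < tol) { converged <- TRUE; break }
  }
  structure(list(weights = theta, bias = bias, alpha = alpha,
                 selected = sort(active), loglik_trace = trace,
                 converged = converged,
                 feature_names = colnames(X)),
            class = "slr_model")
}

#' Predicted probability from a sparse logistic regression model
#'
#' `p = 1 / (1 + exp(-(theta' x + theta_0)))`.
#'
#' @param model an `slr_model`.
#' @param x feature vector (length D) or N x D matrix.
#' @return probability vector in (0, 1).
#' @export
slr_predict <- function(model, x) {
  stopifnot(inherits(model, "slr_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$weights)) {
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 length(model$weights), ncol(x)), call. = FALSE)
  }
  as.vector(plogis(x %*% model$weights + model$bias))
}

#' Rank connections by how many folds selected them
#'
#' Repeat time = the number of outer cross-validation folds in which the
#' connection survived selection. Ordered by decreasing repeat times, ties
#' broken by decreasing mean absolute weight across the folds that selected
#' the connection, then by pair id (smaller first region, then second).
#'
#' @param per_fold_selected list (one element per fold) of character vectors
#'   of selected pair ids.
#' @param per_fold_weights optional list of named weight vectors parallel to
#'   `per_fold_selected`.
#' @return data.frame of class `selection_ranking`: `id`, `i`, `j`,
#'   `repeat_times`, `mean_abs_weight`, `rank`.
#' @export
rank_by_repeat_times <- function(per_fold_selected,
                                 per_fold_weights = NULL) {
  stopifnot(length(per_fold_selected) >= 1)
  ids <- unique(unlist(per_fold_selected))
  if (length(ids) == 0) {
    res <- data.frame(id = character(), i = integer(), j = integer(),
                      repeat_times = integer(), mean_abs_weight = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
    class(res) <- c("selection_ranking", class(res))
    return(res)
  }
  rt <- vapply(ids, function(id)
    sum(vapply(per_fold_selected, function(s) id %in% s, logical(1))),
    integer(1))
  maw <- vapply(ids, function(id) {
    if (is.null(per_fold_weights)) return(0)
    w <- unlist(lapply(per_fold_weights, function(wv)
      if (id %in% names(wv)) abs(wv[[id]]) else NULL))
    if (length(w) == 0) 0 else mean(w)
  }, numeric(1))
  ij <- do.call(rbind, strsplit(ids, "-", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  ord <- order(-rt, -maw, i, j)
  res <- data.frame(id = ids[ord], i = i[ord], j = j[ord],
                    repeat_times = rt[ord], mean_abs_weight = maw[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("selection_ranking", class(res))
  res
}

#' Accuracy as a function of the number of top-ranked connections
#'
#' Evaluates a classifier on the top-k ranked connections for k = 1..k_max
#' and picks the k with the highest accuracy (smallest k on ties). An
#' evaluator failure marks that curve entry invalid and the sweep continues.
#'
#' @param ranking a `selection_ranking`.
#' @param k_max largest k to evaluate (<= nrow(ranking)).
#' @param evaluator function taking a character vector of pair ids and
#'   returning an accuracy in `[0, 1]`.
#' @return list with `curve` (data.frame k / accuracy / valid), `chosen_k`,
#'   `best_accuracy`.
#' @export
sweep_num_connections <- function(ranking, k_max, evaluator) {
  stopifnot(inherits(ranking, "selection_ranking"),
            k_max >= 1, k_max <= nrow(ranking))
  acc <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    acc[k] <- tryCatch(evaluator(ranking$id[seq_len(k)]),
                       error = function(e) NA_real_)
  }
  valid <- !is.na(acc)
  if (!any(valid)) stop("evaluator failed for every k", call. = FALSE)
  chosen <- which(valid & acc >= max(acc[valid]))[1]
  list(curve = data.frame(k = seq_len(k_max), accuracy = acc,
                          valid = valid),
       chosen_k = chosen, best_accuracy = acc[chosen])
}

#' Principal-component baseline sweep
#'
#' Dimension-reduction baseline for [sweep_num_connections()]: evaluates the
#' classifier on the top-k principal components of the full candidate
#' feature matrix instead of the top-k selected connections.
#'
#' @param X N x p candidate feature matrix.
#' @param k_max number of leading components to sweep.
#' @param evaluator function taking an N x k score matrix and returning an
#'   accuracy.
#' @return list as in [sweep_num_connections()].
#' @export
sweep_pca_baseline <- function(X, k_max, evaluator) {
  k_max <- min(k_max, ncol(X), nrow(X) - 1)
  sds <- apply(X, 2, sd)
  pc <- prcomp(X[, sds > 0, drop = FALSE], center = TRUE, scale. = TRUE)
  acc <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    acc[k] <- tryCatch(evaluator(pc$x[, seq_len(k), drop = FALSE]),
                       error = function(e) NA_real_)
  }
  valid <- !is.na(acc)
  if (!any(valid)) stop("evaluator failed for every k", call. = FALSE)
  chosen <- which(valid & acc >= max(acc[valid]))[1]
  list(curve = data.frame(k = seq_len(k_max), accuracy = acc,
                          valid = valid),
       chosen_k = chosen, best_accuracy = acc[chosen])
}
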