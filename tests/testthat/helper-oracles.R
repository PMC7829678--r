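# Independent oracles used across the suite. These are deliberately written
# with naive loops / closed forms so they share no code path with the
# package implementation they check.

# Direct-DFT ALFF oracle: explicit O(T^2) Fourier sum, one-sided bins whose
# frequency k/(T*tr) lies inside the band, sqrt of 2|X_k|^2/T averaged.
oracle_alff <- function(x, tr, band = c(0.01, 0.08), detrend = TRUE) {
  n <- length(x)
  if (detrend) {
    tt <- seq_len(n)
    fitc <- stats::lm.fit(cbind(1, tt), x)
    x <- x - cbind(1, tt) %*% fitc$coefficients
  }
  vals <- c()
  for (k in seq_len(floor(n / 2))) {
    f <- k / (n * tr)
    if (f >= band[1] - 1e-12 && f <= band[2] + 1e-12) {
      re <- sum(x * cos(2 * pi * k * (0:(n - 1)) / n))
      im <- -sum(x * sin(2 * pi * k * (0:(n - 1)) / n))
      vals <- c(vals, sqrt(2 * (re^2 + im^2) / n))
    }
  }
  mean(vals)
}

# Brute-force 3D connected-component labelling by repeated flood fill with
# an explicit neighbour scan (face connectivity by default).
oracle_label_3d <- function(mask, connectivity = 6) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z] || lab[x, y, z] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(x, y, z))
    lab[x, y, z] <- nxt
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        w <- v + as.integer(offs[r, ])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          stack[[length(stack) + 1]] <- w
        }
      }
    }
  }
  lab
}

# Exhaustive Mann-Whitney AUC: fraction of (positive, negative) score pairs
# won, ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Two-pass covariance Pearson correlation oracle.
oracle_cor <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
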