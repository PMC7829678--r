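#' Voxelwise one-way ANOVA mask across three groups
#'
#' Computes a one-way ANOVA F statistic per element over subjects' ALFF maps
#' and returns the mask of elements with p below the (uncorrected) threshold.
#' The mask restricts the subsequent permutation-corrected post hoc t-tests.
#'
#' @param alff_matrix elements x subjects matrix of (standardized) ALFF
#'   values; rows may be voxels (flattened) or regions.
#' @param groups group label per subject (2+ levels, >= 2 subjects each).
#' @param threshold uncorrected p-value threshold, default 0.05.
#' @param mask optional logical vector restricting the analysis.
#' @return list with `mask` (logical), `F` (statistic per element, NA outside
#'   the analysis mask), `p`, and degrees of freedom `df`.
#' @export
anova_mask <- function(alff_matrix, groups, threshold = 0.05, mask = NULL) {
  groups <- as.character(groups)
  stopifnot(is.matrix(alff_matrix), ncol(alff_matrix) == length(groups))
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs >= 2 subjects", call. = FALSE)
  k <- length(tab)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  N <- length(groups)
  if (is.null(mask)) mask <- rep(TRUE, nrow(alff_matrix))
  mask <- as.logical(mask)
  X <- alff_matrix[mask, , drop = FALSE]
  gm <- rowMeans(X)
  ssb <- numeric(nrow(X)); ssw <- numeric(nrow(X))
  for (g in names(tab)) {
    Xg <- X[, groups == g, drop = FALSE]
    mg <- rowMeans(Xg)
    ssb <- ssb + ncol(Xg) * (mg - gm)^2
    ssw <- ssw + rowSums((Xg - mg)^2)
  }
  df1 <- k - 1; df2 <- N - k
  Fv <- (ssb / df1) / (ssw / df2)
  Fv[ssw == 0 & ssb == 0] <- 0
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  out_F <- rep(NA_real_, nrow(alff_matrix)); out_F[mask] <- Fv
  out_p <- rep(NA_real_, nrow(alff_matrix)); out_p[mask] <- p
  out_mask <- rep(FALSE, nrow(alff_matrix))
  out_mask[mask] <- p < threshold
  list(mask = out_mask, F = out_F, p = out_p, df = c(df1, df2))
}

# Vectorized two-sample pooled-variance t statistic per row (group a - group b).
two_sample_t <- function(X, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  Xa <- X[, is_a, drop = FALSE]; Xb <- X[, !is_a, drop = FALSE]
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  va <- rowSums((Xa - ma)^2); vb <- rowSums((Xb - mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tv <- (ma - mb) / se
  tv[se == 0] <- 0
  tv
}

#' Threshold-free cluster enhancement of a 3D statistic map
#'
#' For each voxel, integrates extent^E * height^H over supra-threshold
#' heights: `sum_h e(v,h)^E h^H dh`, where `e(v,h)` is the size of the
#' connected component of `{stat >= h}` containing the voxel. The negative
#' tail is enhanced by applying the same transform to `-stat`; the result
#' carries the sign of the input.
#'
#' @param stat 3D numeric array (a t map). Must be finite.
#' @param E extent exponent, default 0.5.
#' @param H height exponent, default 2.
#' @param dh threshold step; default `max(abs(stat))/100`.
#' @param connectivity 6 (faces), 18 or 26.
#' @return 3D array of signed enhanced values.
#' @export
tfce_transform <- function(stat, E = 0.5, H = 2, dh = NULL,
                           connectivity = 6) {
  stopifnot(length(dim(stat)) == 3, E >= 0, H >= 0)
  if (any(!is.finite(stat))) stop("non-finite values in statistic map",
                                  call. = FALSE)
  mx <- max(abs(stat))
  if (mx == 0) return(array(0, dim = dim(stat)))
  if (is.null(dh)) dh <- mx / 100
  stopifnot(dh > 0)
  pos <- .tfce_3d(pmax(as.vector(stat), 0), dim(stat), E, H, dh,
                  as.integer(connectivity))
  neg <- .tfce_3d(pmax(-as.vector(stat), 0), dim(stat), E, H, dh,
                  as.integer(connectivity))
  array(pos - neg, dim = dim(stat))
}

#' Permutation-corrected two-group comparison with TFCE
#'
#' Computes the two-sample t map (group a minus group b) on each element of
#' a 3D grid, enhances it with TFCE, and derives family-wise-corrected
#' p-values from the permutation distribution of the maximum absolute
#' enhanced statistic under group-label exchange. When the number of
#' distinct relabelings is at most `n_perm`, all of them are enumerated
#' exactly; otherwise `n_perm` random relabelings are drawn.
#'
#' @param alff_maps elements x subjects matrix (flattened 3D grid).
#' @param grid_dim integer length-3 grid dimensions.
#' @param groups two-level label per subject; the first level encountered is
#'   the "patient" side of the contrast (patient - control).
#' @param mask logical vector restricting the test (e.g. the ANOVA mask);
#'   out-of-mask elements never enter the permutation null. Default: all.
#' @param n_perm number of permutations, default 1000 (warning below 100).
#' @param alpha corrected significance level, default 0.05.
#' @param E,H,dh,connectivity TFCE parameters, see [tfce_transform()].
#' @param seed RNG seed for the random relabelings.
#' @return list with `sig_mask` (logical, corrected p < alpha), `p_corr`,
#'   `t_map`, `tfce_map`, `max_null` (permutation maxima), and `n_perm_used`.
#' @export
permutation_correct <- function(alff_maps, grid_dim, groups, mask = NULL,
                                n_perm = 1000, alpha = 0.05, E = 0.5, H = 2,
                                dh = NULL, connectivity = 6, seed = 1) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: corrected p-values are coarse",
                            call. = FALSE)
  nvox <- prod(grid_dim)
  stopifnot(nrow(alff_maps) == nvox, ncol(alff_maps) == length(groups))
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  mask <- as.logical(mask)
  is_a <- groups == lv[1]

  masked_t <- function(labels_a) {
    tv <- rep(0, nvox)
    tv[mask] <- two_sample_t(alff_maps[mask, , drop = FALSE], labels_a)
    array(tv, dim = grid_dim)
  }
  t_obs <- masked_t(is_a)
  if (is.null(dh)) {
    mx <- max(abs(t_obs))
    dh <- if (mx > 0) mx / 100 else 0.01
  }
  enh_obs <- tfce_transform(t_obs, E, H, dh, connectivity)

  n_a <- sum(is_a)
  n_total <- choose(length(groups), n_a)
  exact <- n_total <= n_perm
  if (exact) {
    combos <- combn(length(groups), n_a)
    n_used <- ncol(combos)
  } else {
    set.seed(seed)
    n_used <- n_perm
  }
  max_null <- numeric(n_used)
  for (p_i in seq_len(n_used)) {
    idx_a <- if (exact) combos[, p_i] else sample(length(groups), n_a)
    la <- rep(FALSE, length(groups)); la[idx_a] <- TRUE
    enh <- tfce_transform(masked_t(la), E, H, dh, connectivity)
    max_null[p_i] <- max(abs(enh[array(mask, dim = grid_dim)]), 0)
  }
  p_corr <- rep(NA_real_, nvox)
  av <- abs(as.vector(enh_obs))[mask]
  p_corr[mask] <- vapply(av, function(v) (1 + sum(max_null >= v)) /
                           (n_used + 1), numeric(1))
  sig <- rep(FALSE, nvox)
  sig[mask] <- p_corr[mask] < alpha
  list(sig_mask = array(sig, dim = grid_dim),
       p_corr = array(p_corr, dim = grid_dim),
       t_map = t_obs, tfce_map = enh_obs,
       max_null = max_null, n_perm_used = n_used,
       contrast = paste(lv[1], "-", lv[2]))
}

#' Extract suprathreshold clusters from a significance mask
#'
#' Labels connected components of the mask (positive- and negative-t
#' elements separately, so a cluster has a single sign) and drops components
#' smaller than `min_size` voxels.
#'
#' @param sig_mask 3D logical array.
#' @param t_map 3D t map providing each cluster's sign.
#' @param min_size minimum cluster extent in voxels, default 20 (clusters
#'   with fewer voxels are excluded).
#' @param connectivity 6, 18 or 26; default face connectivity.
#' @return list of clusters, each with `voxels` (linear indices), `size`,
#'   and `direction` ("decreased" for negative t, "increased" for positive,
#'   patient-minus-control convention).
#' @export
extract_clusters <- function(sig_mask, t_map, min_size = 20,
                             connectivity = 6) {
  stopifnot(identical(dim(sig_mask), dim(t_map)))
  out <- list()
  for (sgn in c(1, -1)) {
    m <- sig_mask & (sgn * t_map > 0)
    if (!any(m)) next
    lab <- .cc_label_3d(as.vector(m), dim(m), as.integer(connectivity))
    for (id in setdiff(unique(lab), 0L)) {
      vox <- which(lab == id)
      if (length(vox) >= min_size) {
        out[[length(out) + 1]] <- list(
          voxels = vox, size = length(vox),
          direction = if (sgn > 0) "increased" else "decreased")
      }
    }
  }
  out
}

#' Overlap significant clusters with atlas subregions
#'
#' Counts, per atlas subregion and per direction, the voxels of the
#' significant clusters falling inside it, and ranks subregions by
#' non-increasing overlap volume (ties broken by smaller region id).
#'
#' @param clusters list from [extract_clusters()].
#' @param atlas an [atlas_definition()] with a label volume on the same grid.
#' @param grid_dim grid dimensions the cluster voxel indices refer to.
#' @return data.frame of class `impaired_region_set`: `region_id`,
#'   `overlap_voxels`, `overlap_mm3`, `direction`, `rank` (within direction),
#'   sorted by direction then decreasing overlap.
#' @export
match_clusters_to_atlas <- function(clusters, atlas, grid_dim = NULL) {
  stopifnot(inherits(atlas, "atlas_definition"))
  lab <- atlas$label_volume
  if (is.null(lab)) stop("atlas has no label volume", call. = FALSE)
  if (!is.null(grid_dim) && !identical(as.integer(dim(lab)),
                                       as.integer(grid_dim))) {
    stop("cluster grid and atlas label volume dimensions differ",
         call. = FALSE)
  }
  rows <- list()
  for (cl in clusters) {
    ids <- lab[cl$voxels]
    ids <- ids[ids > 0]
    if (length(ids) == 0) next
    tab <- table(ids)
    rows[[length(rows) + 1]] <- data.frame(
      region_id = as.integer(names(tab)),
      overlap_voxels = as.integer(tab),
      direction = cl$direction, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    res <- data.frame(region_id = integer(), overlap_voxels = integer(),
                      overlap_mm3 = numeric(), direction = character(),
                      rank = integer(), stringsAsFactors = FALSE)
    class(res) <- c("impaired_region_set", class(res))
    return(res)
  }
  df <- do.call(rbind, rows)
  df <- aggregate(overlap_voxels ~ region_id + direction, df, sum)
  df$overlap_mm3 <- df$overlap_voxels * atlas$voxel_volume_mm3
  df <- df[order(df$direction, -df$overlap_voxels, df$region_id), ]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$direction),
                           seq_along), use.names = FALSE)
  df <- df[, c("region_id", "overlap_voxels", "overlap_mm3", "direction",
               "rank")]
  rownames(df) <- NULL
  class(df) <- c("impaired_region_set", class(df))
  df
}

#' Select the impaired subregions used as connection anchors
#'
#' Takes the top-k subregions with decreased ALFF by overlap volume; when
#' fewer than k decreased subregions exist, the list is completed with the
#' top subregions with increased ALFF so all comparisons use the same number
#' of anchors.
#'
#' @param region_set an `impaired_region_set`.
#' @param k anchor count, default 15.
#' @return integer vector of region ids (length <= k, with a warning when
#'   fewer than k subregions are available).
#' @export
select_impaired_subregions <- function(region_set, k = 15) {
  stopifnot(k >= 1)
  dec <- region_set[region_set$direction == "decreased", , drop = FALSE]
  inc <- region_set[region_set$direction == "increased", , drop = FALSE]
  dec <- dec[order(dec$rank), , drop = FALSE]
  inc <- inc[order(inc$rank), , drop = FALSE]
  sel <- head(dec$region_id, k)
  if (length(sel) < k) sel <- c(sel, head(setdiff(inc$region_id, sel),
                                          k - length(sel)))
  if (length(sel) < k) {
    warning(sprintf("only %d impaired subregions available (requested %d)",
                    length(sel), k), call. = FALSE)
  }
  as.integer(sel)
}

#' Region-level anchor selection by two-sample t-tests
#'
#' Region-resolution analogue of the voxel pipeline (ANOVA mask, corrected
#' post hoc tests, cluster-volume sorting) for datasets that carry regional
#' time series only: per-region two-sample t statistics of standardized
#' regional ALFF (patient minus control), significance at `alpha`
#' (uncorrected, the region count playing the role of the voxel grid), and
#' ranking by effect magnitude in place of overlap volume. Decreased regions
#' first, completed with increased ones, exactly like
#' [select_impaired_subregions()].
#'
#' @param alff_matrix regions x subjects matrix of standardized ALFF.
#' @param groups two-level label per subject (first level = patient side).
#' @param k anchor count, default 15.
#' @param alpha per-region significance threshold, default 0.05.
#' @return integer vector of region ids, decreasing effect magnitude,
#'   length <= k.
#' @export
select_anchors_regional <- function(alff_matrix, groups, k = 15,
                                    alpha = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  is_a <- groups == lv[1]
  tv <- two_sample_t(alff_matrix, is_a)
  df <- length(groups) - 2
  p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
  sig <- which(p < alpha)
  dec <- sig[tv[sig] < 0]; inc <- sig[tv[sig] > 0]
  dec <- dec[order(-abs(tv[dec]), dec)]
  inc <- inc[order(-abs(tv[inc]), inc)]
  sel <- head(dec, k)
  if (length(sel) < k) sel <- c(sel, head(inc, k - length(sel)))
  as.integer(sel)
}
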