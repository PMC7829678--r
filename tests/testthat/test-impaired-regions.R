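test_that("the ANOVA mask behaves at the null, boundary and under signal", {
  set.seed(1)
  X <- matrix(rnorm(50 * 12), 50)
  g <- rep(c("a", "b", "c"), each = 4)
  am <- anova_mask(X, g, threshold = 0.05)
  expect_lt(mean(am$mask), 0.15)  # near-nominal false positives
  expect_true(all(is.finite(am$F)))
  # threshold 1 admits every voxel of the analysis mask
  am1 <- anova_mask(X, g, threshold = 1)
  expect_true(all(am1$mask))
  # planted group shift is detected
  X2 <- X
  X2[7, g == "a"] <- X2[7, g == "a"] + 5
  expect_true(anova_mask(X2, g)$mask[7])
  expect_error(anova_mask(X, rep(c("a", "b", "c"), c(1, 5, 6))), ">= 2")
})

test_that("TFCE matches its analytic small-voxel and block limits", {
  g <- array(0, c(7, 7, 7)); g[4, 4, 4] <- 2
  e <- tfce_transform(g, E = 0.5, H = 2, dh = 2 / 1000)
  expect_equal(e[4, 4, 4], 2^3 / 3, tolerance = 0.01)
  b <- array(0, c(9, 9, 9)); b[3:6, 4, 4] <- 1.5
  eb <- tfce_transform(b, dh = 1.5 / 1000)
  expect_equal(eb[4, 4, 4], sqrt(4) * 1.5^3 / 3, tolerance = 0.01)
  expect_equal(tfce_transform(array(0, c(4, 4, 4))), array(0, c(4, 4, 4)))
  bad <- array(0, c(3, 3, 3)); bad[1] <- NaN
  expect_error(tfce_transform(bad), "non-finite")
})

test_that("TFCE is monotone and handles the negative tail by sign", {
  set.seed(4)
  g <- array(rnorm(6^3), c(6, 6, 6))
  e1 <- tfce_transform(g, dh = 0.05)
  g2 <- g; g2[g2 > 0] <- g2[g2 > 0] + 0.5  # raise the positive part
  e2 <- tfce_transform(g2, dh = 0.05)
  pos <- g > 0
  expect_true(all(e2[pos] >= e1[pos] - 1e-9))
  # negative tail: enhancement of -g mirrors g
  em <- tfce_transform(-g, dh = 0.05)
  expect_equal(as.vector(em), -as.vector(e1), tolerance = 1e-9)
})

test_that("cluster extraction enforces the 20-voxel exclusion boundary", {
  d <- c(25, 12, 12)
  tmap <- array(0, d)
  mask <- array(FALSE, d)
  # 19-voxel component: must be excluded
  mask[1:19, 1, 1] <- TRUE; tmap[1:19, 1, 1] <- -3
  # 20-voxel component: must be kept
  mask[1:20, 5, 5] <- TRUE; tmap[1:20, 5, 5] <- -3
  cl <- extract_clusters(mask, tmap, min_size = 20)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 20)
  expect_equal(cl[[1]]$direction, "decreased")
  expect_length(extract_clusters(array(FALSE, d), tmap), 0)
})

test_that("connected-component labelling agrees with a brute-force oracle", {
  set.seed(8)
  for (i in 1:4) {
    mask <- array(runif(5 * 5 * 5) < 0.35, c(5, 5, 5))
    tmap <- array(1, c(5, 5, 5))
    for (conn in c(6, 26)) {
      cl <- extract_clusters(mask, tmap, min_size = 1, connectivity = conn)
      lab <- oracle_label_3d(mask, connectivity = conn)
      sizes_pkg <- sort(vapply(cl, function(x) x$size, integer(1)))
      sizes_orc <- sort(as.integer(table(lab[lab > 0])))
      expect_equal(sizes_pkg, sizes_orc)
    }
  }
  # two blocks touching only at a corner: separate under 6, joined under 26
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, 1:2, 1:2] <- TRUE; m[3:4, 3:4, 3:4] <- TRUE
  t1 <- array(1, c(4, 4, 4))
  expect_length(extract_clusters(m, t1, 1, connectivity = 6), 2)
  expect_length(extract_clusters(m, t1, 1, connectivity = 26), 1)
})

test_that("permutation correction is deterministic and enumerates exactly", {
  set.seed(2)
  X <- matrix(rnorm(27 * 8), 27)
  g <- rep(c("a", "b"), each = 4)
  expect_warning(
    p1 <- permutation_correct(X, c(3, 3, 3), g, n_perm = 80, seed = 3),
    "coarse")
  # choose(8, 4) = 70 < 80: exact enumeration
  expect_equal(p1$n_perm_used, 70)
  suppressWarnings({
    p2 <- permutation_correct(X, c(3, 3, 3), g, n_perm = 80, seed = 99)
  })
  expect_equal(p1$p_corr, p2$p_corr)  # exact => seed-independent
})

test_that("permutation + TFCE recovers a planted deficit and stays clean", {
  cfg <- synthetic_config(n_regions = 8, n_timepoints = 64, seed = 3,
                          grid_shape = c(10, 10, 10))
  eff <- effect_spec(impaired = data.frame(region = c(2, 7),
                                           group = "T2DM-CI", factor = 0.4),
                     group_sizes = c("T2DM-CI" = 8, "HC" = 8))
  sim <- simulate_voxel_dataset(cfg, eff)
  ds <- sim$dataset
  amaps <- vapply(ds$signals, function(s) {
    as.vector(standardize_alff(compute_alff_map(s, ds$tr))$values)
  }, numeric(1000))
  pc <- permutation_correct(amaps, c(10, 10, 10), ds$subjects$group,
                            n_perm = 200, seed = 5)
  cl <- extract_clusters(pc$sig_mask, pc$t_map, min_size = 20)
  irs <- match_clusters_to_atlas(cl, sim$atlas)
  dec <- irs$region_id[irs$direction == "decreased"]
  expect_setequal(dec, c(2, 7))
  expect_equal(select_impaired_subregions(irs, k = 2), c(2L, 7L))
})

test_that("atlas overlap conserves cluster volume and sorts by size", {
  lab <- array(0L, c(6, 6, 1))
  lab[1:3, , 1] <- 5L; lab[4:6, , 1] <- 7L
  atlas <- atlas_definition(8, label_volume = array(lab, c(6, 6, 1)),
                            voxel_volume_mm3 = 27)
  tmap <- array(-1, c(6, 6, 1))
  # one cluster straddling both regions: 10 voxels in r5, 2 in r7
  vox <- c(which(lab == 5L)[1:10], which(lab == 7L)[1:2])
  clusters <- list(list(voxels = vox, size = 12, direction = "decreased"))
  irs <- match_clusters_to_atlas(clusters, atlas, grid_dim = c(6, 6, 1))
  expect_equal(sum(irs$overlap_voxels), 12)
  expect_equal(irs$region_id, c(5L, 7L))  # sorted by decreasing overlap
  expect_equal(irs$rank, 1:2)
  expect_equal(irs$overlap_mm3, c(270, 54))
  expect_error(match_clusters_to_atlas(clusters, atlas,
                                       grid_dim = c(5, 5, 5)), "differ")
})

test_that("anchor selection takes decreased first, then increased", {
  mk <- function(n_dec, n_inc) {
    n <- n_dec + n_inc
    data.frame(
      region_id = seq_len(n),
      overlap_voxels = c(seq(100, by = -1, length.out = n_dec),
                         seq(90, by = -1, length.out = n_inc)),
      overlap_mm3 = rep(0, n),
      direction = rep(c("decreased", "increased"), c(n_dec, n_inc)),
      rank = c(seq_len(n_dec), seq_len(n_inc)),
      stringsAsFactors = FALSE)
  }
  irs <- mk(20, 0)
  expect_equal(select_impaired_subregions(irs, 15), 1:15)
  irs2 <- mk(10, 8)
  sel <- select_impaired_subregions(irs2, 15)
  expect_equal(sel, c(1:10, 11:15))  # 10 decreased + top-5 increased
  expect_warning(s3 <- select_impaired_subregions(mk(3, 2), 15),
                 "only 5")
  expect_length(s3, 5)
  expect_warning(s0 <- select_impaired_subregions(mk(0, 0), 15), "only 0")
  expect_length(s0, 0)
})

test_that("regional anchors are stable across outer folds when effects are strong", {
  ds <- planted_small_dataset(seed = 9)
  alff <- dataset_alff(ds)
  g <- ifelse(ds$subjects$group == "T2DM-CI", "patient", "control")
  sets <- lapply(seq_len(n_subjects(ds)), function(f) {
    keep <- setdiff(seq_len(n_subjects(ds)), f)
    sort(select_anchors_regional(alff[, keep], g[keep], k = 3))
  })
  expect_true(all(vapply(sets, identical, logical(1), sets[[1]])))
  expect_true(all(c(3, 9, 17) %in% sets[[1]]))
})
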