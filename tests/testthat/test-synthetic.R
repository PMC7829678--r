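test_that("the generator is bit-reproducible given the master seed", {
  cfg <- synthetic_config(n_regions = 8, n_timepoints = 64, seed = 42)
  eff <- effect_spec(group_sizes = c("T2DM-CI" = 3, "HC" = 3))
  d1 <- simulate_region_dataset(cfg, eff)
  d2 <- simulate_region_dataset(cfg, eff)
  expect_identical(d1$signals, d2$signals)
  expect_identical(d1$subjects, d2$subjects)
})

test_that("a planted ALFF deficit reproduces its scaling factor", {
  cfg <- synthetic_config(n_regions = 12, n_timepoints = 230, seed = 7)
  eff <- effect_spec(
    impaired = data.frame(region = 7, group = "T2DM-CI", factor = 0.5),
    group_sizes = c("T2DM-CI" = 15, "HC" = 15))
  ds <- simulate_region_dataset(cfg, eff)
  alff <- dataset_alff(ds, standardize = FALSE)
  g <- ds$subjects$group
  ratio <- mean(alff[7, g == "T2DM-CI"]) / mean(alff[7, g == "HC"])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
  # unaffected region stays at parity
  r2 <- mean(alff[3, g == "T2DM-CI"]) / mean(alff[3, g == "HC"])
  expect_gt(r2, 0.85)
  expect_lt(r2, 1.15)
})

test_that("deeper planted deficits give larger group t-statistics", {
  tstat_for <- function(factor, seed) {
    cfg <- synthetic_config(n_regions = 6, n_timepoints = 128, seed = seed)
    eff <- effect_spec(
      impaired = data.frame(region = 2, group = "T2DM-CI", factor = factor),
      group_sizes = c("T2DM-CI" = 10, "HC" = 10))
    ds <- simulate_region_dataset(cfg, eff)
    alff <- dataset_alff(ds, standardize = FALSE)
    g <- ds$subjects$group
    abs(t.test(alff[2, g == "T2DM-CI"], alff[2, g == "HC"])$statistic)
  }
  t_small <- mean(vapply(1:5, function(s) tstat_for(0.8, s), numeric(1)))
  t_big <- mean(vapply(1:5, function(s) tstat_for(0.4, s), numeric(1)))
  expect_gt(t_big, t_small)
})

test_that("regional ALFF group tests are calibrated under null effects", {
  eff <- effect_spec(group_sizes = c("T2DM-CI" = 5, "HC" = 5))
  rej <- 0L; total <- 0L
  for (s in 1:200) {
    cfg <- synthetic_config(n_regions = 6, n_timepoints = 64, seed = s)
    ds <- simulate_region_dataset(cfg, eff)
    alff <- dataset_alff(ds, standardize = FALSE)
    g <- ds$subjects$group
    for (r in 1:6) {
      p <- t.test(alff[r, g == "T2DM-CI"], alff[r, g == "HC"])$p.value
      rej <- rej + (p < 0.05)
      total <- total + 1L
    }
  }
  rate <- rej / total  # 1200 pooled tests, nominal 0.05
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("planted pair correlations approach their group targets", {
  cfg <- synthetic_config(n_regions = 10, n_timepoints = 230, seed = 3)
  eff <- effect_spec(
    altered_pairs = rbind(
      data.frame(i = 2, j = 5, group = "T2DM-CI", r = 0.6),
      data.frame(i = 2, j = 5, group = "HC", r = -0.3)),
    group_sizes = c("T2DM-CI" = 20, "HC" = 20))
  ds <- simulate_region_dataset(cfg, eff)
  z <- connection_strengths(ds, c(2, 5))
  g <- ds$subjects$group
  expect_lt(abs(mean(z[g == "T2DM-CI"]) - 0.6), 0.12)
  expect_lt(abs(mean(z[g == "HC"]) + 0.3), 0.12)
})

test_that("invalid effect specifications are rejected", {
  expect_error(effect_spec(altered_pairs = data.frame(i = 1, j = 2,
                                                      group = "HC", r = 1)),
               "-1, 1")
  expect_error(effect_spec(group_sizes = c("HC" = 1, "T2DM-CI" = 5)),
               ">= 2")
  expect_error(effect_spec(impaired = data.frame(region = 1, group = "HC",
                                                 factor = 0)),
               "> 0")
  expect_error(effect_spec(altered_pairs = data.frame(
    i = c(1, 1), j = c(2, 3), group = "HC", r = 0.5)), "at most one")
  # unreachable target given the noise structure
  cfg <- synthetic_config(n_regions = 4, n_timepoints = 64, seed = 1)
  eff <- effect_spec(altered_pairs = data.frame(i = 1, j = 2, group = "HC",
                                                r = 0.95),
                     group_sizes = c("HC" = 3, "T2DM-CI" = 3),
                     noise_sd = 0.5)
  expect_error(simulate_region_dataset(cfg, eff), "unreachable")
})

test_that("voxel datasets carry a label volume matching the geometry", {
  cfg <- synthetic_config(n_regions = 8, n_timepoints = 64, seed = 2,
                          grid_shape = c(10, 10, 10))
  sim <- simulate_voxel_dataset(cfg)
  expect_equal(dim(sim$atlas$label_volume), c(10, 10, 10))
  labs <- unique(as.vector(sim$atlas$label_volume))
  expect_true(all(1:8 %in% labs))
  expect_true(all(labs %in% 0:8))
  expect_equal(dim(sim$dataset$signals[[1]]), c(10, 10, 10, 64))
  # all voxels of a region share the regional signal (plus voxel noise):
  # correlation between two voxels of the same region is high
  v <- which(sim$atlas$label_volume == 3, arr.ind = TRUE)
  s <- sim$dataset$signals[[1]]
  a <- s[v[1, 1], v[1, 2], v[1, 3], ]
  b <- s[2, 2, 2, ]  # region of voxel (2,2,2)
  same <- sim$atlas$label_volume[v[1, 1], v[1, 2], v[1, 3]] ==
    sim$atlas$label_volume[2, 2, 2]
  expect_false(same)
  a2 <- s[v[2, 1], v[2, 2], v[2, 3], ]
  expect_gt(cor(a, a2), 0.7)

  cfg_bad <- synthetic_config(n_regions = 100, n_timepoints = 64,
                              grid_shape = c(3, 3, 3))
  expect_error(simulate_voxel_dataset(cfg_bad), "too small")
})

test_that("scale correlations can be planted and recovered", {
  cfg <- synthetic_config(n_regions = 6, n_timepoints = 96, seed = 13)
  eff <- effect_spec(group_sizes = c("T2DM-CI" = 25, "T2DM-NC" = 25))
  ds <- simulate_region_dataset(cfg, eff)
  ds2 <- plant_scale_correlation(ds, c(2, 4), "MoCA", -0.43, seed = 8)
  r <- cor(connection_strengths(ds2, c(2, 4)), ds2$subjects$MoCA)
  expect_equal(r, -0.43, tolerance = 0.15)
  # null target keeps the observed correlation small
  ds0 <- plant_scale_correlation(ds, c(2, 4), "MoCA", 0, seed = 9)
  r0 <- cor(connection_strengths(ds0, c(2, 4)), ds0$subjects$MoCA)
  expect_lt(abs(r0), 0.25)
  expect_error(plant_scale_correlation(ds, c(2, 4), "MoCA", 1), "< 1")
  expect_error(plant_scale_correlation(ds, c(2, 400), "MoCA", 0.3),
               "absent")
})

test_that("group relabelling leaves null rejection rates nominal", {
  # exchangeability: permuting group labels of a null dataset must not
  # change the regional test behaviour
  cfg <- synthetic_config(n_regions = 5, n_timepoints = 64, seed = 77)
  eff <- effect_spec(group_sizes = c("T2DM-CI" = 6, "HC" = 6))
  rej <- 0L; total <- 0L
  for (s in 1:100) {
    cfg$seed <- 1000 + s
    ds <- simulate_region_dataset(cfg, eff)
    alff <- dataset_alff(ds, standardize = FALSE)
    set.seed(s)
    g <- sample(ds$subjects$group)  # relabelled
    for (r in 1:5) {
      p <- t.test(alff[r, g == "T2DM-CI"], alff[r, g == "HC"])$p.value
      rej <- rej + (p < 0.05); total <- total + 1L
    }
  }
  expect_gt(rej / total, 0.02)
  expect_lt(rej / total, 0.08)
})
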