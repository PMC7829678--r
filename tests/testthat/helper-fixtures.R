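# Shared small synthetic fixtures, built in code at test time.

small_participants <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3"),
    group = c("T2DM-CI", "T2DM-NC", "HC"),
    age = c(63, 58, 55),
    sex = c(1, 0, 1),
    MoCA = c(21, 27, 28),
    stringsAsFactors = FALSE
  )
}

# A two-group region-level dataset with one planted ALFF deficit and one
# planted connectivity contrast; small enough for per-test pipeline runs.
planted_small_dataset <- function(seed = 5, n_per_group = 8, R = 40,
                                  T_ = 128) {
  cfg <- synthetic_config(n_regions = R, n_timepoints = T_, seed = seed)
  eff <- effect_spec(
    impaired = data.frame(region = c(3, 9, 17), group = "T2DM-CI",
                          factor = 0.5),
    altered_pairs = rbind(
      data.frame(i = 3, j = 22, group = "T2DM-CI", r = 0.6),
      data.frame(i = 3, j = 22, group = "HC", r = -0.4)),
    group_sizes = setNames(c(n_per_group, n_per_group), c("T2DM-CI", "HC")))
  simulate_region_dataset(cfg, eff)
}

null_small_dataset <- function(seed = 11, n_per_group = 8, R = 30,
                               T_ = 96) {
  cfg <- synthetic_config(n_regions = R, n_timepoints = T_, seed = seed)
  eff <- effect_spec(group_sizes = setNames(c(n_per_group, n_per_group),
                                            c("T2DM-CI", "HC")))
  simulate_region_dataset(cfg, eff)
}

# Cheap SVM grids for tests that exercise the full nested pipeline.
fast_config <- function(...) {
  pipeline_config(svm_C_grid = 2^seq(-3, 9, 2),
                  svm_gamma_grid = 2^seq(-9, 1, 2), ...)
}
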