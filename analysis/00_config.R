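# Shared configuration of the synthetic study all analysis scripts use.
# The cohort mirrors the reference study's retained sample (19 / 31 / 39)
# on the 246-region parcellation at TR = 2 s with 230 volumes; effects are
# planted so that every later stage has a known ground truth to recover.

library(alffconn)

study_seed <- 2026

study_config <- synthetic_config(n_regions = 246, n_timepoints = 230,
                                 tr = 2, seed = study_seed)

# 15 subregions with reduced spontaneous activity in the impaired group
# (posterior-DMN / executive / visual subregions of the shipped lookup),
# and three connections with group-dependent coupling.
study_anchors <- c(15, 17, 23, 138, 142, 143, 144, 152, 153, 154,
                   175, 176, 181, 182, 209)
study_planted_pairs <- data.frame(i = c(181, 8, 138), j = c(182, 154, 188))

study_effects <- effect_spec(
  impaired = data.frame(region = study_anchors, group = "T2DM-CI",
                        factor = 0.55),
  altered_pairs = rbind(
    data.frame(i = study_planted_pairs$i, j = study_planted_pairs$j,
               group = "T2DM-CI", r = c(0.6, 0.6, -0.5)),
    data.frame(i = study_planted_pairs$i, j = study_planted_pairs$j,
               group = "HC", r = c(-0.4, -0.4, 0.5))),
  group_sizes = c("T2DM-CI" = 19, "T2DM-NC" = 31, "HC" = 39))

study_comparison <- c("T2DM-CI", "HC")

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE)
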