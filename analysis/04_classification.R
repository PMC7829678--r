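#!/usr/bin/env Rscript
# Accuracy as a function of the connection count, and the fixed-feature
# evaluation protocol on the final discriminative set.

source(file.path("analysis", "00_config.R"))

ds <- simulate_region_dataset(study_config, study_effects)
ranking <- read.delim(file.path(results_dir, "selection_ranking.tsv"),
                      stringsAsFactors = FALSE)
class(ranking) <- c("selection_ranking", class(ranking))
stopifnot(nrow(ranking) >= 1)

k_max <- min(6, nrow(ranking))
ev <- function(ids) {
  fixed_feature_evaluate(ds, ids, study_comparison)$accuracy
}
sw <- sweep_num_connections(ranking, k_max, ev)
cat("Accuracy vs number of top-ranked connections:\n")
print(sw$curve)
cat(sprintf("Chosen k = %d (accuracy %.3f)\n", sw$chosen_k,
            sw$best_accuracy))
write.table(sw$curve, file.path(results_dir, "sweep_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

final_ids <- ranking$id[seq_len(sw$chosen_k)]
rep_fixed <- fixed_feature_evaluate(ds, final_ids, study_comparison)
cat("\nFixed-feature evaluation on the final set (",
    paste(final_ids, collapse = ", "), "):\n", sep = "")
print(rep_fixed)
write.table(rep_fixed$roc, file.path(results_dir, "roc_fixed.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# principal-component baseline on the full candidate pool
sub <- which(ds$subjects$group %in% study_comparison)
fc <- lapply(ds$signals[sub], build_fc_matrix)
cf <- extract_candidate_features(fc, study_anchors)
yl <- as.integer(ds$subjects$group[sub] == study_comparison[1])
ev_pca <- function(S) {
  n <- length(yl)
  pred <- numeric(n)
  for (f in seq_len(n)) {
    tr <- setdiff(seq_len(n), f)
    gs <- grid_search_svm(S[tr, , drop = FALSE], yl[tr],
                          C_grid = 2^seq(-3, 9, 2),
                          gamma_grid = 2^seq(-9, 1, 2))
    pred[f] <- as.integer(as.character(predict(gs$model,
                                               S[f, , drop = FALSE])))
  }
  mean(pred == yl)
}
swp <- sweep_pca_baseline(cf$X, k_max, ev_pca)
cat("\nPCA baseline (top-k principal components of all candidates):\n")
print(swp$curve)
write.table(swp$curve, file.path(results_dir, "sweep_pca_baseline.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
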