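#' Group comparison of selected-connection strengths
#'
#' Two-sample t-test per connection (Welch by default; set
#' `var.equal = TRUE` for the pooled-variance test), with the direction of
#' the difference. Smaller connectivity means a more negative strength, so
#' "greater" names the group with the larger mean correlation.
#'
#' @param features N x k matrix of connection strengths (columns named by
#'   pair id).
#' @param groups two-level label per row.
#' @param var.equal pooled-variance t-test instead of Welch.
#' @param bonferroni apply a Bonferroni correction across the k connections
#'   (off by default, matching per-connection reporting at p < 0.05).
#' @return data.frame: `id`, `mean_a`, `mean_b`, `t`, `p`, `greater_group`,
#'   `flagged` (TRUE when the test is undefined, e.g. zero variance).
#' @export
compare_strengths <- function(features, groups, var.equal = FALSE,
                              bonferroni = FALSE) {
  features <- as.matrix(features)
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  if (any(table(groups) < 2)) stop("every group needs >= 2 subjects",
                                   call. = FALSE)
  a <- groups == lv[1]
  rows <- lapply(seq_len(ncol(features)), function(c_) {
    xa <- features[a, c_]; xb <- features[!a, c_]
    if (sd(xa) == 0 && sd(xb) == 0) {
      return(data.frame(id = colnames(features)[c_], mean_a = mean(xa),
                        mean_b = mean(xb), t = NA_real_, p = NA_real_,
                        greater_group = NA_character_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(xa, xb, var.equal = var.equal)
    data.frame(id = colnames(features)[c_], mean_a = mean(xa),
               mean_b = mean(xb), t = unname(tt$statistic),
               p = tt$p.value,
               greater_group = if (mean(xa) >= mean(xb)) lv[1] else lv[2],
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * ncol(features))
  attr(out, "groups") <- lv
  out
}

#' Correlation of connection strengths with a cognitive scale
#'
#' Pearson r and two-sided p per connection against the given scale values.
#'
#' @param features N x k matrix of connection strengths.
#' @param scale_values numeric scale score per row (no missing values).
#' @param scale_name label recorded in the output.
#' @return data.frame: `id`, `scale`, `r`, `p`, `flagged` (TRUE when the
#'   correlation is undefined, e.g. constant input).
#' @export
correlate_with_scale <- function(features, scale_values,
                                 scale_name = "MoCA") {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(scale_values))
  if (anyNA(scale_values)) {
    stop("scale values missing for some subjects", call. = FALSE)
  }
  const_scale <- sd(scale_values) == 0
  rows <- lapply(seq_len(ncol(features)), function(c_) {
    x <- features[, c_]
    if (const_scale || sd(x) == 0) {
      return(data.frame(id = colnames(features)[c_], scale = scale_name,
                        r = NA_real_, p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, scale_values)
    data.frame(id = colnames(features)[c_], scale = scale_name,
               r = unname(ct$estimate), p = ct$p.value, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the discriminative-connection report table
#'
#' One row per selected connection: endpoints, repeat times, centroid
#' distance, network annotation, group means and test p, and the
#' correlation with the cognitive scale — ordered by decreasing repeat
#' times. All inputs must be keyed by the same pair ids.
#'
#' @param ranking a `selection_ranking` (typically truncated to the final
#'   connection count).
#' @param atlas an [atlas_definition()] for distances and annotations.
#' @param strength_stats output of [compare_strengths()].
#' @param scale_stats output of [correlate_with_scale()].
#' @return data.frame of class `connection_report`.
#' @export
build_report <- function(ranking, atlas, strength_stats, scale_stats) {
  stopifnot(inherits(ranking, "selection_ranking"))
  if (nrow(ranking) == 0) {
    return(structure(data.frame(), class = c("connection_report",
                                             "data.frame")))
  }
  orphans <- c(setdiff(ranking$id, strength_stats$id),
               setdiff(ranking$id, scale_stats$id))
  if (length(orphans) > 0) {
    stop("no statistics for connection(s): ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(ranking)), function(r) {
    id <- ranking$id[r]
    pair <- c(ranking$i[r], ranking$j[r])
    ann <- annotate_connection(atlas, pair)
    ss <- strength_stats[strength_stats$id == id, ]
    cs <- scale_stats[scale_stats$id == id, ]
    data.frame(
      id = id,
      regions = paste(atlas$region_name[pair], collapse = ", "),
      repeat_times = ranking$repeat_times[r],
      distance_mm = pair_distance(atlas, pair),
      network = ann$network,
      hemisphere = ann$hemisphere,
      strength_p = ss$p,
      greater_group = ss$greater_group,
      scale = cs$scale, r = cs$r, r_p = cs$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$repeat_times), ]
  rownames(out) <- NULL
  class(out) <- c("connection_report", class(out))
  out
}

#' Write a connection report as TSV
#' @param report a `connection_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a connection report TSV
#' @param path path written by [write_report_tsv()].
#' @return data.frame of class `connection_report`.
#' @export
read_report_tsv <- function(path) {
  out <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("connection_report", class(out))
  out
}
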