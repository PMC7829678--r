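#' Subject-level functional connectivity matrix
#'
#' Pearson correlation between the average time courses of every region
#' pair: the weighted adjacency matrix of the subject's functional brain
#' network. Raw r is kept (no Fisher transform).
#'
#' @param region_ts R x T matrix of regional time courses.
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
build_fc_matrix <- function(region_ts) {
  stopifnot(is.matrix(region_ts), ncol(region_ts) >= 3)
  sds <- apply(region_ts, 1, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant time course in region(s): %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  C <- cor(t(region_ts))
  diag(C) <- 1
  C
}

#' Canonical pair-id string for an unordered region pair
#' @param i,j region ids.
#' @return character like `"5-12"` with the smaller id first.
#' @export
pair_id <- function(i, j) {
  paste0(pmin(i, j), "-", pmax(i, j))
}

#' Enumerate candidate connections anchored on impaired subregions
#'
#' All unordered region pairs with at least one member in the anchor set,
#' in deterministic lexicographic order (by smaller then larger id). For
#' `a` anchors among `R` regions the count is `a*(R-a) + a*(a-1)/2`
#' (3570 for a = 15, R = 246).
#'
#' @param n_regions total region count R.
#' @param anchors integer vector of anchor region ids.
#' @return data.frame with columns `i`, `j` (i < j) and `id`.
#' @export
candidate_pairs <- function(n_regions, anchors) {
  if (length(anchors) == 0) stop("anchor set is empty", call. = FALSE)
  anchors <- sort(unique(as.integer(anchors)))
  if (any(anchors < 1 | anchors > n_regions)) {
    stop("anchors outside 1..n_regions", call. = FALSE)
  }
  is_anchor <- rep(FALSE, n_regions); is_anchor[anchors] <- TRUE
  ij <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  keep <- is_anchor[ij[, 1]] | is_anchor[ij[, 2]]
  ij <- ij[keep, , drop = FALSE]
  ord <- order(ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  data.frame(i = ij[, 1], j = ij[, 2], id = pair_id(ij[, 1], ij[, 2]),
             stringsAsFactors = FALSE)
}

#' Connection feature matrix over candidate pairs
#'
#' Builds the N x p2 matrix of connection strengths (one column per
#' candidate pair touching the anchor set), the feature block fed to the
#' sparse selection stage.
#'
#' @param fc_list list of per-subject connectivity matrices from
#'   [build_fc_matrix()].
#' @param anchors integer vector of anchor (impaired) region ids.
#' @return list of class `connection_features`: `X` (N x p2 matrix, columns
#'   named by pair id), `pairs` (the pair index), `anchors`.
#' @export
extract_candidate_features <- function(fc_list, anchors) {
  stopifnot(length(fc_list) >= 1)
  R <- nrow(fc_list[[1]])
  pairs <- candidate_pairs(R, anchors)
  lin <- (pairs$j - 1L) * R + pairs$i
  X <- t(vapply(fc_list, function(C) C[lin], numeric(nrow(pairs))))
  if (nrow(pairs) == 1) X <- matrix(X, ncol = 1)
  colnames(X) <- pairs$id
  structure(list(X = X, pairs = pairs, anchors = sort(unique(anchors))),
            class = "connection_features")
}

#' Straight-line distance between two subregion centroids
#'
#' Euclidean distance of the MNI centroids, reported to 2 decimals.
#'
#' @param atlas an [atlas_definition()] with centroids.
#' @param pair integer length-2 region pair.
#' @return distance in mm (rounded to 2 decimals).
#' @export
pair_distance <- function(atlas, pair) {
  stopifnot(inherits(atlas, "atlas_definition"), length(pair) == 2)
  if (is.null(atlas$centroid_mni)) stop("atlas has no centroids",
                                        call. = FALSE)
  a <- atlas$centroid_mni[pair[1], ]
  b <- atlas$centroid_mni[pair[2], ]
  if (anyNA(a) || anyNA(b)) {
    stop("missing centroid for one of the regions", call. = FALSE)
  }
  round(sqrt(sum((a - b)^2)), 2)
}

#' Annotate a connection with network pair and hemisphere relation
#'
#' The network annotation is the region's network for within-network pairs,
#' or "A-B" for between-network pairs. Hemisphere is decided by the sign of
#' the centroid x coordinate (negative = left); at x = 0 a `_L_`/`_R_`
#' region-name infix decides, else "midline".
#'
#' @param atlas an [atlas_definition()] with centroids and network labels.
#' @param pair integer length-2 region pair.
#' @return list with `network` (e.g. "DMN" or "FPN-DMN"), `within_network`
#'   (logical), and `hemisphere` ("inter-hemispheric",
#'   "left intra-hemispheric", "right intra-hemispheric", or "midline").
#' @export
annotate_connection <- function(atlas, pair) {
  stopifnot(inherits(atlas, "atlas_definition"), length(pair) == 2)
  n1 <- atlas$network_label[pair[1]]
  n2 <- atlas$network_label[pair[2]]
  within <- n1 == n2
  network <- if (within) n1 else paste(n1, n2, sep = "-")
  hemi_of <- function(r) {
    x <- if (!is.null(atlas$centroid_mni)) atlas$centroid_mni[r, 1] else NA
    if (!is.na(x) && x < 0) return("L")
    if (!is.na(x) && x > 0) return("R")
    nm <- atlas$region_name[r]
    if (grepl("_L_", nm)) "L" else if (grepl("_R_", nm)) "R" else "M"
  }
  h1 <- hemi_of(pair[1]); h2 <- hemi_of(pair[2])
  hemisphere <- if ("M" %in% c(h1, h2)) "midline"
  else if (h1 != h2) "inter-hemispheric"
  else if (h1 == "L") "left intra-hemispheric" else "right intra-hemispheric"
  list(network = network, within_network = within, hemisphere = hemisphere)
}

#' Per-subject strength of one connection
#' @param dataset region-level `study_dataset`.
#' @param pair integer length-2 region pair.
#' @return numeric vector of Pearson correlations, one per subject.
#' @export
connection_strengths <- function(dataset, pair) {
  stopifnot(inherits(dataset, "study_dataset"),
            dataset$signal_type == "region")
  vapply(dataset$signals, function(S) cor(S[pair[1], ], S[pair[2], ]),
         numeric(1))
}
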