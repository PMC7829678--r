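#' Construct a study dataset
#'
#' Bundles the participants table with per-subject signals into the unit of
#' work every pipeline stage consumes. Signals are either region-by-time
#' matrices (rows = atlas regions) or 4D voxel arrays (x, y, z, time); all
#' subjects must share dimensions, repetition time and timepoint count.
#'
#' @param subjects data.frame with at least `subject_id`, `group`, `age`,
#'   `sex`; cognitive scale columns (MoCA, CDT, AVLT, DST, TMT, VFT) are kept
#'   when present. Row order defines subject order for every downstream fold
#'   index.
#' @param signals list of per-subject matrices (R x T) or 4D arrays
#'   (nx, ny, nz, T), one per row of `subjects`.
#' @param tr repetition time in seconds.
#' @param n_timepoints_retained number of volumes retained per subject
#'   (defaults to the time dimension of the signals).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(subjects, signals, tr,
                          n_timepoints_retained = NULL) {
  subjects <- validate_participants(subjects)
  if (!is.list(signals) || length(signals) != nrow(subjects)) {
    stop("`signals` must be a list with one element per subject", call. = FALSE)
  }
  dims <- lapply(signals, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("each signal must be a matrix or array", call. = FALSE)
  }
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1)))) {
    stop("all subjects must share the same signal dimensions", call. = FALSE)
  }
  type <- if (length(d1) == 2L) "region" else if (length(d1) == 4L) "voxel" else
    stop("signals must be R x T matrices or 4D arrays", call. = FALSE)
  n_t <- d1[length(d1)]
  if (is.null(n_timepoints_retained)) n_timepoints_retained <- n_t
  if (n_timepoints_retained != n_t) {
    stop("n_timepoints_retained does not match the signal time dimension",
         call. = FALSE)
  }
  stopifnot(is.numeric(tr), tr > 0)
  structure(
    list(subjects = subjects, signals = signals, tr = tr,
         n_timepoints = n_t, signal_type = type),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects, %s signals, TR = %gs, T = %d\n",
              nrow(x$subjects), x$signal_type, x$tr, x$n_timepoints))
  print(table(x$subjects$group))
  invisible(x)
}

#' Number of subjects in a study dataset
#' @param dataset a `study_dataset`
#' @return integer count
#' @export
n_subjects <- function(dataset) nrow(dataset$subjects)

validate_participants <- function(df) {
  mandatory <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("participants table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(as.character(df$group)), STUDY_GROUPS)
  if (length(bad) > 0) {
    stop(sprintf("unknown group label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(STUDY_GROUPS, collapse = ", ")), call. = FALSE)
  }
  if (!all(df$sex %in% c(0, 1))) {
    stop("sex must be coded 1 (male) / 0 (female)", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  rownames(df) <- NULL
  df
}

#' Read a participants table
#'
#' Reads a tab-delimited participants table with a header naming at least
#' `subject_id`, `group`, `age`, `sex`; additional columns (cognitive scales,
#' FPG, ...) are preserved. File row order is preserved: fold indices
#' reference positions in this order.
#'
#' @param path path to a TSV file.
#' @return data.frame of subject records.
#' @export
read_participants_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_participants(df)
}

#' Write a participants table
#' @param subjects data.frame of subject records.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_participants_table <- function(subjects, path) {
  subjects <- validate_participants(subjects)
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region-by-time matrix
#'
#' Delimited numeric text, by default one row per region (R fixed at the
#' atlas size, T varying by acquisition). Set `orientation` to
#' `"timepoints_in_rows"` for transposed files.
#'
#' @param path path to a TSV file (no header).
#' @param n_regions expected number of regions.
#' @param orientation which dimension the file rows represent.
#' @return numeric matrix with `n_regions` rows.
#' @export
read_region_timeseries <- function(path, n_regions,
                                   orientation = c("regions_in_rows",
                                                   "timepoints_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 idx[1], idx[2], path), call. = FALSE)
  }
  if (orientation == "timepoints_in_rows") num <- t(num)
  if (nrow(num) != n_regions) {
    stop(sprintf("expected %d regions but file has %d rows (orientation = %s)",
                 n_regions, nrow(num), orientation), call. = FALSE)
  }
  dimnames(num) <- NULL
  num
}

#' Write a region-by-time matrix
#' @param mat numeric R x T matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_timeseries <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an integer atlas label volume
#'
#' Loads a NIfTI label volume mapping voxels to atlas region ids
#' (0 = background), inventories the region ids and records the voxel volume
#' from the header.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return list with `label_volume` (3D integer array), `region_ids`, and
#'   `voxel_volume_mm3`.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("label volume must be 3D", call. = FALSE)
  if (max(abs(arr - round(arr))) > 1e-8) {
    stop("label volume must contain integer labels", call. = FALSE)
  }
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  if (all(arr == 0L)) stop("label volume is empty (all zero)", call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  list(label_volume = arr,
       region_ids = sort(unique(arr[arr > 0L])),
       voxel_volume_mm3 = prod(abs(pd)))
}

#' Write an integer atlas label volume
#' @param label_volume 3D integer array (0 = background).
#' @param path output `.nii`/`.nii.gz` path.
#' @param voxel_dims voxel edge lengths in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(label_volume, path, voxel_dims = c(3, 3, 3)) {
  img <- RNifti::asNifti(array(as.integer(label_volume),
                               dim = dim(label_volume)))
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct an atlas definition
#'
#' @param n_regions number of regions (246 for the whole-brain parcellation
#'   used here).
#' @param region_name character vector of region labels.
#' @param network_label resting-state network membership per region, one of
#'   DMN, ECN, FPN, SAN, DAN, VN, other.
#' @param centroid_mni n_regions x 3 matrix of MNI coordinates (mm).
#' @param label_volume optional 3D integer array mapping voxels to region ids.
#' @param voxel_volume_mm3 voxel volume, used to convert overlap counts to mm3.
#' @return object of class `atlas_definition`.
#' @export
atlas_definition <- function(n_regions,
                             region_name = paste0("R", seq_len(n_regions)),
                             network_label = rep("other", n_regions),
                             centroid_mni = NULL,
                             label_volume = NULL,
                             voxel_volume_mm3 = 27) {
  stopifnot(n_regions >= 1, length(region_name) == n_regions,
            length(network_label) == n_regions)
  if (!all(network_label %in% NETWORK_LABELS)) {
    stop("network_label entries must be one of: ",
         paste(NETWORK_LABELS, collapse = ", "), call. = FALSE)
  }
  if (!is.null(centroid_mni)) {
    centroid_mni <- as.matrix(centroid_mni)
    stopifnot(nrow(centroid_mni) == n_regions, ncol(centroid_mni) == 3)
  }
  if (!is.null(label_volume)) {
    ids <- unique(as.integer(label_volume))
    bad <- setdiff(ids, c(0L, seq_len(n_regions)))
    if (length(bad) > 0) {
      stop("label_volume contains ids outside 1..n_regions: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_regions = as.integer(n_regions),
         region_id = seq_len(n_regions),
         region_name = as.character(region_name),
         network_label = as.character(network_label),
         centroid_mni = centroid_mni,
         label_volume = label_volume,
         voxel_volume_mm3 = voxel_volume_mm3),
    class = "atlas_definition"
  )
}

#' @export
print.atlas_definition <- function(x, ...) {
  cat(sprintf("<atlas_definition> %d regions%s%s\n", x$n_regions,
              if (!is.null(x$centroid_mni)) ", centroids" else "",
              if (!is.null(x$label_volume)) ", label volume" else ""))
  invisible(x)
}

#' Write atlas metadata (everything but the label volume) as JSON
#' @param atlas an [atlas_definition()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_atlas_json <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_definition"))
  meta <- list(n_regions = atlas$n_regions,
               region_id = atlas$region_id,
               region_name = atlas$region_name,
               network_label = atlas$network_label,
               centroid_mni = atlas$centroid_mni,
               voxel_volume_mm3 = atlas$voxel_volume_mm3)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read atlas metadata written by [write_atlas_json()]
#' @param path `.json` path.
#' @return `atlas_definition` (without a label volume).
#' @export
read_atlas_json <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas_definition(meta$n_regions,
                   region_name = meta$region_name,
                   network_label = meta$network_label,
                   centroid_mni = meta$centroid_mni,
                   voxel_volume_mm3 = meta$voxel_volume_mm3)
}

#' Published-subregion coordinate and network lookup
#'
#' Returns the shipped lookup of 246-parcellation subregions whose MNI
#' centroids and resting-state network memberships are published for this
#' pipeline's reference cohort (posterior-DMN, executive and visual
#' subregions recurrently impaired in diabetes-related cognitive decline).
#' Only a subset of the 246 regions is covered; synthetic atlases fill the
#' remainder.
#'
#' @return data.frame with columns `region_id`, `region_name`, `network`,
#'   `x`, `y`, `z` (MNI mm).
#' @export
published_region_lookup <- function() {
  path <- system.file("extdata", "region_lookup.tsv", package = "alffconn",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Build a 246-region atlas from the shipped lookup
#'
#' Regions present in [published_region_lookup()] get their published
#' centroids and network labels; all other regions get deterministic
#' placeholder centroids on a lattice spanning MNI space and network label
#' "other". Suitable for distance/annotation computations on the published
#' subset and as a complete atlas skeleton elsewhere.
#'
#' @param n_regions atlas size (default 246).
#' @return `atlas_definition`.
#' @export
reference_atlas <- function(n_regions = 246) {
  lk <- published_region_lookup()
  # deterministic placeholder lattice: odd ids left (x < 0), even right,
  # mirroring the parcellation's left/right interleaving
  ids <- seq_len(n_regions)
  gx <- ifelse(ids %% 2 == 1, -1, 1) * (20 + 40 * ((ids - 1) %/% 2 %% 2))
  gy <- -90 + 180 * (((ids - 1) %/% 4) %% 8) / 7
  gz <- -50 + 120 * (((ids - 1) %/% 32) %% 8) / 7
  cen <- cbind(x = gx, y = gy, z = gz)
  nm <- paste0("R", ids)
  net <- rep("other", n_regions)
  keep <- lk$region_id <= n_regions
  lk <- lk[keep, , drop = FALSE]
  cen[lk$region_id, ] <- as.matrix(lk[, c("x", "y", "z")])
  nm[lk$region_id] <- lk$region_name
  net[lk$region_id] <- lk$network
  atlas_definition(n_regions, region_name = nm, network_label = net,
                   centroid_mni = cen)
}
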