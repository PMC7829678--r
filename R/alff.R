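#' Amplitude of low-frequency fluctuations of one time series
#'
#' Transforms the (linearly detrended) series to the frequency domain, takes
#' the square root of the one-sided power spectrum, and averages it over the
#' discrete frequencies falling inside `band` (endpoints inclusive). The
#' spectrum scaling is `2 |X_k|^2 / T`; any consistent scaling would do since
#' whole-brain standardization divides it out. ALFF is linear in signal
#' amplitude.
#'
#' @param x numeric time series of length T >= 2.
#' @param tr repetition time in seconds.
#' @param band frequency band in Hz, default `c(0.01, 0.08)`.
#' @param detrend remove a linear trend first (default TRUE).
#' @return non-negative scalar.
#' @export
compute_alff <- function(x, tr, band = c(0.01, 0.08), detrend = TRUE) {
  stopifnot(is.numeric(x), length(x) >= 2, tr > 0, length(band) == 2)
  n <- length(x)
  nyq <- 1 / (2 * tr)
  if (band[1] < 0 || band[2] > nyq + 1e-12 || band[1] >= band[2]) {
    stop(sprintf("band must satisfy 0 <= f_lo < f_hi <= Nyquist (%.4g Hz)", nyq),
         call. = FALSE)
  }
  idx <- alff_band_indices(n, tr, band)
  if (length(idx) == 0) {
    df <- 1 / (n * tr)
    stop(sprintf(paste0("no discrete frequency falls inside [%g, %g] Hz; ",
                        "the resolvable grid is k/%g Hz steps of %.5g Hz"),
                 band[1], band[2], n * tr, df), call. = FALSE)
  }
  if (detrend) x <- detrend_linear(x)
  spec <- fft(x)
  power <- 2 * Mod(spec[idx + 1L])^2 / n
  mean(sqrt(power))
}

# 1-based DFT bins k (frequency k/(n*tr)) inside the band, DC (k = 0) never
# included because band[1] > 0 is enforced upstream via f_lo >= band check.
alff_band_indices <- function(n, tr, band) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  k[f >= band[1] - 1e-12 & f <= band[2] + 1e-12]
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  x - mean(x) - tc * sum(tc * x) / sum(tc^2)
}

#' ALFF map over a region matrix or 4D voxel volume
#'
#' Applies [compute_alff()] element-wise within the mask. All-zero (or
#' constant) series yield ALFF 0 with a warning rather than an error.
#'
#' @param signals an R x T region matrix or a 4D (x, y, z, T) array.
#' @param tr repetition time, seconds.
#' @param band frequency band, Hz.
#' @param mask logical vector (length R) or 3D logical array selecting the
#'   elements to compute; default all.
#' @param detrend passed to [compute_alff()].
#' @return object of class `alff_map`: list with `values` (NA outside the
#'   mask), `mask`, `band`, `standardized = FALSE`, and `type`
#'   ("region"/"voxel").
#' @export
compute_alff_map <- function(signals, tr, band = c(0.01, 0.08), mask = NULL,
                             detrend = TRUE) {
  d <- dim(signals)
  if (length(d) == 2L) {
    type <- "region"
    n_el <- d[1]
    series <- signals
  } else if (length(d) == 4L) {
    type <- "voxel"
    n_el <- prod(d[1:3])
    series <- matrix(signals, nrow = n_el)
  } else stop("signals must be an R x T matrix or a 4D array", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n_el)
  mask_v <- as.logical(mask)
  if (length(mask_v) != n_el) stop("mask does not match the signal grid",
                                   call. = FALSE)
  if (!any(mask_v)) stop("mask is empty", call. = FALSE)
  vals <- rep(NA_real_, n_el)
  idxs <- which(mask_v)
  flat <- vapply(idxs, function(i) {
    s <- series[i, ]
    if (sd(s) == 0) return(NA_real_)  # flagged below
    compute_alff(s, tr, band, detrend = detrend)
  }, numeric(1))
  nz <- is.na(flat)
  if (any(nz)) {
    warning(sprintf("%d constant series inside the mask; ALFF recorded as 0",
                    sum(nz)), call. = FALSE)
    flat[nz] <- 0
  }
  vals[idxs] <- flat
  if (type == "voxel") {
    vals <- array(vals, dim = d[1:3])
    mask_out <- array(mask_v, dim = d[1:3])
  } else mask_out <- mask_v
  structure(list(values = vals, mask = mask_out, band = band,
                 standardized = FALSE, type = type),
            class = "alff_map")
}

#' Standardize an ALFF map by its whole-mask mean
#'
#' Divides every value by the mean ALFF over the analysis mask, so the
#' standardized map has mean exactly 1 over the mask. Removes global scaling
#' differences between subjects.
#'
#' @param map an `alff_map`.
#' @param mask optional logical mask overriding the map's own.
#' @return standardized `alff_map`.
#' @export
standardize_alff <- function(map, mask = NULL) {
  stopifnot(inherits(map, "alff_map"))
  if (is.null(mask)) mask <- map$mask
  m <- mean(map$values[as.logical(mask)])
  if (!is.finite(m) || m <= 0) {
    stop("mean ALFF over the mask is not positive; cannot standardize",
         call. = FALSE)
  }
  map$values <- map$values / m
  map$standardized <- TRUE
  map
}

#' Per-subject regional ALFF for a whole dataset
#'
#' Convenience wrapper: standardized regional ALFF for every subject of a
#' region-level dataset, as an R x N matrix.
#'
#' @param dataset a region-level `study_dataset`.
#' @param band frequency band, Hz.
#' @param standardize divide each subject's map by its whole-brain mean
#'   (default TRUE).
#' @return matrix (n_regions x n_subjects).
#' @export
dataset_alff <- function(dataset, band = c(0.01, 0.08), standardize = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"),
            dataset$signal_type == "region")
  vapply(dataset$signals, function(s) {
    m <- compute_alff_map(s, dataset$tr, band)
    if (standardize) m <- standardize_alff(m)
    m$values
  }, numeric(nrow(dataset$signals[[1]])))
}
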