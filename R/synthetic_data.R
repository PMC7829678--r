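#' Synthetic dataset configuration
#'
#' Geometry and acquisition parameters of a synthetic resting-state dataset.
#' Defaults mirror the reference acquisition: 246-region parcellation,
#' TR = 2 s, 230 retained volumes, spontaneous fluctuations band-limited to
#' 0.01-0.08 Hz.
#'
#' @param n_regions number of atlas regions.
#' @param n_timepoints retained volumes per subject (>= 64).
#' @param tr repetition time, seconds.
#' @param band fluctuation band in Hz; `band[2]` must stay below the Nyquist
#'   frequency 1/(2 tr).
#' @param seed master seed; per-subject substreams are spawned from it so a
#'   subject's signals do not depend on group ordering.
#' @param grid_shape integer length-3 voxel grid, required for
#'   [simulate_voxel_dataset()].
#' @param voxel_noise_sd SD of the voxel-level noise added on top of the
#'   shared regional signal in voxel datasets.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 246, n_timepoints = 230, tr = 2,
                             band = c(0.01, 0.08), seed = 1,
                             grid_shape = NULL, voxel_noise_sd = 0.3) {
  stopifnot(n_regions >= 2, n_timepoints >= 64, tr > 0, length(band) == 2)
  if (band[2] >= 1 / (2 * tr)) {
    stop("band[2] must be below the Nyquist frequency 1/(2*tr)", call. = FALSE)
  }
  if (band[1] <= 0 || band[1] >= band[2]) {
    stop("band must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  if (!is.null(grid_shape)) stopifnot(length(grid_shape) == 3,
                                      all(grid_shape >= 1))
  structure(list(n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 tr = tr, band = band, seed = as.integer(seed),
                 grid_shape = grid_shape, voxel_noise_sd = voxel_noise_sd),
            class = "synthetic_config")
}

#' Planted-effect specification
#'
#' Describes the group structure and the effects planted into a synthetic
#' dataset: per-region ALFF scaling factors for designated groups (< 1 means
#' reduced spontaneous activity, ALFF scales by the factor) and target
#' pairwise correlations for designated region pairs in designated groups.
#'
#' @param impaired data.frame with columns `region`, `group`, `factor`
#'   (positive ALFF scaling), or NULL for no ALFF effect. Groups not listed
#'   for a region keep factor 1.
#' @param altered_pairs data.frame with columns `i`, `j`, `group`, `r`
#'   (target Pearson correlation of the pair's time courses in that group,
#'   in (-1, 1)), or NULL. A region may appear in at most one altered pair.
#' @param group_sizes named counts per group; default the retained cohort
#'   19 / 31 / 39 (T2DM-CI / T2DM-NC / HC).
#' @param noise_sd SD of the broadband (white) noise added to the unit-SD
#'   band-limited component.
#' @param covariate_model optional named list per group with elements
#'   `age_mean`, `age_sd`, `p_male`; defaults mirror the reference cohort's
#'   demographics.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(impaired = NULL, altered_pairs = NULL,
                        group_sizes = c("T2DM-CI" = 19, "T2DM-NC" = 31,
                                        "HC" = 39),
                        noise_sd = 0.3, covariate_model = NULL) {
  if (!is.null(impaired)) {
    stopifnot(all(c("region", "group", "factor") %in% names(impaired)))
    if (any(impaired$factor <= 0)) stop("ALFF scaling factors must be > 0",
                                        call. = FALSE)
    bad <- setdiff(impaired$group, STUDY_GROUPS)
    if (length(bad)) stop("unknown group in impaired: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(altered_pairs)) {
    stopifnot(all(c("i", "j", "group", "r") %in% names(altered_pairs)))
    if (any(abs(altered_pairs$r) >= 1)) {
      stop("target correlations must lie in (-1, 1)", call. = FALSE)
    }
    if (any(altered_pairs$i == altered_pairs$j)) {
      stop("altered pairs must join two distinct regions", call. = FALSE)
    }
    for (g in unique(altered_pairs$group)) {
      regs <- with(altered_pairs[altered_pairs$group == g, ], c(i, j))
      if (anyDuplicated(regs)) {
        stop("a region may appear in at most one altered pair per group",
             call. = FALSE)
      }
    }
  }
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% STUDY_GROUPS)) {
    stop("group_sizes must be named with study group labels", call. = FALSE)
  }
  if (any(group_sizes < 2)) stop("each group needs >= 2 subjects",
                                 call. = FALSE)
  structure(list(impaired = impaired, altered_pairs = altered_pairs,
                 group_sizes = group_sizes, noise_sd = noise_sd,
                 covariate_model = covariate_model),
            class = "effect_spec")
}

default_covariate_model <- function() {
  list("T2DM-CI" = list(age_mean = 62.6, age_sd = 4.9, p_male = 12 / 22,
                        moca_mean = 21.9, moca_sd = 2.8),
       "T2DM-NC" = list(age_mean = 59.6, age_sd = 7.6, p_male = 18 / 31,
                        moca_mean = 27.2, moca_sd = 1.15),
       "HC" = list(age_mean = 58.3, age_sd = 6.7, p_male = 23 / 39,
                   moca_mean = 27.2, moca_sd = 1.15))
}

# Unit-SD band-limited Gaussian noise: white noise with all DFT coefficients
# outside the band zeroed (conjugate-symmetric), back-transformed.
band_limited_noise <- function(n, tr, band) {
  z <- rnorm(n)
  zf <- fft(z)
  keep <- rep(FALSE, n)
  k <- alff_band_indices(n, tr, band)
  keep[k + 1L] <- TRUE
  keep[n - k + 1L] <- TRUE
  zf[!keep] <- 0
  x <- Re(fft(zf, inverse = TRUE)) / n
  x / sd(x)
}

# Latent mixing weight needed to reach the target observed correlation once
# ALFF scaling (f_i, f_j) and broadband noise dilute the shared component.
latent_weight <- function(r, f_i, f_j, noise_sd) {
  w <- r * sqrt((f_i^2 + noise_sd^2) * (f_j^2 + noise_sd^2)) / (f_i * f_j)
  if (abs(w) > 0.99) {
    stop(sprintf(paste0("target correlation %.3g is unreachable with the ",
                        "configured noise/ALFF structure (required latent ",
                        "weight %.3g)"), r, w), call. = FALSE)
  }
  w
}

simulate_covariates <- function(groups, effects) {
  cm <- effects$covariate_model
  if (is.null(cm)) cm <- default_covariate_model()
  n <- length(groups)
  age <- numeric(n); sex <- integer(n); moca <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    p <- cm[[g]]
    age[idx] <- pmin(75, pmax(45, rnorm(length(idx), p$age_mean, p$age_sd)))
    sex[idx] <- rbinom(length(idx), 1, p$p_male)
    m <- rnorm(length(idx), p$moca_mean, p$moca_sd)
    # keep the diagnostic MoCA threshold (< 26 for cognitive impairment)
    m <- if (g == "T2DM-CI") pmin(m, 25.5) else pmax(m, 26)
    moca[idx] <- pmin(30, pmax(5, m))
  }
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups, age = round(age, 1), sex = sex,
    MoCA = round(moca, 1),
    CDT = round(pmin(4, pmax(0, rnorm(n, 2.8, 0.6))), 1),
    AVLT = round(pmin(40, pmax(5, rnorm(n, 24, 5))), 1),
    DST = round(pmin(20, pmax(4, rnorm(n, 12, 2.2))), 1),
    TMT = round(pmin(200, pmax(20, rnorm(n, 55, 25))), 1),
    VFT = round(pmin(45, pmax(5, rnorm(n, 22, 6))), 1),
    stringsAsFactors = FALSE
  )
}

# Core generator shared by the region- and voxel-level paths. Returns the
# subjects table and the list of R x T regional signal matrices.
simulate_region_signals <- function(config, effects) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(effects, "effect_spec"))
  R <- config$n_regions
  if (!is.null(effects$impaired) && any(effects$impaired$region > R)) {
    stop("impaired regions reference ids beyond n_regions", call. = FALSE)
  }
  if (!is.null(effects$altered_pairs) &&
      any(c(effects$altered_pairs$i, effects$altered_pairs$j) > R)) {
    stop("altered pairs reference ids beyond n_regions", call. = FALSE)
  }
  gs <- effects$group_sizes
  groups <- rep(names(gs), gs)
  N <- length(groups)
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, N)
  subjects <- simulate_covariates(groups, effects)

  # per-group region -> amplitude factor
  fac <- matrix(1, nrow = R, ncol = length(STUDY_GROUPS),
                dimnames = list(NULL, STUDY_GROUPS))
  if (!is.null(effects$impaired)) {
    for (k in seq_len(nrow(effects$impaired))) {
      e <- effects$impaired[k, ]
      fac[e$region, e$group] <- e$factor
    }
  }
  pairs_by_group <- if (is.null(effects$altered_pairs)) NULL else
    split(effects$altered_pairs, effects$altered_pairs$group)

  T_ <- config$n_timepoints
  sigma <- effects$noise_sd
  signals <- vector("list", N)
  for (s in seq_len(N)) {
    set.seed(subject_seeds[s])
    g <- groups[s]
    f <- fac[, g]
    B <- matrix(0, nrow = R, ncol = T_)
    mixed <- rep(FALSE, R)
    ap <- pairs_by_group[[g]]
    if (!is.null(ap) && nrow(ap) > 0) {
      ap <- ap[order(ap$i, ap$j), , drop = FALSE]
      for (k in seq_len(nrow(ap))) {
        i <- ap$i[k]; j <- ap$j[k]
        w <- latent_weight(ap$r[k], f[i], f[j], sigma)
        L <- band_limited_noise(T_, config$tr, config$band)
        ei <- band_limited_noise(T_, config$tr, config$band)
        ej <- band_limited_noise(T_, config$tr, config$band)
        B[i, ] <- sqrt(abs(w)) * L + sqrt(1 - abs(w)) * ei
        B[j, ] <- sign(w) * sqrt(abs(w)) * L + sqrt(1 - abs(w)) * ej
        mixed[c(i, j)] <- TRUE
      }
    }
    for (r in which(!mixed)) {
      B[r, ] <- band_limited_noise(T_, config$tr, config$band)
    }
    noise <- matrix(rnorm(R * T_, sd = sigma), nrow = R)
    signals[[s]] <- B * f + noise
  }
  list(subjects = subjects, signals = signals)
}

#' Simulate a region-level study dataset
#'
#' Per-subject R x T regional BOLD-like signals: a unit-SD band-limited
#' Gaussian component (the spontaneous fluctuation) plus broadband white
#' noise. Planted ALFF deficits scale the band-limited amplitude of the
#' designated regions in the designated groups; planted connectivity shifts
#' mix a shared band-limited latent into both members of a pair with a
#' weight solved so the observed Pearson correlation approaches the target
#' despite noise dilution. Bit-reproducible given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param effects an [effect_spec()].
#' @return a region-level [study_dataset()].
#' @export
simulate_region_dataset <- function(config, effects = effect_spec()) {
  sim <- simulate_region_signals(config, effects)
  study_dataset(sim$subjects, sim$signals, tr = config$tr)
}

#' Simulate a voxel-level study dataset with a matching label volume
#'
#' The voxel grid is tiled into axis-aligned blocks, one region per block
#' (leftover blocks are background 0). All voxels of a region share its
#' regional signal (with the planted effects) plus independent voxel noise.
#'
#' @param config a [synthetic_config()] with `grid_shape` set.
#' @param effects an [effect_spec()].
#' @return list with `dataset` (voxel-level [study_dataset()]) and `atlas`
#'   (an [atlas_definition()] carrying the label volume).
#' @export
simulate_voxel_dataset <- function(config, effects = effect_spec()) {
  if (is.null(config$grid_shape)) {
    stop("config$grid_shape is required for voxel simulation", call. = FALSE)
  }
  lab <- tile_grid(config$grid_shape, config$n_regions)
  sim <- simulate_region_signals(config, effects)
  T_ <- config$n_timepoints
  nvox <- prod(config$grid_shape)
  vox_of_region <- split(seq_len(nvox), as.vector(lab))
  vox_of_region[["0"]] <- NULL
  signals <- lapply(sim$signals, function(S) {
    V <- matrix(rnorm(nvox * T_, sd = config$voxel_noise_sd), nrow = nvox)
    for (r in names(vox_of_region)) {
      idx <- vox_of_region[[r]]
      V[idx, ] <- V[idx, , drop = FALSE] +
        matrix(S[as.integer(r), ], nrow = length(idx), ncol = T_,
               byrow = TRUE)
    }
    array(V, dim = c(config$grid_shape, T_))
  })
  atlas <- atlas_definition(config$n_regions, label_volume = lab,
                            voxel_volume_mm3 = 27)
  list(dataset = study_dataset(sim$subjects, signals, tr = config$tr),
       atlas = atlas)
}

# Tile a 3D grid into axis-aligned blocks and label the first n_regions of
# them 1..n_regions (remaining blocks are background 0).
tile_grid <- function(grid_shape, n_regions) {
  a <- ceiling(n_regions^(1 / 3))
  b <- ceiling(sqrt(n_regions / a))
  c_ <- ceiling(n_regions / (a * b))
  nb <- c(a, b, c_)
  if (any(nb > grid_shape)) {
    stop(sprintf("grid %s too small for %d regions (needs >= %s blocks)",
                 paste(grid_shape, collapse = "x"), n_regions,
                 paste(nb, collapse = "x")), call. = FALSE)
  }
  cuts <- lapply(1:3, function(d) {
    bounds <- round(seq(0, grid_shape[d], length.out = nb[d] + 1))
    rep(seq_len(nb[d]), diff(bounds))
  })
  bx <- cuts[[1]]; by <- cuts[[2]]; bz <- cuts[[3]]
  lab <- array(0L, dim = grid_shape)
  for (z in seq_len(grid_shape[3]))
    for (y in seq_len(grid_shape[2]))
      lab[, y, z] <- (bx - 1L) + a * (by[y] - 1L) + a * b * (bz[z] - 1L) + 1L
  lab[lab > n_regions] <- 0L
  lab
}

#' Regenerate a cognitive scale to correlate with a connection's strength
#'
#' Computes every subject's Pearson connection strength for `pair`, then
#' redraws the given scale so that its correlation with the strength
#' approaches `r_target` (exact in expectation; sampling noise of order
#' 1/sqrt(N) remains). The scale keeps its original mean and SD.
#'
#' @param dataset a region-level `study_dataset`.
#' @param pair integer length-2 region pair.
#' @param scale scale column name, default "MoCA".
#' @param r_target target correlation, |r| < 1.
#' @param seed RNG seed for the residual draw.
#' @return the dataset with the scale column regenerated.
#' @export
plant_scale_correlation <- function(dataset, pair, scale = "MoCA", r_target,
                                    seed = 1) {
  stopifnot(inherits(dataset, "study_dataset"),
            dataset$signal_type == "region", length(pair) == 2)
  if (abs(r_target) >= 1) stop("|r_target| must be < 1", call. = FALSE)
  R <- nrow(dataset$signals[[1]])
  if (any(pair < 1 | pair > R)) stop("pair references absent regions",
                                     call. = FALSE)
  if (!scale %in% names(dataset$subjects)) {
    stop(sprintf("scale '%s' not present in the participants table", scale),
         call. = FALSE)
  }
  z <- vapply(dataset$signals,
              function(S) cor(S[pair[1], ], S[pair[2], ]), numeric(1))
  zs <- as.numeric(scale(z))
  old <- dataset$subjects[[scale]]
  set.seed(seed)
  eps <- rnorm(length(zs))
  eps <- as.numeric(scale(eps - zs * sum(eps * zs) / sum(zs^2)))
  newv <- r_target * zs + sqrt(1 - r_target^2) * eps
  dataset$subjects[[scale]] <- mean(old) + sd(old) * newv
  dataset
}
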