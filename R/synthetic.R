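#' Synthetic cohort specification
#'
#' Parameters of the generative model emulating an uncertainty-variation
#' threat-anticipation study: each participant completes `n_runs` runs
#' with `trials_per_condition_per_run` anticipation trials in each of four
#' cue conditions (certain safety, low / medium / high shock uncertainty),
#' rates anxious arousal from 1 (none) to 5 (extreme) after each anticipation
#' epoch, and receives a shock after a condition-dependent fraction of
#' uncertain-threat trials (60% in the reference paradigm, safety never
#' shocked). Trial activation is a participant-specific gain times the rating
#' times a distributed ground-truth pattern, plus confound patterns (an
#' autonomic-arousal-like covariate partially correlated with ratings, and a
#' visual cue pattern tracking condition), plus spatially smooth Gaussian
#' noise.
#'
#' @param n_participants number of participants.
#' @param n_runs runs per participant.
#' @param trials_per_condition_per_run anticipation trials per condition and
#'   run (5 in the reference paradigm).
#' @param conditions ordered condition labels.
#' @param condition_rating_means mean 1-5 rating per condition; must be
#'   nondecreasing in the given condition order.
#' @param rating_sd SD of the latent Gaussian rating before rounding/clipping.
#' @param shock_probability per-condition probability that a trial is followed
#'   by a shock.
#' @param signal_amplitude beta units of pattern expression per rating unit.
#' @param confound_amplitude beta units of the arousal-like confound pattern.
#' @param confound_rating_correlation target correlation between the confound
#'   amplitude and the realized ratings, in \[-1, 1\].
#' @param visual_amplitude beta units of the condition-cue (visual) pattern
#'   per condition step (0 = safety ... 3 = high).
#' @param noise_sd per-voxel SD of the smooth Gaussian noise (beta units).
#' @param smoothing_fwhm FWHM (mm) of the Gaussian kernel applied to the
#'   white-noise field, emulating smoothed fMRI residuals.
#' @param gain_log_sd SD of log participant gain (log-normal heterogeneity).
#' @param seed integer seed; every random draw is derived from it.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_participants = 30,
                       n_runs = 4,
                       trials_per_condition_per_run = 5,
                       conditions = c("safety", "low", "medium", "high"),
                       condition_rating_means = c(1.2, 2.4, 3.3, 4.3),
                       rating_sd = 0.8,
                       shock_probability = c(0, 0.6, 0.6, 0.6),
                       signal_amplitude = 0.1,
                       confound_amplitude = 0,
                       confound_rating_correlation = 0.5,
                       visual_amplitude = 0,
                       noise_sd = 0.04,
                       smoothing_fwhm = 8,
                       gain_log_sd = 0.3,
                       seed = 1L) {
  stopifnot(length(conditions) == length(condition_rating_means),
            length(conditions) == length(shock_probability))
  if (is.unsorted(condition_rating_means))
    stop("condition_rating_means must be nondecreasing across conditions")
  if (any(shock_probability < 0 | shock_probability > 1))
    stop("shock probabilities must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (abs(confound_rating_correlation) > 1)
    stop("confound_rating_correlation must lie in [-1, 1]")
  structure(as.list(environment()), class = "synth_spec")
}

# Separable 3-D Gaussian filtering of an array; sigma in voxels per axis.
# Each axis is convolved with a truncated (+-4 sigma) normalized kernel via a
# dense band matrix, which is fast for the small grids used in simulation.
smooth_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    n <- d[ax]
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      S[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dims <- dim(a)
    a <- S %*% matrix(a, nrow = dims[1])
    dim(a) <- dims
    arr <- aperm(a, order(perm))
  }
  arr
}

# sd attenuation factor of unit white noise after smooth_gaussian()
smoothing_sd_factor <- function(shape, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  f <- 1
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    f <- f * sqrt(sum(k^2))
  }
  f
}

fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / sqrt(8 * log(2))) / voxel_size_mm
}

#' Generate a distributed ground-truth pattern
#'
#' Places `n_blobs` compact Gaussian-profile blobs at random in-mask
#' locations, mimicking the multi-region support of a distributed neural
#' signature. Values are positive within each blob and zero elsewhere; the
#' map is scaled to unit Euclidean norm. Blob centres are drawn at least
#' `2 * blob_radius_mm + 2` voxel-widths apart so the blobs form disjoint
#' connected components.
#'
#' @param mask a [brain_mask].
#' @param n_blobs number of blobs (>= 1).
#' @param blob_radius_mm blob support radius in mm.
#' @param seed integer seed (deterministic placement).
#' @param within optional logical vector over mask voxels restricting where
#'   blob centres and support may fall.
#' @return an [activation_map] with unit L2 norm (`unit = "contrast"`).
#' @export
make_pattern <- function(mask, n_blobs = 3, blob_radius_mm = 6, seed = 1L,
                         within = NULL) {
  stopifnot(inherits(mask, "brain_mask"), n_blobs >= 1)
  grid <- mask$grid
  if (blob_radius_mm >= min(grid$shape * grid$voxel_size) / 2)
    stop("blob radius exceeds grid extent")
  coords <- arrayInd(mask$indices, grid$shape)   # n_voxels x 3, voxel units
  mm <- coords * rep(grid$voxel_size, each = nrow(coords))
  eligible <- if (is.null(within)) seq_len(mask$n_voxels) else which(within)
  if (!length(eligible)) stop("no eligible voxels for blob placement")
  # separation keeps supports > 1 voxel apart: distinct 6-connected components
  min_sep <- 2 * blob_radius_mm + 1.5 * min(grid$voxel_size)
  rng <- local_rng(seed)
  centres <- integer(0)
  for (restart in 1:50) {
    centres <- integer(0)
    for (b in seq_len(n_blobs)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- eligible[rng$int(length(eligible))]
        if (length(centres) == 0 ||
            all(sqrt(colSums((t(mm[centres, , drop = FALSE]) -
                                mm[cand, ])^2)) >= min_sep)) {
          centres <- c(centres, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
    if (length(centres) == n_blobs) break
  }
  if (length(centres) < n_blobs)
    stop("could not place ", n_blobs, " non-overlapping blobs in the mask")
  vals <- numeric(mask$n_voxels)
  sigma <- blob_radius_mm / 2
  for (cv in centres) {
    d2 <- colSums((t(mm) - mm[cv, ])^2)
    inside <- d2 <= blob_radius_mm^2
    if (!is.null(within)) inside <- inside & seq_along(d2) %in% eligible
    vals[inside] <- vals[inside] + exp(-d2[inside] / (2 * sigma^2))
  }
  vals <- vals / sqrt(sum(vals^2))
  activation_map(vals, mask, unit = "contrast",
                 condition = sprintf("pattern_%dblobs", n_blobs))
}

#' Ground truth of a synthetic cohort
#'
#' Bundles the generating patterns and per-participant gains that downstream
#' recovery analyses are scored against.
#'
#' @param anxiety_pattern unit-norm [activation_map]: the latent pattern whose
#'   expression scales with the rating.
#' @param confound_patterns named list of [activation_map]s (e.g. `arousal`,
#'   `visual`) sharing the anxiety pattern's mask.
#' @param per_participant_gain numeric vector of multiplicative gains.
#' @param generative_noise_sd the noise SD used at generation time.
#' @export
synthetic_ground_truth <- function(anxiety_pattern, confound_patterns = list(),
                                   per_participant_gain,
                                   generative_noise_sd) {
  stopifnot(inherits(anxiety_pattern, "activation_map"))
  nrm <- sqrt(sum(anxiety_pattern$values^2))
  if (abs(nrm - 1) > 1e-8) stop("anxiety_pattern must have unit L2 norm")
  for (p in confound_patterns)
    if (!grids_match(p$mask$grid, anxiety_pattern$mask$grid))
      stop("confound patterns must share the anxiety pattern's mask")
  structure(list(anxiety_pattern = anxiety_pattern,
                 confound_patterns = confound_patterns,
                 per_participant_gain = per_participant_gain,
                 generative_noise_sd = generative_noise_sd),
            class = "synthetic_ground_truth")
}

# Small counter-based RNG wrapper: isolates all synthetic draws from the
# global RNG state and derives independent substreams from (seed, tag).
local_rng <- function(seed, tag = 0L) {
  env <- new.env()
  env$state <- NULL
  with_stream <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    if (is.null(env$state)) {
      set.seed((as.integer(seed) + 1000003L * as.integer(tag)) %% .Machine$integer.max)
    } else assign(".Random.seed", env$state, envir = globalenv())
    res <- f()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    norm = function(n) with_stream(function() stats::rnorm(n)),
    unif = function(n) with_stream(function() stats::runif(n)),
    int  = function(n, size = 1) with_stream(function() sample.int(n, size)),
    perm = function(n) with_stream(function() sample.int(n)),
    binom = function(n, p) with_stream(function() stats::rbinom(n, 1L, p))
  )
}

#' Simulate one participant's trials
#'
#' Draws a full set of anticipation trials for one participant under the
#' generative model: the latent rating is Gaussian around the condition mean,
#' rounded and clipped to 1-5; each trial's activation vector is
#' `signal_amplitude * gain * rating * anxiety_pattern` plus
#' `confound_amplitude * c_t * arousal_pattern` (with `c_t` constructed to
#' correlate `confound_rating_correlation` with the realized ratings) plus
#' `visual_amplitude * condition_step * visual_pattern` plus spatially smooth
#' Gaussian noise of per-voxel SD `noise_sd`. Shock-followed flags are drawn
#' per condition.
#'
#' @param spec a [synth_spec].
#' @param gt a [synthetic_ground_truth].
#' @param participant participant index (also selects the gain entry).
#' @return a `beta_series`: list with `X` (trials x voxels matrix), `trials`
#'   (data.frame with participant, run, condition, rating, shock_followed,
#'   onset, duration), and `mask`.
#' @export
simulate_trials <- function(spec, gt, participant = 1L) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(gt, "synthetic_ground_truth"))
  gain <- gt$per_participant_gain[participant]
  if (is.na(gain)) stop("no gain defined for participant ", participant)
  mask <- gt$anxiety_pattern$mask
  rng <- local_rng(spec$seed, tag = 17L * as.integer(participant))
  k <- length(spec$conditions)
  tpc <- spec$trials_per_condition_per_run
  n_per_run <- k * tpc
  n_trials <- spec$n_runs * n_per_run

  cond_idx <- integer(0)
  for (r in seq_len(spec$n_runs))
    cond_idx <- c(cond_idx, rng$perm(n_per_run) %% k + 1L)
  run <- rep(seq_len(spec$n_runs), each = n_per_run)

  latent <- spec$condition_rating_means[cond_idx] +
    spec$rating_sd * rng$norm(n_trials)
  rating <- pmin(5L, pmax(1L, as.integer(round(latent))))
  shock <- rng$binom(n_trials, spec$shock_probability[cond_idx]) == 1L

  # cue 6-10 s, outcome 2 s, rating 4 s, fixation 6 s
  duration <- 6 + 4 * rng$unif(n_trials)
  iti <- 12
  onset <- numeric(n_trials)
  for (r in seq_len(spec$n_runs)) {
    sel <- which(run == r)
    onset[sel] <- cumsum(c(6, duration[sel][-length(sel)] + iti))
  }

  # arousal-like confound correlated with realized ratings (shared latent)
  rho <- spec$confound_rating_correlation
  zr <- if (stats::sd(rating) > 0) as.numeric(scale(rating)) else
    numeric(n_trials)
  c_t <- rho * zr + sqrt(max(0, 1 - rho^2)) * rng$norm(n_trials)

  amp <- spec$signal_amplitude * gain * rating
  X <- tcrossprod(amp, gt$anxiety_pattern$values)
  if (spec$confound_amplitude != 0 &&
      !is.null(gt$confound_patterns$arousal))
    X <- X + tcrossprod(spec$confound_amplitude * c_t,
                        gt$confound_patterns$arousal$values)
  if (spec$visual_amplitude != 0 && !is.null(gt$confound_patterns$visual))
    X <- X + tcrossprod(spec$visual_amplitude * (cond_idx - 1),
                        gt$confound_patterns$visual$values)

  sigma_vox <- fwhm_to_sigma(spec$smoothing_fwhm, mask$grid$voxel_size)
  att <- smoothing_sd_factor(mask$grid$shape, sigma_vox)
  noise <- matrix(0, n_trials, mask$n_voxels)
  shp <- mask$grid$shape
  for (t in seq_len(n_trials)) {
    w <- array(rng$norm(prod(shp)), dim = shp)
    w <- smooth_gaussian(w, sigma_vox) / att
    noise[t, ] <- w[mask$indices]
  }
  X <- X + spec$noise_sd * noise

  trials <- data.frame(
    participant = participant, run = run, trial = seq_len(n_trials),
    condition = spec$conditions[cond_idx], rating = rating,
    shock_followed = shock, onset = onset, duration = duration,
    confound = c_t, stringsAsFactors = FALSE)
  structure(list(X = X, trials = trials, mask = mask),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("beta_series:", nrow(x$X), "trials x", ncol(x$X), "voxels;",
      sum(!x$trials$shock_followed), "no-shock trials\n")
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Builds a mask-shaped ground truth (anxiety + confound patterns,
#' log-normal participant gains) and simulates every participant's beta
#' series under one [synth_spec].
#'
#' @param spec a [synth_spec].
#' @param mask a [brain_mask].
#' @param n_blobs blobs in the anxiety pattern.
#' @param blob_radius_mm blob radius (mm).
#' @param anxiety_pattern optional pre-built pattern overriding the random
#'   one (e.g. for orthogonal-pattern specificity designs).
#' @return list with `gt` ([synthetic_ground_truth]), `participants` (list of
#'   `beta_series`), and `spec`.
#' @export
simulate_cohort <- function(spec, mask, n_blobs = 3, blob_radius_mm = 6,
                            anxiety_pattern = NULL) {
  rng <- local_rng(spec$seed, tag = 5L)
  if (is.null(anxiety_pattern))
    anxiety_pattern <- make_pattern(mask, n_blobs, blob_radius_mm,
                                    seed = spec$seed + 101L)
  confounds <- list(
    arousal = make_pattern(mask, 1, blob_radius_mm, seed = spec$seed + 211L),
    visual = make_pattern(mask, 1, blob_radius_mm, seed = spec$seed + 307L))
  gains <- exp(spec$gain_log_sd * rng$norm(spec$n_participants))
  gt <- synthetic_ground_truth(anxiety_pattern, confounds, gains,
                               spec$noise_sd)
  participants <- lapply(seq_len(spec$n_participants),
                         function(p) simulate_trials(spec, gt, p))
  list(gt = gt, participants = participants, spec = spec)
}

#' Average no-shock trials by rating level
#'
#' Builds the per-participant training maps of the population signature: for
#' each rating level the participant actually used, the mean of that
#' participant's no-shock anticipation trial vectors at that level.
#' Shock-followed trials are excluded; rating levels with no no-shock trials
#' are simply absent (participants typically contribute 3-5 maps).
#'
#' @param beta_series a `beta_series` from [simulate_trials()] or a
#'   trial-wise GLM.
#' @return list of [activation_map]s (`unit = "rating-level"`), one per
#'   observed rating level, or an empty list with a warning when every trial
#'   was shock-followed.
#' @export
aggregate_by_rating <- function(beta_series) {
  tr <- beta_series$trials
  keep <- !tr$shock_followed & !is.na(tr$rating)
  if (!any(keep)) {
    warning("all trials shock-followed: no rating-level maps")
    return(list())
  }
  out <- list()
  for (lev in sort(unique(tr$rating[keep]))) {
    sel <- keep & tr$rating == lev
    out[[length(out) + 1L]] <- activation_map(
      colMeans(beta_series$X[sel, , drop = FALSE]),
      beta_series$mask,
      participant = tr$participant[1], unit = "rating-level", rating = lev)
  }
  out
}

#' Simulate BOLD time series from a beta series
#'
#' Forms a 4-D BOLD run set by convolving each trial's boxcar with the
#' canonical double-gamma HRF and mixing the trial activation vectors through
#' the resulting per-trial regressors: `Y = R %*% B` plus AR(1) noise and a
#' low-frequency drift whose regressors are returned for use as nuisance
#' columns. Uses the same regressor construction as [build_design()], so a
#' noiseless simulation is exactly recovered by OLS.
#'
#' @param beta_series a `beta_series` (its `trials` table supplies onsets,
#'   durations and runs; its `X` the trial activation vectors).
#' @param tr_s repetition time in seconds (2 s in the reference acquisition).
#' @param noise_sd marginal SD of the AR(1) noise (0 for noiseless).
#' @param ar1_phi lag-1 autocorrelation of the noise.
#' @param drift_amplitude SD of per-voxel loading on a linear drift.
#' @param hrf an [hrf_spec].
#' @param seed integer seed.
#' @return list with `bold` (frames x voxels matrix), `frame_times`,
#'   `run_labels`, `nuisance` (data.frame of drift regressors) and the input
#'   `trials` table.
#' @export
simulate_bold <- function(beta_series, tr_s = 2, noise_sd = 1,
                          ar1_phi = 0.4, drift_amplitude = 0,
                          hrf = hrf_spec(), seed = 1L) {
  tr <- beta_series$trials
  if (any(tr$duration < 0)) stop("negative trial durations")
  rng <- local_rng(seed, tag = 23L)
  runs <- sort(unique(tr$run))
  bold <- NULL; ft_all <- NULL; run_lab <- NULL
  for (r in runs) {
    sel <- tr$run == r
    t_end <- max(tr$onset[sel] + tr$duration[sel]) + 20
    n_frames <- ceiling(t_end / tr_s)
    ft <- (seq_len(n_frames) - 1) * tr_s
    R <- trial_regressors(tr$onset[sel], tr$duration[sel], ft, tr_s, hrf)
    Y <- R %*% beta_series$X[sel, , drop = FALSE]
    if (noise_sd > 0) {
      innov_sd <- noise_sd * sqrt(1 - ar1_phi^2)
      e <- matrix(rng$norm(n_frames * ncol(Y)) * innov_sd, n_frames)
      e <- apply(e, 2, function(col)
        as.numeric(stats::filter(col, ar1_phi, method = "recursive")))
      Y <- Y + e
    }
    if (drift_amplitude > 0) {
      drift <- scale(ft)
      Y <- Y + drift %*% t(rng$norm(ncol(Y)) * drift_amplitude)
    }
    bold <- rbind(bold, Y)
    ft_all <- c(ft_all, ft)
    run_lab <- c(run_lab, rep(r, n_frames))
  }
  nuis <- data.frame(drift_linear = as.numeric(scale(ft_all)))
  list(bold = bold, frame_times = ft_all, run_labels = run_lab,
       nuisance = nuis, trials = tr)
}
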