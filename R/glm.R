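#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical haemodynamic response function modelled as the
#' difference of two gamma densities: a positive response peaking ~5-6 s
#' after stimulus onset and a later undershoot, in the widely used
#' parameterization (peak delay 6 s, undershoot delay 16 s, dispersions 1,
#' peak:undershoot ratio 6, 32 s kernel).
#'
#' @param peak_delay_s,undershoot_delay_s gamma delays (s).
#' @param peak_dispersion,undershoot_dispersion gamma dispersions.
#' @param peak_undershoot_ratio ratio of peak to undershoot amplitude.
#' @param kernel_length_s kernel support (s).
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6, kernel_length_s = 32) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_dispersion,
            undershoot_dispersion, peak_undershoot_ratio, kernel_length_s)
  if (any(vals <= 0)) stop("all HRF parameters must be positive")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length_s = kernel_length_s),
            class = "hrf_spec")
}

#' Sample the canonical double-gamma HRF
#'
#' `h(t) = g(t; delay_p/disp_p, disp_p) - g(t; delay_u/disp_u, disp_u)/ratio`,
#' with `g` the gamma density (shape, scale), peak-normalized so
#' `max(h) = 1`.
#'
#' @param spec an [hrf_spec].
#' @param dt_s sampling interval (s); must divide `kernel_length_s`.
#' @return numeric kernel sampled at `seq(0, kernel_length_s, by = dt_s)`.
#' @export
canonical_hrf <- function(spec = hrf_spec(), dt_s = 0.1) {
  stopifnot(inherits(spec, "hrf_spec"))
  if (abs(spec$kernel_length_s / dt_s - round(spec$kernel_length_s / dt_s)) >
      1e-8)
    stop("dt_s must divide kernel_length_s")
  t <- seq(0, spec$kernel_length_s, by = dt_s)
  h <- stats::dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    stats::dgamma(t, shape = spec$undershoot_delay_s /
                    spec$undershoot_dispersion,
                  scale = spec$undershoot_dispersion) /
    spec$peak_undershoot_ratio
  h / max(h)
}

# Convolved regressor matrix (frames x trials). Boxcars are built on a
# microtime grid of dt = tr_s/16, convolved with the HRF, and sampled at the
# frame acquisition times.
trial_regressors <- function(onsets, durations, frame_times, tr_s,
                             hrf = hrf_spec(), oversample = 16L) {
  dt <- tr_s / oversample
  t_max <- max(frame_times) + tr_s + hrf$kernel_length_s
  n_hi <- ceiling(t_max / dt) + 1L
  kern_len <- round(hrf$kernel_length_s / dt)
  kern <- canonical_hrf(hrf, dt_s = hrf$kernel_length_s / kern_len)
  R <- matrix(0, length(frame_times), length(onsets))
  for (j in seq_along(onsets)) {
    box <- numeric(n_hi)
    i0 <- floor(onsets[j] / dt) + 1L
    i1 <- min(n_hi, ceiling((onsets[j] + durations[j]) / dt))
    box[i0:i1] <- 1
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_hi)]
    R[, j] <- conv[pmin(n_hi, round(frame_times / dt) + 1L)]
  }
  R
}

#' Expand 6 motion parameters to the 24-parameter nuisance set
#'
#' The standard expansion: the 6 realignment parameters demeaned, their
#' first-order temporal derivatives, and the squares of those 12.
#'
#' @param motion6 frames x 6 matrix of realignment parameters.
#' @return frames x 24 matrix with descriptive column names.
#' @export
motion_expand <- function(motion6) {
  motion6 <- as.matrix(motion6)
  stopifnot(ncol(motion6) == 6)
  dm <- scale(motion6, center = TRUE, scale = FALSE)
  dv <- rbind(0, diff(dm))
  out <- cbind(dm, dv, dm^2, dv^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("mot_d", 1:6),
                     paste0("mot_sq", 1:6), paste0("mot_dsq", 1:6))
  out
}

# Discrete-cosine high-pass drift basis (cutoff in seconds)
dct_basis <- function(frame_times, cutoff_s = 128) {
  n <- length(frame_times)
  dur <- max(frame_times) - min(frame_times)
  k_max <- floor(2 * dur / cutoff_s)
  if (k_max < 1) return(NULL)
  t01 <- (frame_times - min(frame_times)) / dur
  b <- sapply(seq_len(k_max), function(k) cos(pi * k * t01))
  colnames(b) <- paste0("dct", seq_len(k_max))
  b
}

#' Nuisance specification for first-level designs
#'
#' @param motion_expansion include the 24-parameter motion set built from 6
#'   realignment parameters.
#' @param fd_spike_threshold_mm framewise-displacement threshold above which
#'   a frame gets a one-hot spike regressor (0.50 mm default).
#' @param extra_spikes additional frame indices to model as spikes.
#' @param highpass_cutoff_s discrete-cosine drift cutoff (s); `NA` disables.
#' @export
nuisance_spec <- function(motion_expansion = TRUE,
                          fd_spike_threshold_mm = 0.50,
                          extra_spikes = integer(0),
                          highpass_cutoff_s = 128) {
  if (!is.na(fd_spike_threshold_mm) && fd_spike_threshold_mm <= 0)
    stop("fd_spike_threshold_mm must be > 0")
  structure(list(motion_expansion = motion_expansion,
                 fd_spike_threshold_mm = fd_spike_threshold_mm,
                 extra_spikes = as.integer(extra_spikes),
                 highpass_cutoff_s = highpass_cutoff_s),
            class = "nuisance_spec")
}

#' Build a first-level design matrix
#'
#' Constructs the concatenated-run design in one of two modes. In
#' `"per-rating"` mode, no-shock anticipation epochs get one HRF-convolved
#' boxcar column per observed rating level (a level with zero events is
#' omitted, never zero-filled); shock-followed anticipations and any
#' no-interest epochs (`trial_type` of `outcome`, `rating`, `dummy_fast`,
#' `dummy_slow`, `missed`, ...) each get their own column; unmodelled time is
#' the implicit fixation baseline. In `"per-trial"` mode every anticipation
#' epoch gets its own column (a beta-series design). Motion, spike, drift and
#' per-run intercept columns are appended.
#'
#' @param events events data.frame (see [read_events()]).
#' @param frame_times frame acquisition times (s), 0-based per run then
#'   concatenated; times are interpreted within `run_labels`.
#' @param run_labels per-frame run id (same length as `frame_times`).
#' @param tr_s repetition time (s).
#' @param hrf an [hrf_spec].
#' @param mode `"per-rating"` or `"per-trial"`.
#' @param nuisance a [nuisance_spec].
#' @param motion optional frames x 6 realignment-parameter matrix.
#' @param fd optional per-frame framewise displacement (mm) for spikes.
#' @param extra_nuisance optional numeric matrix of additional regressors.
#' @return object of class `design_matrix`: list with `X` (frames x columns),
#'   `task_columns` (names of regressors of interest), `task_info`
#'   (data.frame describing each task column), `frame_times`, `run_labels`.
#' @export
build_design <- function(events, frame_times, run_labels, tr_s = 2,
                         hrf = hrf_spec(),
                         mode = c("per-rating", "per-trial"),
                         nuisance = nuisance_spec(),
                         motion = NULL, fd = NULL, extra_nuisance = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(frame_times) == length(run_labels))
  antic <- events$trial_type == "anticipation"

  blocks <- list()   # each: list(name, rows, info)
  if (mode == "per-rating") {
    noshock <- antic & !events$shock_followed & !is.na(events$rating)
    for (lev in sort(unique(events$rating[noshock])))
      blocks[[length(blocks) + 1L]] <- list(
        name = paste0("rating_", lev),
        rows = which(noshock & events$rating == lev),
        info = data.frame(kind = "rating", rating = lev))
    if (any(antic & events$shock_followed))
      blocks[[length(blocks) + 1L]] <- list(
        name = "anticipation_shock",
        rows = which(antic & events$shock_followed),
        info = data.frame(kind = "no-interest", rating = NA))
  } else {
    for (i in which(antic))
      blocks[[length(blocks) + 1L]] <- list(
        name = sprintf("trial_%03d", i),
        rows = i,
        info = data.frame(kind = "trial", rating = events$rating[i]))
  }
  for (tt in setdiff(unique(events$trial_type), "anticipation"))
    blocks[[length(blocks) + 1L]] <- list(
      name = tt, rows = which(events$trial_type == tt),
      info = data.frame(kind = "no-interest", rating = NA))

  n_frames <- length(frame_times)
  task <- matrix(0, n_frames, length(blocks))
  colnames(task) <- vapply(blocks, `[[`, "", "name")
  for (r in unique(run_labels)) {
    fsel <- run_labels == r
    for (j in seq_along(blocks)) {
      rows <- blocks[[j]]$rows
      rows <- rows[events$run[rows] == r]
      if (!length(rows)) next
      R <- trial_regressors(events$onset[rows], events$duration[rows],
                            frame_times[fsel], tr_s, hrf)
      task[fsel, j] <- task[fsel, j] + rowSums(R)
    }
  }
  if (any(colSums(abs(task)) == 0))
    stop("all-zero task column(s): ",
         paste(colnames(task)[colSums(abs(task)) == 0], collapse = ", "))

  conf <- NULL
  if (!is.null(motion) && isTRUE(nuisance$motion_expansion))
    conf <- cbind(conf, motion_expand(motion))
  else if (!is.null(motion)) {
    m <- as.matrix(motion); colnames(m) <- paste0("mot", seq_len(ncol(m)))
    conf <- cbind(conf, m)
  }
  spikes <- nuisance$extra_spikes
  if (!is.null(fd))
    spikes <- union(spikes, which(fd > nuisance$fd_spike_threshold_mm))
  for (s in sort(spikes)) {
    col <- numeric(n_frames); col[s] <- 1
    conf <- cbind(conf, col)
    colnames(conf)[ncol(conf)] <- paste0("spike_", s)
  }
  if (!is.na(nuisance$highpass_cutoff_s)) {
    for (r in unique(run_labels)) {
      fsel <- run_labels == r
      b <- dct_basis(frame_times[fsel], nuisance$highpass_cutoff_s)
      if (!is.null(b)) {
        bb <- matrix(0, n_frames, ncol(b))
        bb[fsel, ] <- b
        colnames(bb) <- paste0("run", r, "_", colnames(b))
        conf <- cbind(conf, bb)
      }
    }
  }
  if (!is.null(extra_nuisance)) {
    en <- as.matrix(extra_nuisance)
    if (is.null(colnames(en)))
      colnames(en) <- paste0("nuis", seq_len(ncol(en)))
    conf <- cbind(conf, en)
  }
  intercepts <- sapply(unique(run_labels),
                       function(r) as.numeric(run_labels == r))
  colnames(intercepts) <- paste0("run", unique(run_labels), "_intercept")

  X <- cbind(task, conf, intercepts)
  if (anyDuplicated(colnames(X))) stop("duplicate design column names")
  structure(list(X = X, task_columns = colnames(task),
                 task_info = do.call(rbind, lapply(seq_along(blocks),
                   function(j) cbind(name = blocks[[j]]$name,
                                     blocks[[j]]$info))),
                 frame_times = frame_times, run_labels = run_labels),
            class = "design_matrix")
}

#' Fit a first-level GLM by ordinary least squares
#'
#' Per-voxel OLS of the BOLD data on the design; returns the beta estimates
#' of the task columns and a residual-variance map for diagnostics. A
#' rank-deficient design raises an error naming the collinear columns (no
#' silent pseudo-inverse).
#'
#' @param bold frames x voxels matrix (vectorized over a mask), or a 4-D
#'   array with a `mask` supplied.
#' @param design a `design_matrix` from [build_design()], or any numeric
#'   matrix with column names.
#' @param mask optional [brain_mask] used to vectorize a 4-D `bold` array.
#' @return list with `betas` (task columns x voxels), `task_columns`,
#'   `residual_variance` (per voxel), `df_residual`.
#' @export
fit_glm <- function(bold, design, mask = NULL) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  task_cols <- if (inherits(design, "design_matrix")) design$task_columns
               else colnames(X)
  if (length(dim(bold)) == 4L) {
    stopifnot(inherits(mask, "brain_mask"))
    bold <- t(apply(bold, 4, function(v) v[mask$indices]))
  }
  bold <- as.matrix(bold)
  if (nrow(bold) != nrow(X))
    stop("frames (", nrow(bold), ") do not match design rows (", nrow(X), ")")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qr_x, bold)
  resid <- bold - X %*% betas
  dfres <- nrow(X) - ncol(X)
  list(betas = betas[task_cols, , drop = FALSE],
       task_columns = task_cols,
       residual_variance = colSums(resid^2) / max(dfres, 1L),
       df_residual = dfres)
}

#' Extract a beta series from a per-trial GLM fit
#'
#' Combines a `"per-trial"` [fit_glm()] result with its events table into the
#' `beta_series` container used by the signature modules.
#'
#' @param fit result of [fit_glm()] on a per-trial design.
#' @param design the `design_matrix` used.
#' @param events the events table passed to [build_design()].
#' @param mask the [brain_mask] the data were vectorized over.
#' @param participant participant id recorded in the trial table.
#' @export
beta_series_from_glm <- function(fit, design, events, mask,
                                 participant = NA) {
  info <- design$task_info
  trial_rows <- info$kind == "trial"
  idx <- match(info$name[trial_rows], rownames(fit$betas))
  ev_idx <- as.integer(sub("trial_", "", info$name[trial_rows]))
  trials <- events[ev_idx, , drop = FALSE]
  trials$participant <- participant
  trials$trial <- seq_len(nrow(trials))
  structure(list(X = fit$betas[idx, , drop = FALSE],
                 trials = trials, mask = mask),
            class = "beta_series")
}
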