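#' Retrain a signature restricted to an ROI
#'
#' Refits the SVR using only the ROI's voxels as features, under the same
#' participant-grouped cross-validation scheme and metrics as the
#' whole-brain model, to test whether a single region carries the
#' distributed signal.
#'
#' @param maps maps x voxels matrix or list of [activation_map]s (voxel
#'   order = analysis-mask order).
#' @param roi logical vector over the mask voxels, or integer voxel
#'   positions.
#' @param ratings,participants per-map labels.
#' @param scheme a [cv_scheme].
#' @param config a [train_config].
#' @return list with `model` (`signature_model` trained on all maps, ROI
#'   features only; weights are zero outside the ROI so the model applies
#'   to full-mask maps), `cv` (a `prediction_result`), `roi_size`.
#' @export
restrict_train <- function(maps, roi, ratings, participants,
                           scheme = cv_scheme(), config = train_config()) {
  X <- maps_matrix(maps)
  if (is.logical(roi)) {
    stopifnot(length(roi) == ncol(X))
    roi <- which(roi)
  }
  if (!length(roi)) stop("ROI does not intersect the analysis mask")
  Xr <- X[, roi, drop = FALSE]
  cv <- cross_validate_signature(Xr, ratings, participants, scheme, config)
  fit <- svr_fit(Xr, as.numeric(ratings), config)
  w_full <- numeric(ncol(X))
  w_full[roi] <- fit$weights
  model <- structure(list(weights = w_full, intercept = fit$intercept,
                          mask = NULL, config = config,
                          manifest = list(n_maps = nrow(X),
                                          roi_size = length(roi))),
                     class = "signature_model")
  list(model = model, cv = cv, roi_size = length(roi))
}

#' Cross-validated performance of random voxel subsets
#'
#' Draws `n_reps` uniform random subsets (without replacement) of each
#' requested size from a source voxel set, retrains and cross-validates the
#' signature on each subset, and records the prediction-outcome r. Used to
#' ask how many randomly placed voxels are needed to approach whole-brain
#' performance.
#'
#' @param maps maps x voxels matrix or list of [activation_map]s.
#' @param ratings,participants per-map labels.
#' @param sizes integer vector of subset sizes (each >= 2).
#' @param source logical vector over the mask voxels to sample from
#'   (default: all voxels).
#' @param n_reps subsets per size.
#' @param scheme a [cv_scheme].
#' @param config a [train_config].
#' @param seed integer seed (fixes the exact subsets).
#' @return list with `curve` (data.frame: size, rep, r), `summary`
#'   (data.frame: size, mean_r, sd_r).
#' @export
voxel_sampling_curve <- function(maps, ratings, participants, sizes,
                                 source = NULL, n_reps = 5,
                                 scheme = cv_scheme(),
                                 config = train_config(), seed = 1L) {
  X <- maps_matrix(maps)
  pool <- if (is.null(source)) seq_len(ncol(X)) else which(source)
  sizes <- as.integer(sizes)
  if (any(sizes < 2)) stop("subset sizes must be >= 2")
  if (max(sizes) > length(pool))
    stop("largest size (", max(sizes), ") exceeds source voxels (",
         length(pool), ")")
  rng <- local_rng(seed, tag = 89L)
  rows <- list()
  for (s in sizes) {
    reps <- if (s == length(pool)) 1L else n_reps
    for (k in seq_len(reps)) {
      vox <- pool[rng$int(length(pool), size = s)]
      cv <- cross_validate_signature(X[, vox, drop = FALSE], ratings,
                                     participants, scheme, config)
      rows[[length(rows) + 1L]] <- data.frame(size = s, rep = k,
                                              r = cv$overall_r)
    }
  }
  curve <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(curve, curve$size), function(d)
    data.frame(size = d$size[1], mean_r = mean(d$r),
               sd_r = if (nrow(d) > 1) stats::sd(d$r) else 0)))
  rownames(summary) <- NULL
  list(curve = curve, summary = summary)
}
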