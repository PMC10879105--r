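#' SVR training configuration
#'
#' Fixed hyperparameters of the linear epsilon-insensitive support vector
#' regression used throughout: cost `C = 1` and `epsilon = 0.1` (no grid
#' search). Feature scaling is off by default so signature responses are
#' plain dot products on raw beta maps; when `"zscore"` is selected the
#' scaling is estimated on the training maps only and folded back into the
#' weights and intercept, so application always remains a dot product.
#'
#' @param cost_C SVR cost parameter (> 0).
#' @param epsilon insensitivity-tube half-width (>= 0).
#' @param feature_scaling `"none"` or `"zscore"`.
#' @param seed integer seed recorded in the model manifest (training itself
#'   is deterministic).
#' @export
train_config <- function(cost_C = 1, epsilon = 0.1,
                         feature_scaling = c("none", "zscore"), seed = 1L) {
  if (cost_C <= 0) stop("cost_C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(cost_C = cost_C, epsilon = epsilon,
                 feature_scaling = match.arg(feature_scaling),
                 kernel = "linear", seed = as.integer(seed)),
            class = "train_config")
}

# Core linear eps-SVR fit on a numeric matrix; returns weights + intercept.
svr_fit <- function(X, y, config) {
  if (length(unique(y)) < 2) stop("degenerate labels: ratings are constant")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (config$feature_scaling == "zscore") {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                  cost = config$cost_C, epsilon = config$epsilon,
                  scale = FALSE, tolerance = 1e-10, fitted = FALSE)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # fold z-scoring into (w, b): f(x) = sum w_j (x_j - c_j)/s_j + b
  w <- w / scl
  b <- b - sum(w * ctr)
  list(weights = w, intercept = b)
}

#' Train a population signature model
#'
#' Fits a linear epsilon-SVR predicting the rating label from the vectorized
#' activation maps, yielding a whole-brain (or ROI-restricted) weight map
#' plus intercept: the signature. Prediction for a new map is the dot
#' product of the weights with the map plus the intercept.
#'
#' @param maps list of [activation_map]s with rating metadata, or a
#'   maps x voxels matrix.
#' @param ratings rating labels; taken from the maps' metadata when omitted.
#' @param config a [train_config].
#' @param mask the [brain_mask] (taken from the maps when omitted).
#' @param participants optional participant ids recorded in the manifest.
#' @return object of class `signature_model` with fields `weights`,
#'   `intercept`, `mask`, `config`, `manifest`.
#' @export
train_signature <- function(maps, ratings = NULL, config = train_config(),
                            mask = NULL, participants = NULL) {
  if (!is.matrix(maps)) {
    if (is.null(ratings))
      ratings <- vapply(maps, function(m) as.numeric(m$meta$rating), 1)
    if (is.null(participants))
      participants <- vapply(maps, function(m)
        as.character(m$meta$participant), "")
    if (is.null(mask)) mask <- maps[[1]]$mask
    maps <- maps_matrix(maps, mask)
  }
  stopifnot(nrow(maps) == length(ratings))
  fit <- svr_fit(maps, as.numeric(ratings), config)
  structure(list(weights = fit$weights, intercept = fit$intercept,
                 mask = mask, config = config,
                 manifest = list(
                   n_maps = nrow(maps),
                   participants = unique(participants),
                   rating_range = range(ratings))),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("signature_model:", length(x$weights), "voxel weights; intercept",
      signif(x$intercept, 4), "; trained on", x$manifest$n_maps, "maps\n")
  invisible(x)
}

#' Apply a signature to activation maps
#'
#' The signature response (pattern expression) of each map: the dot product
#' of the model's weight map with the vectorized activation map, plus the
#' intercept. Responses are on the rating scale and affine in the map.
#'
#' @param model a `signature_model`.
#' @param maps list of [activation_map]s or a maps x voxels matrix.
#' @return numeric vector of signature responses.
#' @export
apply_signature <- function(model, maps) {
  if (!is.matrix(maps)) {
    for (m in maps)
      if (inherits(m, "activation_map") && !is.null(model$mask) &&
          !grids_match(m$mask$grid, model$mask$grid))
        stop("activation map grid does not match the model mask")
    maps <- maps_matrix(maps)
  }
  if (ncol(maps) != length(model$weights))
    stop("maps have ", ncol(maps), " voxels; model expects ",
         length(model$weights))
  as.numeric(maps %*% model$weights + model$intercept)
}

#' Participant-grouped cross-validation scheme
#'
#' Repeated k-fold cross-validation at the participant level: all of a
#' participant's maps fall in exactly one fold per repeat, so no model is
#' ever evaluated on a participant it saw during training. The default is
#' 10 x 10-fold.
#'
#' @param n_folds folds per repeat.
#' @param n_repeats independent repetitions with different splits.
#' @param seed integer seed controlling the splits.
#' @export
cv_scheme <- function(n_folds = 10, n_repeats = 10, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

# fold assignment for a set of group ids; returns list (per repeat) of
# integer fold label per group
make_folds <- function(groups, scheme) {
  ug <- unique(groups)
  if (length(ug) < scheme$n_folds)
    stop("need at least n_folds (", scheme$n_folds, ") groups, got ",
         length(ug))
  rng <- local_rng(scheme$seed, tag = 97L)
  lapply(seq_len(scheme$n_repeats), function(rep) {
    ord <- rng$perm(length(ug))
    fold_of_group <- integer(length(ug))
    fold_of_group[ord] <- rep_len(seq_len(scheme$n_folds), length(ug))
    stats::setNames(fold_of_group, ug)
  })
}

#' Cross-validated signature prediction
#'
#' Runs repeated participant-grouped k-fold cross-validation: within each
#' repeat, each fold's maps are predicted by a model trained on the remaining
#' participants only. Per-map predictions are averaged across repeats before
#' computing the overall prediction-outcome correlation and explained
#' variance score.
#'
#' @param maps maps x voxels matrix or list of [activation_map]s.
#' @param ratings per-map rating labels.
#' @param participants per-map participant ids (grouping variable).
#' @param scheme a [cv_scheme].
#' @param config a [train_config].
#' @param keep_fold_models keep the per-fold models of the first repeat.
#' @return a `prediction_result` (see [evaluate_predictions()]) with extra
#'   fields `per_repeat_r` and optionally `fold_models`.
#' @export
cross_validate_signature <- function(maps, ratings, participants,
                                     scheme = cv_scheme(),
                                     config = train_config(),
                                     keep_fold_models = FALSE) {
  X <- maps_matrix(maps)
  ratings <- as.numeric(ratings)
  stopifnot(nrow(X) == length(ratings),
            length(participants) == length(ratings))
  folds <- make_folds(participants, scheme)
  pred <- matrix(NA_real_, nrow(X), scheme$n_repeats)
  fold_models <- if (keep_fold_models) vector("list", scheme$n_folds)
  for (rep_i in seq_len(scheme$n_repeats)) {
    fog <- folds[[rep_i]]
    for (f in seq_len(scheme$n_folds)) {
      test <- fog[as.character(participants)] == f
      if (!any(test)) next
      if (any(participants[test] %in% participants[!test]))
        stop("internal error: participant leakage across folds")
      fit <- svr_fit(X[!test, , drop = FALSE], ratings[!test], config)
      pred[test, rep_i] <- X[test, , drop = FALSE] %*% fit$weights +
        fit$intercept
      if (keep_fold_models && rep_i == 1L)
        fold_models[[f]] <- fit
    }
  }
  predicted <- rowMeans(pred)
  res <- evaluate_predictions(predicted, ratings, participants)
  res$per_repeat_r <- apply(pred, 2, stats::cor, y = ratings)
  if (keep_fold_models) res$fold_models <- fold_models
  res
}

#' Evaluate predicted against actual ratings
#'
#' Computes the overall prediction-outcome Pearson correlation, the
#' explained variance score
#' `EVS = 1 - mean((actual - predicted)^2) / mean((actual - mean(actual))^2)`
#' (1 for perfect prediction, 0 for the constant-mean predictor, negative
#' for anything worse), and within-participant
#' correlations summarized by r-to-z (Fisher) averaging with a bootstrap
#' standard error over participants.
#'
#' @param predicted,actual numeric vectors (length >= 3).
#' @param grouping optional per-observation participant ids.
#' @param n_boot bootstrap resamples for the within-mean SE.
#' @param seed seed for the bootstrap.
#' @return object of class `prediction_result`.
#' @export
evaluate_predictions <- function(predicted, actual, grouping = NULL,
                                 n_boot = 1000, seed = 1L) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 3)
  if (stats::sd(actual) == 0)
    stop("actual ratings have zero variance: correlation undefined")
  flat_predicted <- stats::sd(predicted) == 0
  overall_r <- if (flat_predicted) NA_real_ else
    stats::cor(predicted, actual)
  overall_p <- if (flat_predicted) NA_real_ else
    stats::cor.test(predicted, actual)$p.value
  evs <- 1 - mean((actual - predicted)^2) /
    mean((actual - mean(actual))^2)
  within <- NULL; within_mean <- NA_real_; within_se <- NA_real_
  if (!is.null(grouping)) {
    ug <- unique(grouping)
    r <- vapply(ug, function(g) {
      sel <- grouping == g
      if (sum(sel) < 3 || stats::sd(actual[sel]) == 0 ||
          stats::sd(predicted[sel]) == 0) return(NA_real_)
      stats::cor(predicted[sel], actual[sel])
    }, 1)
    within <- stats::setNames(r, as.character(ug))
    ok <- !is.na(within)
    if (any(ok)) {
      z <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, within[ok])))
      within_mean <- tanh(mean(z))
      rng <- local_rng(seed, tag = 131L)
      bm <- vapply(seq_len(n_boot), function(b) {
        tanh(mean(z[sample_with_replacement(z, rng)]))
      }, 1)
      within_se <- stats::sd(bm)
    }
  }
  structure(list(predicted = predicted, actual = actual,
                 grouping = grouping,
                 overall_r = overall_r, overall_p = overall_p, evs = evs,
                 flat_predicted = flat_predicted,
                 within_participant_r = within,
                 within_mean_r = within_mean, within_se = within_se),
            class = "prediction_result")
}

sample_with_replacement <- function(x, rng) {
  ceiling(rng$unif(length(x)) * length(x))
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result: r =", signif(x$overall_r, 3),
      "| EVS =", signif(x$evs, 3),
      if (!is.na(x$within_mean_r))
        paste("| within-participant mean r =", signif(x$within_mean_r, 3)),
      "\n")
  invisible(x)
}

#' Train within-individual signature models
#'
#' Fits a separate linear SVR (same fixed C and epsilon) to each
#' participant's single-trial no-shock maps, with trial-stratified k-fold
#' cross-validation for a per-participant prediction-outcome r, and returns
#' the per-participant full-data weight maps for downstream group tests
#' (core-system analysis). Participants with too few eligible trials or
#' constant ratings are skipped with a logged reason.
#'
#' @param beta_series_list list of `beta_series`, one per participant.
#' @param scheme a [cv_scheme] (folds stratify trials; no grouping needed).
#' @param config a [train_config].
#' @param min_trials minimum eligible trials per participant.
#' @return list with `weights` (participants x voxels matrix), `cv_r`
#'   (per-participant cross-validated r), `participants`, `skipped`
#'   (data.frame of skipped participants and reasons).
#' @export
train_within_individual <- function(beta_series_list, scheme = cv_scheme(),
                                    config = train_config(),
                                    min_trials = 10) {
  W <- NULL; cv_r <- numeric(0); ids <- character(0)
  skipped <- data.frame(participant = character(0), reason = character(0))
  rng <- local_rng(scheme$seed, tag = 59L)
  for (bs in beta_series_list) {
    id <- as.character(bs$trials$participant[1])
    keep <- !bs$trials$shock_followed & !is.na(bs$trials$rating)
    X <- bs$X[keep, , drop = FALSE]
    y <- as.numeric(bs$trials$rating[keep])
    if (nrow(X) < min_trials) {
      skipped <- rbind(skipped, data.frame(participant = id,
                                           reason = "too few trials"))
      next
    }
    if (length(unique(y)) < 2) {
      skipped <- rbind(skipped, data.frame(participant = id,
                                           reason = "constant ratings"))
      next
    }
    pred <- matrix(NA_real_, nrow(X), scheme$n_repeats)
    for (rep_i in seq_len(scheme$n_repeats)) {
      fold <- integer(nrow(X))
      fold[rng$perm(nrow(X))] <- rep_len(seq_len(scheme$n_folds), nrow(X))
      for (f in seq_len(scheme$n_folds)) {
        test <- fold == f
        if (!any(test) || length(unique(y[!test])) < 2) next
        fit <- svr_fit(X[!test, , drop = FALSE], y[!test], config)
        pred[test, rep_i] <- X[test, , drop = FALSE] %*% fit$weights +
          fit$intercept
      }
    }
    full <- svr_fit(X, y, config)
    W <- rbind(W, full$weights)
    p_bar <- rowMeans(pred, na.rm = TRUE)
    cv_r <- c(cv_r, if (stats::sd(p_bar) > 0) stats::cor(p_bar, y)
              else NA_real_)
    ids <- c(ids, id)
  }
  list(weights = W, cv_r = cv_r, participants = ids, skipped = skipped)
}

#' Serialize a signature model
#'
#' Writes the weight map as NIfTI plus a JSON sidecar carrying the
#' intercept, training configuration, manifest and a content hash of the
#' weight file.
#'
#' @param model a `signature_model` (must carry its mask).
#' @param path_nii output NIfTI path for the weights.
#' @param path_json sidecar path (defaults to `path_nii` with `.json`).
#' @export
write_signature <- function(model, path_nii, path_json = NULL) {
  stopifnot(inherits(model, "signature_model"), !is.null(model$mask))
  if (is.null(path_json))
    path_json <- sub("\\.nii(\\.gz)?$", ".json", path_nii)
  write_volume(unvectorize(model$weights, model$mask), model$mask$grid,
               path_nii)
  meta <- list(intercept = model$intercept,
               config = unclass(model$config),
               manifest = model$manifest,
               weights_md5 = unname(tools::md5sum(path_nii)))
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(path_nii, path_json))
}

#' Read a serialized signature model
#'
#' @param path_nii weight NIfTI written by [write_signature()].
#' @param mask the [brain_mask] to vectorize the weights over.
#' @param path_json sidecar path (defaults next to `path_nii`).
#' @export
read_signature <- function(path_nii, mask, path_json = NULL) {
  if (is.null(path_json))
    path_json <- sub("\\.nii(\\.gz)?$", ".json", path_nii)
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  w <- vectorize(read_volume(path_nii), mask)
  cfg <- train_config(cost_C = meta$config$cost_C,
                      epsilon = meta$config$epsilon,
                      feature_scaling = meta$config$feature_scaling,
                      seed = meta$config$seed)
  structure(list(weights = w, intercept = meta$intercept, mask = mask,
                 config = cfg, manifest = meta$manifest),
            class = "signature_model")
}
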