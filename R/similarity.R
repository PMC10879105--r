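#' Apply a signature to a foreign dataset
#'
#' Cross-prediction: computes signature responses on another cohort's maps
#' (same mask/voxel order), evaluates the prediction-outcome correlation and
#' within-participant correlations, and runs the high-vs-low forced-choice
#' test when both rating extremes are available. Feeds
#' [permutation_test_delta_r()] for specificity claims.
#'
#' @param model a `signature_model`.
#' @param maps maps x voxels matrix or list of [activation_map]s.
#' @param ratings,participants per-map labels.
#' @param high,low rating levels of the forced-choice sides.
#' @return list with `responses`, `prediction` (a `prediction_result`) and
#'   `forced_choice` (`NULL` when no eligible pairs).
#' @export
cross_predict <- function(model, maps, ratings, participants,
                          high = c(4, 5), low = c(1, 2)) {
  X <- maps_matrix(maps)
  responses <- apply_signature(model, X)
  prediction <- evaluate_predictions(responses, as.numeric(ratings),
                                     participants)
  pairs <- high_low_pairs(X, ratings, participants, high, low)
  fc <- if (!is.null(pairs$high_maps) && nrow(pairs$high_maps) > 0)
    forced_choice(model, pairs$high_maps, pairs$low_maps) else NULL
  list(responses = responses, prediction = prediction, forced_choice = fc)
}

#' Spatial correlation between two weight maps
#'
#' Pearson correlation of two voxel weight maps over the analysis mask,
#' optionally restricted to bootstrap-surviving voxels: with a threshold,
#' each map keeps only its voxels significant at the given uncorrected
#' bootstrap p (others set to 0) and the correlation is computed over the
#' union of surviving voxels. The permutation p-value spatially shuffles the
#' first map's values (unstructured shuffle; smoothness-preserving nulls are
#' out of scope).
#'
#' @param w1,w2 weight vectors over the same mask.
#' @param threshold_p `NA` (unthresholded), `0.01` or `0.001`.
#' @param boot1,boot2 `bootstrap_weight_map`s of `w1` and `w2` (required
#'   when thresholding).
#' @param n_perm,seed permutation settings.
#' @return list with `r`, `p` (two-sided permutation), `n_voxels` (voxels
#'   entering the correlation), `unstable` (fewer than 10 voxels).
#' @export
spatial_correlation <- function(w1, w2, threshold_p = NA,
                                boot1 = NULL, boot2 = NULL,
                                n_perm = 1000, seed = 1L) {
  stopifnot(length(w1) == length(w2))
  if (!is.na(threshold_p)) {
    if (is.null(boot1) || is.null(boot2))
      stop("thresholded spatial correlation needs both bootstrap maps")
    s1 <- boot1$p < threshold_p
    s2 <- boot2$p < threshold_p
    keep <- s1 | s2
    w1 <- ifelse(s1, w1, 0)[keep]
    w2 <- ifelse(s2, w2, 0)[keep]
  }
  unstable <- length(w1) < 10
  if (length(w1) < 3 || stats::sd(w1) == 0 || stats::sd(w2) == 0)
    return(list(r = NA_real_, p = NA_real_, n_voxels = length(w1),
                unstable = TRUE))
  r <- stats::cor(w1, w2)
  rng <- local_rng(seed, tag = 83L)
  null_values <- vapply(seq_len(n_perm), function(i)
    stats::cor(w1[rng$perm(length(w1))], w2), 1)
  list(r = r, p = perm_p(r, null_values, "two"),
       n_voxels = length(w1), unstable = unstable)
}

#' ROI cosine-similarity profiles of thresholded weight maps
#'
#' For each model and each ROI: the cosine between the model's thresholded
#' positive weight vector and the ROI indicator vector, both restricted to
#' the analysis mask. Ribbon values normalize the cosines by the maximum
#' across the whole report. Per-ROI contribution fractions assign each
#' in-ROI voxel to the model with the largest absolute thresholded weight
#' there (ties split equally); fractions sum to 1 per ROI.
#'
#' @param models named list of weight vectors (or `signature_model`s).
#' @param rois named list of logical vectors over the mask voxels.
#' @param threshold `function(w)` returning the thresholded weights;
#'   default keeps positive weights and zeroes the rest.
#' @return object of class `similarity_report` with `cosine` (models x
#'   ROIs), `ribbon` (same, max-normalized), `contribution` (models x
#'   ROIs, columns summing to 1), `dropped` (models with empty thresholded
#'   maps).
#' @export
roi_cosine_profile <- function(models, rois,
                               threshold = function(w) pmax(w, 0)) {
  W <- lapply(models, function(m)
    if (inherits(m, "signature_model")) m$weights else as.numeric(m))
  Wt <- lapply(W, threshold)
  nonempty <- vapply(Wt, function(w) any(w != 0), TRUE)
  dropped <- names(Wt)[!nonempty]
  if (length(dropped))
    message("dropping model(s) with empty thresholded map: ",
            paste(dropped, collapse = ", "))
  Wt <- Wt[nonempty]
  if (!length(Wt)) stop("no model survives thresholding")
  for (r in rois) if (!any(r)) stop("empty ROI within the analysis mask")
  cosine <- t(vapply(Wt, function(w)
    vapply(rois, function(r)
      sum(w * r) / (sqrt(sum(w^2)) * sqrt(sum(r^2))), 1),
    numeric(length(rois))))
  dimnames(cosine) <- list(names(Wt), names(rois))
  contribution <- matrix(0, length(Wt), length(rois),
                         dimnames = dimnames(cosine))
  absW <- do.call(rbind, lapply(Wt, function(w) abs(w)))
  for (j in seq_along(rois)) {
    vox <- which(rois[[j]])
    for (v in vox) {
      a <- absW[, v]
      winners <- which(a == max(a))
      contribution[winners, j] <- contribution[winners, j] + 1 / length(winners)
    }
    contribution[, j] <- contribution[, j] / length(vox)
  }
  structure(list(cosine = cosine, ribbon = cosine / max(cosine),
                 contribution = contribution, dropped = dropped),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("similarity_report:", nrow(x$cosine), "models x", ncol(x$cosine),
      "ROIs\ncosine similarities:\n")
  print(round(x$cosine, 3))
  invisible(x)
}
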