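#' Haufe structure-coefficient (encoding) map
#'
#' Transforms a backward-model weight vector into the forward (encoding)
#' pattern it tracks: `A = cov(X) W cov(W'X)^-1`, which for a
#' one-dimensional latent reduces voxelwise to
#' `A_v = cov(x_v, y_hat) / Var(y_hat)` with `y_hat = X W`. Columns of `X`
#' are mean-centred over trials and covariances use the unbiased `n - 1`
#' estimator. Because the overall scale of a backward model is arbitrary,
#' `W` is normalized to unit Euclidean length before the latent is formed;
#' `A` is therefore invariant to rescaling `W` by any positive constant.
#'
#' @param X trials x voxels matrix (>= 2 trials).
#' @param W weight vector (length = voxels), e.g. a signature's weights.
#' @param participant optional id recorded in the result.
#' @return object of class `encoding_map` with fields `A`, `participant`,
#'   `n_trials`.
#' @export
structure_coefficients <- function(X, W, participant = NA) {
  X <- as.matrix(X)
  W <- as.numeric(W)
  stopifnot(ncol(X) == length(W))
  if (nrow(X) < 2) stop("need at least 2 trials")
  nw <- sqrt(sum(W^2))
  if (nw == 0) stop("zero latent variance: W is all zero")
  W <- W / nw
  yhat <- as.numeric(X %*% W)
  v <- stats::var(yhat)
  if (v <= 0) stop("zero latent variance: W'X is constant")
  Xc <- sweep(X, 2, colMeans(X))
  A <- as.numeric(crossprod(Xc, yhat - mean(yhat))) / (nrow(X) - 1) / v
  structure(list(A = A, participant = participant, n_trials = nrow(X)),
            class = "encoding_map")
}

#' Encoding maps for every participant
#'
#' Applies [structure_coefficients()] to each participant's no-shock
#' single-trial maps with that participant's own decoder weights.
#'
#' @param beta_series_list list of `beta_series`.
#' @param weights participants x voxels matrix of within-individual decoder
#'   weights (rows aligned with `beta_series_list` entries that were fit).
#' @param participants ids aligned with the weight rows.
#' @return participants x voxels matrix of structure coefficients.
#' @export
encoding_maps <- function(beta_series_list, weights, participants) {
  ids <- vapply(beta_series_list,
                function(bs) as.character(bs$trials$participant[1]), "")
  A <- matrix(NA_real_, length(participants), ncol(weights))
  for (i in seq_along(participants)) {
    bs <- beta_series_list[[match(participants[i], ids)]]
    keep <- !bs$trials$shock_followed & !is.na(bs$trials$rating)
    A[i, ] <- structure_coefficients(bs$X[keep, , drop = FALSE],
                                     weights[i, ],
                                     participant = participants[i])$A
  }
  rownames(A) <- participants
  A
}

#' Core-system conjunction of decoding and encoding maps
#'
#' A voxel belongs to the core system iff the one-sample group t-test across
#' within-individual decoder weight maps passes BH-FDR at `q` AND the same
#' test across their Haufe encoding maps passes at `q` AND both group means
#' are positive (one-sided, preserving positive values). A signed variant
#' keeps significant voxels of either sign, labelled by the weight-map mean.
#'
#' @param weight_maps participants x voxels matrix of decoder weights.
#' @param encoding_maps participants x voxels matrix of structure
#'   coefficients (same participants and voxel order).
#' @param q FDR level.
#' @param signed if `TRUE`, two-sided tests keeping both signs.
#' @return list with `core` (logical per voxel), `sign` (+1/-1/0),
#'   `t_weights`, `t_encodings` (the two test objects), `q`.
#' @export
core_system <- function(weight_maps, encoding_maps, q = 0.05,
                        signed = FALSE) {
  stopifnot(identical(dim(weight_maps), dim(encoding_maps)))
  if (nrow(weight_maps) < 3) stop("need at least 3 participants")
  side <- if (signed) "two" else "one"
  tw <- group_ttest_map(weight_maps, sidedness = side)
  te <- group_ttest_map(encoding_maps, sidedness = side)
  mw <- fdr_bh(tw$p, q)$mask
  me <- fdr_bh(te$p, q)$mask
  if (signed) {
    core <- mw & me & (sign(tw$mean) == sign(te$mean)) & tw$mean != 0
    sgn <- ifelse(core, sign(tw$mean), 0)
  } else {
    core <- mw & me & tw$mean > 0 & te$mean > 0
    sgn <- ifelse(core, 1, 0)
  }
  list(core = core, sign = sgn, t_weights = tw, t_encodings = te, q = q)
}
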