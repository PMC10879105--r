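#' Permutation test of a prediction-outcome correlation
#'
#' Tests whether the observed correlation between signature responses and
#' ratings exceeds chance by shuffling the ratings `n_perm` times (5000 in
#' the reference analysis) and recomputing the correlation each time. The
#' one-sided p-value uses the add-one convention
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, so it can never be
#' exactly zero. Supply `refit_fun` to re-run a whole (cross-validated)
#' pipeline on each shuffled label vector instead of correlating fixed
#' responses.
#'
#' @param responses signature responses (ignored when `refit_fun` is given,
#'   beyond defining the statistic's inputs).
#' @param ratings actual ratings.
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @param sidedness `"one"` (greater) or `"two"`.
#' @param refit_fun optional `function(shuffled_ratings)` returning the test
#'   statistic under that relabelling; the observed statistic is
#'   `refit_fun(ratings)`.
#' @return object of class `permutation_result` with fields `observed`,
#'   `null_values`, `n_perm`, `p`, `sidedness`, `seed`.
#' @export
permutation_test_r <- function(responses, ratings, n_perm = 5000, seed = 1L,
                               sidedness = c("one", "two"),
                               refit_fun = NULL) {
  sidedness <- match.arg(sidedness)
  if (n_perm == 0) stop("n_perm must be positive")
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse")
  stat <- if (is.null(refit_fun))
    function(y) stats::cor(responses, y) else refit_fun
  observed <- stat(ratings)
  rng <- local_rng(seed, tag = 41L)
  null_values <- vapply(seq_len(n_perm), function(i)
    stat(ratings[rng$perm(length(ratings))]), 1)
  p <- perm_p(observed, null_values, sidedness)
  structure(list(observed = observed, null_values = null_values,
                 n_perm = n_perm, p = p, sidedness = sidedness,
                 seed = seed),
            class = "permutation_result")
}

perm_p <- function(observed, null_values, sidedness) {
  if (sidedness == "one")
    (1 + sum(null_values >= observed)) / (1 + length(null_values))
  else
    (1 + sum(abs(null_values) >= abs(observed))) /
      (1 + length(null_values))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result: observed =", signif(x$observed, 4),
      "| p =", signif(x$p, 4), sprintf("(%s-sided, %d shuffles)\n",
                                       x$sidedness, x$n_perm))
  invisible(x)
}

#' Permutation test of a correlation difference
#'
#' Tests whether one set of signature responses predicts its target better
#' than a comparison target (or a comparison response set predicts matched
#' data): `delta_r = r(responses, target_a) - r(responses_b, target_b)`.
#' The null jointly permutes the row order of the responses — the SAME
#' permutation for both correlations when the two sets are matched in
#' length — breaking the response-target coupling while preserving all
#' marginals, and recomputes `delta_r` each time. With two sets of unequal
#' size (e.g. cross-application to a different cohort) each set is permuted
#' independently. One-sided p with the add-one convention. This null
#' construction is a documented interpretation: the original analysis names
#' the test but not the scheme. With identical targets the null is
#' degenerate at zero and p = 1.
#'
#' @param responses signature responses paired with `target_a`.
#' @param target_a first prediction target.
#' @param target_b second prediction target.
#' @param responses_b responses paired with `target_b` (defaults to
#'   `responses`: one response set, two targets).
#' @param n_perm,seed as in [permutation_test_r()].
#' @return a `permutation_result` whose `observed` is the r difference.
#' @export
permutation_test_delta_r <- function(responses, target_a, target_b,
                                     responses_b = responses,
                                     n_perm = 5000, seed = 1L) {
  if (length(responses) != length(target_a) ||
      length(responses_b) != length(target_b))
    stop("responses and targets must have matched lengths")
  observed <- stats::cor(responses, target_a) -
    stats::cor(responses_b, target_b)
  rng <- local_rng(seed, tag = 43L)
  joint <- length(responses) == length(responses_b)
  null_values <- vapply(seq_len(n_perm), function(i) {
    ord <- rng$perm(length(responses))
    ord_b <- if (joint) ord else rng$perm(length(responses_b))
    stats::cor(responses[ord], target_a) -
      stats::cor(responses_b[ord_b], target_b)
  }, 1)
  structure(list(observed = observed, null_values = null_values,
                 n_perm = n_perm,
                 p = perm_p(observed, null_values, "one"),
                 sidedness = "one", seed = seed),
            class = "permutation_result")
}

#' Bootstrap a signature weight map over participants
#'
#' Resamples participants with replacement (keeping all of a sampled
#' participant's maps, duplicates included), retrains the signature on each
#' replicate, and summarizes the per-voxel weight distribution:
#' `z = mean/sd` with a two-sided normal p-value, plus threshold masks at
#' uncorrected p < 0.001 and p < 0.01. Replicates that end up with fewer
#' than two distinct rating values are redrawn (counted), keeping the
#' replicate count at `n_boot`. The reference analysis uses 5000 iterations.
#'
#' @param maps maps x voxels matrix or list of [activation_map]s.
#' @param ratings per-map ratings.
#' @param participants per-map participant ids.
#' @param config a [train_config].
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return object of class `bootstrap_weight_map` with per-voxel `mean_w`,
#'   `sd_w`, `z`, `p`, threshold masks `sig_p001`, `sig_p01`, and counters.
#' @export
bootstrap_weight_map <- function(maps, ratings, participants,
                                 config = train_config(),
                                 n_boot = 5000, seed = 1L) {
  X <- maps_matrix(maps)
  ratings <- as.numeric(ratings)
  ug <- unique(participants)
  if (length(ug) < 10)
    warning("fewer than 10 participants: bootstrap weight maps unstable")
  if (n_boot < 10)
    warning("n_boot too small for a stable per-voxel sd")
  rng <- local_rng(seed, tag = 71L)
  sum_w <- numeric(ncol(X)); sum_w2 <- numeric(ncol(X))
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      take <- ug[sample_with_replacement(ug, rng)]
      rows <- unlist(lapply(take, function(g) which(participants == g)))
      if (length(unique(ratings[rows])) >= 2) break
      redrawn <- redrawn + 1L
    }
    fit <- svr_fit(X[rows, , drop = FALSE], ratings[rows], config)
    sum_w <- sum_w + fit$weights
    sum_w2 <- sum_w2 + fit$weights^2
  }
  mean_w <- sum_w / n_boot
  sd_w <- sqrt(pmax(0, sum_w2 / n_boot - mean_w^2) * n_boot / (n_boot - 1))
  z <- ifelse(sd_w > 0, mean_w / sd_w, 0)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(mean_w = mean_w, sd_w = sd_w, z = z, p = p,
                 sig_p001 = p < 0.001, sig_p01 = p < 0.01,
                 n_boot = n_boot, redrawn = redrawn, seed = seed),
            class = "bootstrap_weight_map")
}

#' Bootstrap test that a mean is positive
#'
#' Resamples the values with replacement and reports the fraction of
#' bootstrap means at or below zero (one-sided), floored at
#' `1/(n_boot + 1)`. Used for testing whether within-participant
#' prediction-outcome correlations are greater than zero (5000 iterations in
#' the reference analysis).
#'
#' @param values numeric vector (length >= 5).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return one-sided p-value.
#' @export
bootstrap_mean_positive <- function(values, n_boot = 5000, seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("need at least 5 values")
  rng <- local_rng(seed, tag = 73L)
  means <- vapply(seq_len(n_boot), function(b)
    mean(values[sample_with_replacement(values, rng)]), 1)
  max(mean(means <= 0), 1 / (n_boot + 1))
}

#' Average maps at high vs low rating levels per participant
#'
#' Builds the paired maps of the two-alternative forced-choice test: per
#' participant, the average of maps at ratings in `high` (4-5) and in `low`
#' (1-2). Participants lacking either side are excluded and counted.
#'
#' @param maps maps x voxels matrix or list of [activation_map]s.
#' @param ratings,participants per-map labels.
#' @param high,low rating levels defining the two sides.
#' @return list with matrices `high_maps`, `low_maps` (participants x
#'   voxels), `participants`, `n_excluded`.
#' @export
high_low_pairs <- function(maps, ratings, participants,
                           high = c(4, 5), low = c(1, 2)) {
  X <- maps_matrix(maps)
  ug <- unique(participants)
  H <- NULL; L <- NULL; keep_ids <- character(0); excl <- 0L
  for (g in ug) {
    hi <- participants == g & ratings %in% high
    lo <- participants == g & ratings %in% low
    if (!any(hi) || !any(lo)) { excl <- excl + 1L; next }
    H <- rbind(H, colMeans(X[hi, , drop = FALSE]))
    L <- rbind(L, colMeans(X[lo, , drop = FALSE]))
    keep_ids <- c(keep_ids, as.character(g))
  }
  list(high_maps = H, low_maps = L, participants = keep_ids,
       n_excluded = excl)
}

#' Two-alternative forced-choice classification
#'
#' For each participant pair of a high-rating and a low-rating average map,
#' the choice is correct iff the signature response of the high map exceeds
#' that of the low map; ties count 0.5. Reports accuracy, its standard
#' error, Cohen's d of the paired response differences, a two-sided exact
#' binomial p-value against chance (ties excluded from the binomial count),
#' and ROC points swept over response thresholds.
#'
#' @param model a `signature_model`.
#' @param high_maps,low_maps participants x voxels matrices, row-aligned.
#' @return object of class `forced_choice_result`.
#' @export
forced_choice <- function(model, high_maps, low_maps) {
  if (is.null(high_maps) || is.null(low_maps) || nrow(high_maps) == 0)
    stop("no eligible participant pairs")
  stopifnot(nrow(high_maps) == nrow(low_maps))
  rh <- apply_signature(model, high_maps)
  rl <- apply_signature(model, low_maps)
  d_resp <- rh - rl
  correct <- ifelse(d_resp > 0, 1, ifelse(d_resp < 0, 0, 0.5))
  accuracy <- mean(correct)
  se <- stats::sd(correct) / sqrt(length(correct))
  cohens_d <- mean(d_resp) / stats::sd(d_resp)
  nontied <- d_resp != 0
  binomial_p <- if (any(nontied))
    stats::binom.test(sum(d_resp > 0), sum(nontied), 0.5,
                      alternative = "two.sided")$p.value else 1
  thr <- sort(unique(c(rh, rl, -Inf, Inf)), decreasing = TRUE)
  roc_points <- data.frame(
    fpr = vapply(thr, function(th) mean(rl > th), 1),
    tpr = vapply(thr, function(th) mean(rh > th), 1))
  structure(list(accuracy = accuracy, se = se, cohens_d = cohens_d,
                 binomial_p = binomial_p, roc_points = roc_points,
                 n_pairs = length(d_resp),
                 response_diff = d_resp),
            class = "forced_choice_result")
}

#' @export
print.forced_choice_result <- function(x, ...) {
  cat(sprintf(
    "forced_choice_result: accuracy = %.3f (n = %d), d = %.2f, p = %.3g\n",
    x$accuracy, x$n_pairs, x$cohens_d, x$binomial_p))
  invisible(x)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up false-discovery-rate control at level `q`: returns the
#' significance mask and the largest raw p-value passing.
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `mask` (logical), `threshold` (largest passing raw p,
#'   or `NA` when nothing passes), `q`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values))
    return(list(mask = logical(0), threshold = NA_real_, q = q))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  mask <- stats::p.adjust(p_values, method = "BH") <= q
  mask[is.na(mask)] <- FALSE
  list(mask = mask,
       threshold = if (any(mask)) max(p_values[mask]) else NA_real_,
       q = q)
}

#' Voxelwise one-sample t-test across participants
#'
#' Tests each voxel's mean across participant-level maps against zero.
#' Voxels with zero across-participant variance are flagged and given the
#' limiting p-value (0 or 1 by the sign of the mean for one-sided tests, 1
#' for an exactly zero mean).
#'
#' @param maps participants x voxels matrix (>= 3 rows).
#' @param sidedness `"one"` (positive direction) or `"two"`.
#' @return list with `t`, `p`, `mean`, `df`, `degenerate` (logical per
#'   voxel).
#' @export
group_ttest_map <- function(maps, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3) stop("need at least 3 participant maps")
  m <- colMeans(maps)
  s <- apply(maps, 2, stats::sd)
  degenerate <- s == 0
  t_stat <- ifelse(degenerate, ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)),
                   m / (s / sqrt(n)))
  p <- if (sidedness == "one") stats::pt(t_stat, df = n - 1,
                                         lower.tail = FALSE)
       else 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  p[degenerate & m == 0] <- 1
  list(t = t_stat, p = p, mean = m, df = n - 1, degenerate = degenerate)
}
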