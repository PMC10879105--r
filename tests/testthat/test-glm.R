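test_that("canonical double-gamma HRF has the expected shape", {
  h <- canonical_hrf(hrf_spec(), dt_s = 0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(max(h), 1)                      # peak-normalized
  expect_equal(t[which.max(h)], 5.0)           # argmax of the two-gamma difference
  expect_lt(min(h), 0)                         # undershoot present

  # ratio -> Inf: kernel collapses to the single normalized gamma density
  h_inf <- canonical_hrf(hrf_spec(peak_undershoot_ratio = 1e12), dt_s = 0.1)
  g <- dgamma(t, shape = 6, scale = 1)
  expect_equal(h_inf, g / max(g), tolerance = 1e-9)

  expect_error(canonical_hrf(hrf_spec(), dt_s = 0.7), "divide")
  expect_error(hrf_spec(peak_delay_s = -1), "positive")
})

test_that("24-parameter motion expansion follows the standard recipe", {
  set.seed(1)
  m6 <- matrix(rnorm(60), 10, 6)
  m24 <- motion_expand(m6)
  expect_equal(ncol(m24), 24L)
  expect_equal(m24[, 1:6], scale(m6, scale = FALSE), ignore_attr = TRUE)
  expect_equal(m24[, 7:12], rbind(0, diff(scale(m6, scale = FALSE))),
               ignore_attr = TRUE)
  expect_equal(m24[, 13:18], m24[, 1:6]^2, ignore_attr = TRUE)
  expect_equal(m24[, 19:24], m24[, 7:12]^2, ignore_attr = TRUE)
})

make_run_events <- function(ratings, shock = FALSE, run = 1L) {
  n <- length(ratings)
  data.frame(onset = 6 + (0:(n - 1)) * 20, duration = 8,
             condition = "low", rating = ratings,
             shock_followed = rep_len(shock, n), run = run,
             trial_type = "anticipation")
}

test_that("per-rating designs have one column per observed level", {
  ev <- make_run_events(c(1L, 2L, 2L, 1L))
  ft <- seq(0, 98, by = 2)
  des <- build_design(ev, ft, rep(1L, length(ft)), tr_s = 2,
                      mode = "per-rating",
                      nuisance = nuisance_spec(highpass_cutoff_s = NA))
  expect_equal(des$task_columns, c("rating_1", "rating_2"))
  expect_true("run1_intercept" %in% colnames(des$X))

  # shock-followed anticipation becomes a separate no-interest column
  ev2 <- make_run_events(c(1L, 2L, 3L), shock = c(FALSE, FALSE, TRUE))
  des2 <- build_design(ev2, ft, rep(1L, length(ft)), tr_s = 2,
                       mode = "per-rating",
                       nuisance = nuisance_spec(highpass_cutoff_s = NA))
  expect_setequal(des2$task_columns,
                  c("rating_1", "rating_2", "anticipation_shock"))

  # spike frame -> one-hot indicator column
  des3 <- build_design(ev, ft, rep(1L, length(ft)), tr_s = 2,
                       mode = "per-rating",
                       nuisance = nuisance_spec(extra_spikes = 7L,
                                                highpass_cutoff_s = NA))
  expect_equal(sum(des3$X[, "spike_7"]), 1)
  expect_equal(which(des3$X[, "spike_7"] == 1), 7L)

  # per-trial mode: one column per anticipation trial
  des4 <- build_design(ev, ft, rep(1L, length(ft)), tr_s = 2,
                       mode = "per-trial",
                       nuisance = nuisance_spec(highpass_cutoff_s = NA))
  expect_length(des4$task_columns, 4L)
})

test_that("OLS betas match brute-force normal equations", {
  set.seed(7)
  ev <- make_run_events(c(1L, 3L))
  ft <- seq(0, 58, by = 2)
  des <- build_design(ev, ft, rep(1L, length(ft)), tr_s = 2,
                      mode = "per-trial",
                      nuisance = nuisance_spec(highpass_cutoff_s = NA))
  Y <- matrix(rnorm(length(ft) * 5), length(ft), 5)
  fit <- fit_glm(Y, des)
  # independent oracle: solve(X'X) X'y per voxel
  Xd <- des$X
  B <- solve(t(Xd) %*% Xd, t(Xd) %*% Y)
  expect_equal(fit$betas, B[des$task_columns, , drop = FALSE],
               tolerance = 1e-10)

  # adding a constant offset changes only the intercept betas
  fit2 <- fit_glm(Y + 10, des)
  expect_equal(fit2$betas, fit$betas, tolerance = 1e-8)

  # duplicated column -> rank error naming the column
  des_dup <- des
  des_dup$X <- cbind(des_dup$X, dup = des_dup$X[, 1])
  expect_error(fit_glm(Y, des_dup), "collinear")
})

test_that("noiseless simulated BOLD recovers generating amplitudes", {
  mask <- brain_mask(array(1, c(3, 3, 3)), volume_grid(c(3, 3, 3)))
  pat <- rnorm(27)
  amps <- c(1.5, -2, 0.5, 3)
  trials <- data.frame(participant = 1, run = rep(1:2, each = 2),
                       trial = 1:4, condition = "low",
                       rating = 2L, shock_followed = FALSE,
                       onset = c(6, 40, 6, 40), duration = c(8, 6, 7, 9))
  bs <- structure(list(X = tcrossprod(amps, pat), trials = trials,
                       mask = mask), class = "beta_series")
  bold <- simulate_bold(bs, tr_s = 2, noise_sd = 0, seed = 1)
  ev <- trials
  ev$trial_type <- "anticipation"
  des <- build_design(ev, bold$frame_times, bold$run_labels, tr_s = 2,
                      mode = "per-trial",
                      nuisance = nuisance_spec(highpass_cutoff_s = NA))
  fit <- fit_glm(bold$bold, des)
  rec <- beta_series_from_glm(fit, des, ev, mask, participant = 1)
  expect_equal(rec$X, bs$X, tolerance = 1e-8, ignore_attr = TRUE)

  # convolution linearity: fit on the sum of two signals = sum of fits
  bs2 <- bs
  bs2$X <- matrix(rnorm(4 * 27), 4)
  boldsum <- simulate_bold(bs2, tr_s = 2, noise_sd = 0, seed = 1)
  fit_sum <- fit_glm(bold$bold + boldsum$bold, des)
  expect_equal(fit_sum$betas,
               fit$betas + fit_glm(boldsum$bold, des)$betas,
               tolerance = 1e-8)
})

test_that("per-trial betas aggregated by rating match per-rating betas", {
  # noiseless: each trial of a rating level has the same amplitude
  mask <- brain_mask(array(1, c(3, 3, 3)), volume_grid(c(3, 3, 3)))
  pat <- rnorm(27)
  trials <- data.frame(participant = 1, run = 1L, trial = 1:4,
                       condition = "low", rating = c(1L, 1L, 4L, 4L),
                       shock_followed = FALSE,
                       onset = c(6, 46, 86, 126), duration = 8)
  bs <- structure(list(X = tcrossprod(trials$rating, pat),
                       trials = trials, mask = mask),
                  class = "beta_series")
  bold <- simulate_bold(bs, tr_s = 2, noise_sd = 0, seed = 1)
  ev <- trials
  ev$trial_type <- "anticipation"
  nuis <- nuisance_spec(highpass_cutoff_s = NA)
  des_t <- build_design(ev, bold$frame_times, bold$run_labels, tr_s = 2,
                        mode = "per-trial", nuisance = nuis)
  des_r <- build_design(ev, bold$frame_times, bold$run_labels, tr_s = 2,
                        mode = "per-rating", nuisance = nuis)
  fit_t <- fit_glm(bold$bold, des_t)
  fit_r <- fit_glm(bold$bold, des_r)
  rec <- beta_series_from_glm(fit_t, des_t, ev, mask, participant = 1)
  agg <- aggregate_by_rating(rec)
  expect_equal(agg[[1]]$values,
               unname(fit_r$betas["rating_1", ]), tolerance = 1e-6)
  expect_equal(agg[[2]]$values,
               unname(fit_r$betas["rating_4", ]), tolerance = 1e-6)
})
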