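test_that("permutation p-values follow the add-one formula and are valid", {
  set.seed(4)
  resp <- 1:20 + rnorm(20, sd = 0.01)
  perm <- permutation_test_r(resp, 1:20, n_perm = 400, seed = 2)
  expect_equal(perm$p, 1 / 401)  # observed beats every shuffle
  expect_length(perm$null_values, 400L)

  perm2 <- permutation_test_r(resp, 1:20, n_perm = 400, seed = 2)
  expect_identical(perm$null_values, perm2$null_values)

  expect_error(permutation_test_r(resp, 1:20, n_perm = 0), "positive")
  expect_warning(permutation_test_r(resp, 1:20, n_perm = 50, seed = 1),
                 "coarse")

  # calibration under the null: p approximately uniform
  set.seed(9)
  pv <- replicate(150, {
    permutation_test_r(rnorm(15), sample(rep(1:5, 3)), n_perm = 119,
                       seed = sample.int(1e6, 1))$p
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.05)
  expect_lt(abs(mean(pv < 0.5) - 0.5), 0.12)
})

test_that("delta-r permutation test matches its defining cases", {
  set.seed(12)
  resp <- as.numeric(scale(rnorm(40))) + rep(1:5, 8) / 2
  target <- rep(1:5, 8)

  # identical targets: observed 0, degenerate null
  d0 <- permutation_test_delta_r(resp, target, target, n_perm = 300,
                                 seed = 3)
  expect_equal(d0$observed, 0)
  expect_equal(d0$p, 1)  # degenerate null: every joint shuffle gives 0

  # target A = responses exactly, B = independent noise -> minimal p
  noise_target <- rnorm(40)
  d1 <- permutation_test_delta_r(resp, resp, noise_target, n_perm = 300,
                                 seed = 4)
  expect_equal(d1$p, 1 / 301)

  # swapping the roles negates the observed difference
  d2 <- permutation_test_delta_r(resp, noise_target, resp, n_perm = 50,
                                 seed = 5) |> suppressWarnings()
  expect_equal(d2$observed, -d1$observed)

  expect_error(permutation_test_delta_r(resp, target[-1], target),
               "matched")
})

test_that("bootstrap weight map separates signal from noise voxels", {
  set.seed(31)
  n_vox <- 60
  signal_vox <- 1:6
  parts <- rep(1:14, each = 4)
  ratings <- rep(c(1, 2, 4, 5), 14)
  X <- matrix(rnorm(length(parts) * n_vox, sd = 0.05), length(parts))
  X[, signal_vox] <- X[, signal_vox] + 0.1 * ratings
  bw <- bootstrap_weight_map(X, ratings, parts, n_boot = 120, seed = 6)
  expect_true(all(bw$sig_p001[signal_vox]))
  expect_gte(mean(!bw$sig_p001[-signal_vox]), 0.95)

  bw2 <- bootstrap_weight_map(X, ratings, parts, n_boot = 120, seed = 6)
  expect_identical(bw$z, bw2$z)
  expect_warning(bootstrap_weight_map(X, ratings, parts, n_boot = 2,
                                      seed = 1), "sd")
})

test_that("bootstrap mean-positive test behaves at the extremes", {
  expect_equal(bootstrap_mean_positive(rep(0.5, 10), n_boot = 200,
                                       seed = 1), 1 / 201)
  set.seed(2)
  sym <- rep(c(-1, 1), 25)
  p <- bootstrap_mean_positive(sym, n_boot = 400, seed = 3)
  expect_lt(abs(p - 0.5), 0.08)
  expect_identical(bootstrap_mean_positive(sym, n_boot = 100, seed = 4),
                   bootstrap_mean_positive(sym, n_boot = 100, seed = 4))
  expect_error(bootstrap_mean_positive(1:3), "at least 5")
})

test_that("forced choice scores pairs, ties and the exact binomial", {
  mask <- tiny_mask()
  n_vox <- mask$n_voxels
  w <- rnorm(n_vox)
  model <- structure(list(weights = w, intercept = 0.3, mask = NULL,
                          config = train_config(), manifest = list()),
                     class = "signature_model")
  set.seed(18)
  low <- matrix(rnorm(20 * n_vox), 20)
  high <- low + matrix(w / sum(w^2), 20, n_vox, byrow = TRUE)  # +1 response
  fc <- forced_choice(model, high, low)
  expect_equal(fc$accuracy, 1)
  expect_equal(fc$binomial_p, 2 * 0.5^20, tolerance = 1e-10)
  expect_equal(fc$binomial_p, 1.91e-6, tolerance = 1e-2)

  # ties contribute half a success to the accuracy
  fc_tie <- forced_choice(model, rbind(high[1:2, ], low[3, ]),
                          rbind(low[1:2, ], low[3, ]))
  expect_equal(fc_tie$accuracy, (1 + 1 + 0.5) / 3)

  # Cohen's d of paired differences [1, 2, 3] is 2
  d_resp <- c(1, 2, 3)
  expect_equal(mean(d_resp) / sd(d_resp), 2)

  # accuracy is invariant to strictly increasing response transforms
  resp_h <- apply_signature(model, high)
  resp_l <- apply_signature(model, low)
  expect_equal(mean(resp_h > resp_l), mean(exp(resp_h) > exp(resp_l)))

  # ROC sweeps from (0,0) to (1,1)
  expect_equal(fc$roc_points$fpr[1], 0)
  expect_equal(fc$roc_points$tpr[nrow(fc$roc_points)], 1)
})

test_that("exact binomial p matches brute-force pmf summation", {
  for (n in c(5, 12, 20, 50)) {
    for (k in unique(c(0, 1, floor(n / 3), floor(n / 2), n))) {
      expect_equal(stats::binom.test(k, n, 0.5)$p.value,
                   binom_p_bruteforce(k, n), tolerance = 1e-12,
                   label = sprintf("binom n=%d k=%d", n, k))
    }
  }
})

test_that("BH-FDR equals the brute-force step-up definition", {
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)$mask))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)$mask))
  expect_true(fdr_bh(0.04, 0.05)$mask)   # m = 1 reduces to p <= q
  expect_false(fdr_bh(0.06, 0.05)$mask)
  expect_equal(fdr_bh(numeric(0), 0.05)$mask, logical(0))
  expect_error(fdr_bh(c(0.2, 1.4)), "0, 1")

  set.seed(10)
  for (i in 1:300) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_bh(p, q)$mask, bh_bruteforce(p, q),
                     label = sprintf("BH case %d", i))
  }
})

test_that("group t-test maps match hand-computed statistics", {
  maps <- rbind(c(1, 5, 2), c(2, 5, 2), c(3, 5, 2))
  res <- group_ttest_map(maps, sidedness = "one")
  expect_equal(res$t[1], 2 * sqrt(3), tolerance = 1e-12)  # mean 2, sd 1, n 3
  expect_equal(res$p[1], pt(2 * sqrt(3), df = 2, lower.tail = FALSE))
  expect_equal(res$p[1], 0.0371, tolerance = 1e-3)
  expect_true(all(res$degenerate[2:3]))
  expect_equal(res$p[2], 0)   # all +5: limiting one-sided p
  expect_error(group_ttest_map(maps[1:2, ]), "at least 3")

  res2 <- group_ttest_map(rbind(c(-1, 0), c(-2, 0), c(-3, 0)), "two")
  expect_lt(res2$t[1], 0)
  expect_equal(res2$p[2], 1)  # exactly zero mean, zero variance
})
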