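test_that("SVR training matches the exhaustive KKT dual solution", {
  set.seed(11)
  for (trial in 1:12) {
    n <- sample(3:6, 1)
    p <- sample(1:2, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n, sd = 2)
    oracle <- svr_kkt_oracle(X, y, C = 1, eps = 0.1)
    model <- train_signature(X, y, train_config())
    expect_lt(max(abs(model$weights - oracle$w)), 1e-6)
  }
})

test_that("training recovers a realizable linear rule and is order-invariant", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  w_true <- c(1, -0.5, 2, 0, 0.3, -1)
  y <- as.numeric(X %*% w_true)
  m <- train_signature(X, y, train_config(epsilon = 0))
  expect_equal(apply_signature(m, X), y, tolerance = 1e-6)

  ord <- sample(40)
  m2 <- train_signature(X[ord, ], y[ord], train_config(epsilon = 0))
  expect_equal(m2$weights, m$weights, tolerance = 1e-6)
  expect_error(train_signature(X, rep(2, 40)), "constant")
})

test_that("scaled training problems are dual-equivalent under cost rescaling", {
  # maps scaled by k with cost C/k^2 give weights/k and the same responses
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rnorm(30, mean = 3)
  k <- 2.5
  m1 <- train_signature(X, y, train_config(cost_C = 1))
  m2 <- train_signature(k * X, y, train_config(cost_C = 1 / k^2))
  expect_equal(m2$weights, m1$weights / k, tolerance = 1e-6)
  expect_equal(m2$intercept, m1$intercept, tolerance = 1e-6)
})

test_that("z-scored features fold back into a plain dot product", {
  set.seed(8)
  X <- matrix(rnorm(30 * 5, mean = 4, sd = 3), 30, 5)
  y <- rnorm(30, mean = 3)
  m <- train_signature(X, y, train_config(feature_scaling = "zscore"))
  # responses via folded weights equal responses via explicit scaling
  Xs <- scale(X)
  ms <- train_signature(Xs, y, train_config())
  expect_equal(apply_signature(m, X),
               as.numeric(Xs %*% ms$weights + ms$intercept),
               tolerance = 1e-6)
})

test_that("signature responses are affine dot products", {
  mask <- tiny_mask()
  set.seed(2)
  X <- matrix(rnorm(20 * mask$n_voxels), 20)
  y <- rnorm(20, 3)
  m <- train_signature(X, y, mask = mask)
  expect_equal(apply_signature(m, matrix(0, 1, mask$n_voxels)),
               m$intercept)
  a <- X[1, , drop = FALSE]
  b <- X[2, , drop = FALSE]
  expect_equal(apply_signature(m, a + b),
               apply_signature(m, a) + apply_signature(m, b) - m$intercept)
  wn <- m$weights / sqrt(sum(m$weights^2))
  expect_equal(apply_signature(m, matrix(wn, 1)),
               sqrt(sum(m$weights^2)) + m$intercept)
  expect_error(apply_signature(m, matrix(0, 1, 3)), "voxels")
})

test_that("grouped cross-validation never leaks participants", {
  scheme <- cv_scheme(4, 3, seed = 9)
  parts <- rep(sprintf("s%02d", 1:8), each = 5)
  folds <- brainsig:::make_folds(parts, scheme)
  expect_length(folds, 3L)
  for (fog in folds) {
    expect_setequal(names(fog), unique(parts))
    expect_equal(sort(unique(unname(fog))), 1:4)
    # every participant in exactly one fold: train/test always disjoint
    for (f in 1:4) {
      test_ids <- names(fog)[fog == f]
      expect_length(intersect(test_ids, names(fog)[fog != f]), 0L)
    }
  }
})

test_that("cross-validated r is null-centred without signal and grows with it", {
  set.seed(21)
  null_r <- replicate(12, {
    X <- matrix(rnorm(60 * 30), 60)
    y <- rep(rep(1:5, each = 2), 6)
    parts <- rep(1:6, each = 10)
    cross_validate_signature(X, y, parts, cv_scheme(3, 2, seed = 1))$overall_r
  })
  expect_lte(mean(null_r), 0.1)

  # signal sweep: r increases monotonically with signal amplitude
  mask <- tiny_mask()
  rs <- sapply(c(0.02, 0.05, 0.1, 0.3), function(sa) {
    cohort <- small_cohort(10, seed = 33, signal_amplitude = sa)
    d <- cohort_maps(cohort)
    cross_validate_signature(d$X, d$ratings, d$participants,
                             cv_scheme(5, 2, seed = 2))$overall_r
  })
  expect_true(all(diff(rs) > 0))
})

test_that("prediction metrics match hand-computed values", {
  r <- evaluate_predictions(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(r$overall_r, 1)
  expect_equal(r$evs, 0.5)   # 1 - Var(const shift... residual 1)/Var(actual 2.5)

  ident <- evaluate_predictions(1:5, 1:5)
  expect_equal(ident$overall_r, 1)
  expect_equal(ident$evs, 1)

  flat <- evaluate_predictions(rep(3, 5), 1:5)
  expect_true(flat$flat_predicted)
  expect_true(is.na(flat$overall_r))
  expect_equal(flat$evs, 0)

  expect_error(evaluate_predictions(1:5, rep(2, 5)), "zero variance")

  # r-to-z closed form: atanh(0.5)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  g <- rep(1:2, each = 5)
  res <- evaluate_predictions(c(1:5, 5:1), c(1:5, 1:5), grouping = g)
  expect_equal(unname(res$within_participant_r), c(1, -1))
  expect_equal(res$within_mean_r, 0, tolerance = 1e-6)
})

test_that("within-individual models recover patterns and skip ineligible", {
  mask <- tiny_mask()
  pat <- make_pattern(mask, 1, 4, seed = 2)
  # noiseless participant: trial maps exactly rating * pattern
  ratings <- rep(1:5, each = 6)
  bs <- structure(list(
    X = tcrossprod(ratings, pat$values),
    trials = data.frame(participant = "s01", run = 1, trial = 1:30,
                        condition = "low", rating = ratings,
                        shock_followed = FALSE),
    mask = mask), class = "beta_series")
  few <- structure(list(
    X = bs$X[1:5, ], trials = bs$trials[1:5, ], mask = mask),
    class = "beta_series")
  out <- train_within_individual(list(bs, few), cv_scheme(5, 2, seed = 3))
  expect_equal(nrow(out$weights), 1L)
  expect_equal(out$skipped$reason, "too few trials")
  expect_gte(cosine_sim(out$weights[1, ], pat$values), 0.99)
  expect_gte(out$cv_r[1], 0.99)

  # shuffled ratings: cross-validated r centred at or below zero
  set.seed(14)
  null_r <- replicate(10, {
    shuf <- bs
    shuf$X <- matrix(rnorm(30 * mask$n_voxels), 30)
    train_within_individual(list(shuf), cv_scheme(5, 1, seed = 4))$cv_r
  })
  expect_lte(mean(null_r), 0.1)
})

test_that("signature models serialize to NIfTI + JSON and back", {
  mask <- tiny_mask()
  set.seed(6)
  X <- matrix(rnorm(20 * mask$n_voxels), 20)
  y <- rnorm(20, 3)
  m <- train_signature(X, y, mask = mask, participants = rep(1:4, 5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_signature(m, f)
  m2 <- read_signature(f, mask)
  expect_equal(m2$weights, m$weights, tolerance = 1e-6)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$config$cost_C, 1)
  expect_equal(apply_signature(m2, X), apply_signature(m, X),
               tolerance = 1e-5)
})
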