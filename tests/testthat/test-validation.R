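# jackknife, error metrics, frequency chi-square, Moran's I, Spearman

test_that("mpe and mae hand arithmetic", {
  expect_equal(mpe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mpe(c(0, 2), c(1, 1)), 0)
  expect_equal(mpe(c(3, 0, 1), c(1, 1, 1)), 1 / 3)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(0, 2), c(1, 1)), 1)
  expect_equal(mae(c(3, 0, 1), c(1, 1, 1)), 1)
  expect_error(mpe(numeric(0), numeric(0)))
  # shift linearity and the MAE >= |MPE| inequality on random vectors
  set.seed(1)
  y <- rpois(50, 2); yh <- rpois(50, 2) + runif(50)
  expect_equal(mpe(y, yh + 0.7), mpe(y, yh) - 0.7)
  expect_gte(mae(y, yh), abs(mpe(y, yh)))
})

test_that("frequency chi-square: arithmetic, merging, invariance", {
  # identical tables give 0
  y <- rep(c(0L, 1L), c(10, 5))
  expect_equal(frequency_chi2(y, y, breaks = 0:1)$chi2, 0)
  # O = (8, 2) vs P = (5, 5): 9/5 + 9/5
  o <- rep(c(0L, 1L), c(8, 2)); p <- rep(c(0, 1), c(5, 5))
  expect_equal(frequency_chi2(o, p, breaks = 0:1)$chi2, 3.6)
  # permutation invariance in block order
  set.seed(2)
  y <- rpois(200, 1); yh <- rpois(200, 1) + 0.2
  i <- sample(200)
  expect_equal(frequency_chi2(y, yh)$chi2, frequency_chi2(y[i], yh[i])$chi2)
  # small predicted categories merge upward
  res <- frequency_chi2(c(rep(0L, 9), 8L), rep(0, 10), breaks = 0:5)
  expect_true(is.finite(res$chi2) || is.infinite(res$chi2))
  # all predictions in one category, observations elsewhere: infinite + warn
  expect_warning(
    r2 <- frequency_chi2(rep(5L, 10), rep(0, 10), breaks = 0:5,
                         min_expected = 0),
    "infinite")
  expect_identical(r2$chi2, Inf)
})

test_that("probability-mode chi-square prefers the generating model", {
  # NB-hurdle data scored with its own model's implied category
  # probabilities vs a plain Poisson fit's; the generating model should give
  # the smaller statistic in most replicates.  10 replicates at n = 500
  # (scaled for runtime).
  wins <- 0
  for (r in 1:10) {
    cfg <- sim_config(n_blocks = 500,
                      beta = c(22.6, -0.013, -0.927, 0.288),
                      alpha = c(-26.1, 0.014, 0.787, -0.621),
                      seed = 70000 + r)
    d <- simulate_block_data(cfg)
    f_true <- suppressWarnings(
      fit_count_model(model_spec("hurdle_nb", quadrature_points = 3), d))
    f_pois <- fit_count_model(model_spec("poisson", quadrature_points = 3), d)
    c_true <- frequency_chi2(
      d$y, predicted_probs = predicted_category_probs(f_true, d))$chi2
    c_pois <- frequency_chi2(
      d$y, predicted_probs = predicted_category_probs(f_pois, d))$chi2
    wins <- wins + (c_true < c_pois)
  }
  expect_gte(wins, 8)
  # the probability matrix itself is a distribution per block
  cfg <- sim_config(n_blocks = 50, seed = 71000)
  d <- simulate_block_data(cfg)
  f <- suppressWarnings(
    fit_count_model(model_spec("hurdle_nb", quadrature_points = 3), d))
  pr <- predicted_category_probs(f, d)
  expect_equal(rowSums(pr), rep(1, 50), tolerance = 1e-8)
  expect_true(all(pr >= 0))
})

test_that("Moran's I: checkerboard, null calibration, errors", {
  w <- build_lattice_weights(c(4, 4), "rook")
  i <- seq_len(16) - 1L
  v <- (i %/% 4 + i %% 4) %% 2  # checkerboard in row-major cell order
  m <- morans_i(v, w)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected_I, -1 / 15)
  # iid noise on a big lattice: I within 3 SD of -1/(n-1)
  w2 <- build_lattice_weights(c(50, 50), "rook")
  set.seed(3)
  m2 <- morans_i(rnorm(2500), w2)
  expect_lt(abs(m2$I - m2$expected_I), 3 * sqrt(m2$var_I))
  expect_true(m2$p_value >= 0 && m2$p_value <= 1)
  expect_error(morans_i(rep(1, 2500), w2), "constant")
  # row-standardization does not change the checkerboard extreme
  wrs <- build_lattice_weights(c(4, 4), "rook", row_standardize = TRUE)
  expect_equal(morans_i(v, wrs)$I, -1, tolerance = 1e-12)
  # on row-standardized weights, I is bracketed by the extreme eigenvalues
  # of the symmetrized weight matrix (S0 = n there)
  wr <- build_lattice_weights(c(6, 6), "rook", row_standardize = TRUE)
  Wm <- blockcount:::.weights_matrix(wr)
  lam <- range(eigen((Wm + t(Wm)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values)
  set.seed(8)
  for (k in 1:20) {
    I_k <- morans_i(rnorm(36), wr)$I
    expect_gte(I_k, lam[1] - 1e-10)
    expect_lte(I_k, lam[2] + 1e-10)
  }
})

test_that("Spearman observed-vs-predicted", {
  expect_equal(spearman_obs_pred(1:5, 1:5 + 0.5), 1)
  expect_equal(spearman_obs_pred(1:5, 6 - (1:5)), -1)
  expect_equal(spearman_obs_pred(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- spearman_obs_pred(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("jackknife matches the closed-form intercept-only offset Poisson", {
  d <- toy_blocks(y = c(3L, 0L, 1L), n_tests = c(2L, 4L, 1L))
  spec <- model_spec("poisson", random_effects = FALSE,
                     covariate_columns = character(0))
  jk <- jackknife(spec, d)
  expected <- vapply(1:3, function(i) {
    d$n_tests[i] * sum(d$y[-i]) / sum(d$n_tests[-i])
  }, numeric(1))
  expect_equal(jk$yhat, expected, tolerance = 1e-6)
  expect_equal(mpe(jk$y, jk$yhat), mean(d$y - expected), tolerance = 1e-6)
  # identical blocks give identical predictions
  d2 <- toy_blocks(y = rep(2L, 4), n_tests = rep(3L, 4))
  d2$y[1] <- 3L  # keep some variation so the fit is non-degenerate
  jk2 <- jackknife(spec, d2)
  expect_equal(jk2$yhat[2], jk2$yhat[3], tolerance = 1e-8)
  expect_equal(jk2$yhat[3], jk2$yhat[4], tolerance = 1e-8)
})

test_that("jackknife warm starts reproduce cold-start predictions", {
  fx <- get_fixture()
  d <- fx$data[1:120, ]
  spec <- model_spec("poisson", quadrature_points = 3)
  f_full <- fit_count_model(spec, d)
  warm <- jackknife(spec, d, subsample = 6, seed = 9, full_fit = f_full)
  cold <- vapply(match(warm$block_id, d$block_id), function(i) {
    f_i <- fit_count_model(spec, d[-i, ])
    predict_expected_counts(f_i, d[i, ], mode = "marginal")
  }, numeric(1))
  expect_equal(warm$yhat, cold, tolerance = 1e-4)
})

test_that("subsampled jackknife is seeded and reproducible", {
  fx <- get_fixture()
  d <- fx$data[1:100, ]
  spec <- model_spec("poisson", random_effects = FALSE)
  j1 <- jackknife(spec, d, subsample = 5, seed = 4)
  j2 <- jackknife(spec, d, subsample = 5, seed = 4)
  expect_identical(j1, j2)
  expect_equal(nrow(j1), 5)
})

test_that("compare_models emits the comparison table with AIC deltas", {
  fx <- get_fixture()
  d <- fx$data[1:350, ]
  cmp <- compare_models(d, families = c("poisson", "nb"),
                        jackknife_subsample = 0, quadrature_points = 3)
  expect_equal(nrow(cmp$table), 2)
  expect_equal(cmp$table$aic, -2 * (-cmp$table$minus2loglik / 2) +
                 2 * cmp$table$n_params)
  expect_equal(min(cmp$table$delta_aic), 0)
  expect_true(cmp$best %in% c("poisson", "nb"))
  expect_equal(cmp$table$delta_aic, cmp$table$aic - min(cmp$table$aic))
})
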