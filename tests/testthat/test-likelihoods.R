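# marginal likelihood, quadrature, and fitting

test_that("gauss_hermite integrates polynomials exactly", {
  gh <- gauss_hermite(7)
  # int exp(-x^2) x^(2k) dx = gamma(k + 1/2)
  for (k in 0:6) {
    expect_equal(sum(gh$weights * gh$nodes^(2 * k)), gamma(k + 0.5),
                 tolerance = 1e-10)
    expect_equal(sum(gh$weights * gh$nodes^(2 * k + 1)), 0,
                 tolerance = 1e-10)
  }
})

test_that("marginal loglik at sigma2 = 0 equals the fixed-effects loglik", {
  fx <- get_fixture()
  d <- fx$data[1:200, ]
  spec <- model_spec("poisson", random_effects = TRUE)
  beta <- c(22.3, -0.013, -0.927, 0.288)
  ml <- marginal_loglik(spec, list(beta = beta, sigma2 = 0), d)
  eta <- beta[1] + beta[2] * d$x1 + beta[3] * d$x2 + beta[4] * d$x3 +
    log(d$n_tests)
  expect_equal(ml, sum(dpois(d$y, exp(eta), log = TRUE)), tolerance = 1e-10)
  # hurdle at sigma2 = 0: logistic + truncated factors, by hand
  spec_h <- model_spec("hurdle_nb")
  alpha <- c(-26.1, 0.014, 0.787, -0.621)
  ml_h <- marginal_loglik(spec_h, list(beta = beta, alpha = alpha,
                                       kappa = 1.2, sigma2 = 0,
                                       sigma2_zero = 0), d)
  eta0 <- alpha[1] + alpha[2] * d$x1 + alpha[3] * d$x2 + alpha[4] * d$x3
  z <- d$y == 0
  byhand <- sum(ifelse(z, plogis(eta0, log.p = TRUE),
                       plogis(-eta0, log.p = TRUE))) +
    sum(truncated_logpmf(d$y[!z], exp(eta[!z]), 1.2))
  expect_equal(ml_h, byhand, tolerance = 1e-8)
})

test_that("marginal likelihood matches Monte-Carlo integration on single
          blocks", {
  spec <- model_spec("poisson", quadrature_points = 25)
  for (case in list(list(y = 0L, N = 30L, s2 = 0.7),
                    list(y = 3L, N = 10L, s2 = 1.2))) {
    d1 <- as_block_table(data.frame(block_id = "a", y = case$y,
                                    n_tests = case$N,
                                    x1 = 0, x2 = 0, x3 = 0))
    beta <- c(-3.2, 0, 0, 0)
    ml <- marginal_loglik(spec, list(beta = beta, sigma2 = case$s2), d1)
    set.seed(42)
    mu <- case$N * exp(beta[1] + rnorm(1e6, 0, sqrt(case$s2)))
    p <- dpois(case$y, mu)
    mc <- mean(p)
    mc_se <- sd(p) / sqrt(1e6)
    expect_lt(abs(exp(ml) - mc), 3 * mc_se)
  }
})

test_that("quadrature converges in the node count on the fixture", {
  fx <- get_fixture()
  d <- fx$data
  params <- list(beta = get_fixture()$config$beta, sigma2 = 0.35)
  ll <- vapply(c(7, 15, 25), function(nq) {
    marginal_loglik(model_spec("poisson", quadrature_points = nq), params, d)
  }, numeric(1))
  # Cauchy criterion between 15 and 25 nodes; measured 4.7e-8 here
  expect_lt(abs(ll[3] - ll[2]), 1e-4)
  # 7-node total error on the 1393-block fixture, derived against the
  # 25-node limit: 2.6e-4 (about 1.9e-7 per block)
  expect_lt(abs(ll[3] - ll[1]), 1e-3)
  expect_lt(abs(ll[3] - ll[2]), abs(ll[2] - ll[1]))  # monotone approach
})

test_that("no-RE fits reproduce reference GLM coefficients to 1e-4 relative", {
  fx <- get_fixture()
  d <- fx$data
  # Poisson with offset vs stats::glm
  f <- fit_count_model(model_spec("poisson", random_effects = FALSE), d)
  ref <- glm(y ~ x1 + x2 + x3 + offset(log(n_tests)), poisson(), data = d)
  expect_equal(unname(f$beta_hat), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(f$n_params, 4L)
  # NB vs MASS::glm.nb (kappa = 1/theta)
  f_nb <- fit_count_model(model_spec("nb", random_effects = FALSE), d)
  ref_nb <- MASS::glm.nb(y ~ x1 + x2 + x3 + offset(log(n_tests)), data = d)
  expect_equal(unname(f_nb$beta_hat), unname(coef(ref_nb)), tolerance = 1e-4)
  expect_equal(f_nb$kappa_hat, 1 / ref_nb$theta, tolerance = 1e-3)
  expect_equal(f_nb$n_params, 5L)
  # hurdle logistic part vs stats::glm on the zero indicator
  f_h <- fit_count_model(model_spec("hurdle_poisson", random_effects = FALSE),
                         d)
  ref_b <- glm(I(y == 0) ~ x1 + x2 + x3, binomial(), data = d)
  expect_equal(unname(f_h$alpha_hat), unname(coef(ref_b)), tolerance = 1e-4)
  # truncated Poisson part vs an independently-coded optim oracle
  # (the oracle centres the covariates itself so BFGS is well-conditioned)
  pos <- d$y > 0
  Xp <- cbind(d$x1, d$x2, d$x3)[pos, ]
  xm <- colMeans(Xp)
  Xp <- sweep(Xp, 2, xm)
  nll <- function(b) {
    mu <- exp(b[1] + Xp %*% b[2:4] + log(d$n_tests[pos]))
    -sum(dpois(d$y[pos], mu, log = TRUE) - log(1 - exp(-mu)))
  }
  # alternate optimizers until the flat intercept direction is fully polished
  op <- rep(0, 4)
  for (k in 1:4) {
    op <- optim(op, nll, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-15))$par
    op <- nlminb(op, nll, control = list(rel.tol = 1e-15, x.tol = 1e-12))$par
  }
  oracle_par <- c(op[1] - sum(op[2:4] * xm), op[2:4])
  expect_equal(unname(f_h$beta_hat), oracle_par, tolerance = 1e-4)
  expect_equal(f_h$n_params, 8L)
})

test_that("parameter counts follow the published accounting for RE models", {
  fx <- get_fixture()
  d <- fx$data[1:400, ]
  counts <- vapply(c("poisson", "nb", "hurdle_poisson", "hurdle_nb"),
                   function(fam) {
                     fit_count_model(model_spec(fam, quadrature_points = 3),
                                     d)$n_params
                   }, numeric(1))
  expect_equal(unname(counts), c(5, 6, 10, 11))
})

test_that("hurdle likelihood factorizes: joint loglik = part logliks", {
  fx <- get_fixture()
  d <- fx$data[1:400, ]
  spec <- model_spec("hurdle_nb", quadrature_points = 7)
  f <- fit_count_model(spec, d)
  joint <- marginal_loglik(spec, list(
    beta = f$beta_hat, alpha = f$alpha_hat, kappa = f$kappa_hat,
    sigma2 = f$sigma2_hat, sigma2_zero = f$sigma2_zero_hat
  ), d)
  # marginal_loglik integrates the binary part at spec$quadrature_points,
  # the fit at >= 25 nodes; both are converged well past 1e-3 here
  expect_equal(joint, f$loglik, tolerance = 1e-3)
  # aic invariant holds exactly
  expect_identical(f$aic, -2 * f$loglik + 2 * f$n_params)
})

test_that("fitting NB to Poisson data drives kappa to zero", {
  cfg <- sim_config(n_blocks = 1e4, family = "poisson",
                    beta = c(22.3, -0.013, -0.927, 0.288), sigma2 = 0,
                    seed = 201)
  d <- simulate_block_data(cfg)
  f <- fit_count_model(model_spec("nb", random_effects = FALSE), d)
  expect_lt(f$kappa_hat, 0.05)
})

test_that("Poisson+RE recovery: 3-SE coverage over replicates", {
  beta <- c(22.3, -0.013, -0.927, 0.288)
  covered <- matrix(NA, 15, 4)
  for (r in 1:15) {
    cfg <- sim_config(family = "poisson", beta = beta, sigma2 = 0.7,
                      seed = 300 + r)
    d <- simulate_block_data(cfg)
    f <- fit_count_model(model_spec("poisson", quadrature_points = 7), d)
    covered[r, ] <- abs(f$beta_hat - beta) < 3 * f$beta_se
  }
  expect_true(all(colMeans(covered) >= 0.9))
})

test_that("expected-count predictions: degenerate, marginal, and hurdle", {
  fx <- get_fixture()
  d <- fx$data[1:300, ]
  # sigma2 = 0: plain GLM mean
  f0 <- fit_count_model(model_spec("poisson", random_effects = FALSE), d)
  pred <- predict_expected_counts(f0, d)
  eta <- cbind(1, d$x1, d$x2, d$x3) %*% f0$beta_hat + log(d$n_tests)
  expect_equal(pred, drop(exp(eta)), tolerance = 1e-10)
  # marginal Poisson+RE mean: lognormal identity vs Monte Carlo
  f1 <- fit_count_model(model_spec("poisson"), d)
  pred1 <- predict_expected_counts(f1, d, mode = "marginal")
  set.seed(7)
  g <- rnorm(1e6, 0, sqrt(f1$sigma2_hat))
  mc_factor <- mean(exp(g)); mc_se <- sd(exp(g)) / sqrt(1e6)
  eta1 <- drop(cbind(1, d$x1, d$x2, d$x3) %*% f1$beta_hat + log(d$n_tests))
  expect_lt(max(abs(pred1 - exp(eta1) * mc_factor)),
            3 * mc_se * max(exp(eta1)))
  # conditional mode requires fitted blocks
  expect_error(predict_expected_counts(f1, fx$data[301:310, ],
                                       mode = "conditional"),
               "marginal")
  # hurdle block with p0 ~ 1 predicts ~ 0
  fh <- fit_count_model(model_spec("hurdle_nb", quadrature_points = 3), d)
  fh$alpha_hat[1] <- fh$alpha_hat[1] + 50  # push logit P(zero) to +inf
  ph <- predict_expected_counts(fh, d[1, ], mode = "marginal")
  expect_lt(ph, 1e-6)
})

test_that("degenerate inputs are rejected with useful errors", {
  d <- toy_blocks(y = c(0L, 0L, 0L))
  expect_error(fit_count_model(model_spec("poisson"), d), "variation")
  d2 <- get_fixture()$data[1:50, ]
  d2$y <- pmax(d2$y, 1L)
  d2$y[1] <- 3L  # variation among positives, but no zero anywhere
  expect_error(fit_count_model(model_spec("hurdle_nb"), d2), "zero")
  d3 <- get_fixture()$data[1:50, ]
  d3$n_tests[3] <- 0L
  expect_error(fit_count_model(model_spec("poisson"), d3), "offset")
})
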