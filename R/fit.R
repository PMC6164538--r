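# Maximum marginal likelihood fitting of the four count-model families with
# a block-level random intercept and a log-offset, via adaptive Gauss-Hermite
# quadrature (see quadrature.R).
#
# Hurdle likelihoods factorize exactly into a Bernoulli part (zero vs
# positive, with its own intercept variance) and a zero-truncated count part
# (positives only), because the two random-effect streams are independent.
# The factors are maximized separately, which is the exact joint MLE; the
# joint marginal log-likelihood is still exposed through marginal_loglik().

#' Model specification
#'
#' @param family one of \code{"poisson"}, \code{"nb"},
#'   \code{"hurdle_poisson"}, \code{"hurdle_nb"}.
#' @param random_effects include a Gaussian block random intercept (one per
#'   part for hurdle families)?
#' @param offset_column column of \code{data} holding the population-at-risk
#'   offset \code{N_i} (coefficient fixed at 1 on the log scale).
#' @param covariate_columns covariate columns entering both linear
#'   predictors; may be empty for an intercept-only model.
#' @param quadrature_points odd positive number of adaptive Gauss-Hermite
#'   nodes; 1 gives the Laplace approximation.
#' @param rel_tol,grad_tol,max_iter optimizer stopping controls: relative
#'   log-likelihood change, gradient max-norm at the reported optimum, and
#'   the iteration cap.
#' @return a \code{model_spec} object.
#' @export
model_spec <- function(family = c("poisson", "nb", "hurdle_poisson",
                                  "hurdle_nb"),
                       random_effects = TRUE,
                       offset_column = "n_tests",
                       covariate_columns = c("x1", "x2", "x3"),
                       quadrature_points = 7L,
                       rel_tol = 1e-8, grad_tol = 1e-4, max_iter = 500L) {
  family <- match.arg(family)
  quadrature_points <- as.integer(quadrature_points)
  stopifnot(quadrature_points >= 1)
  structure(
    list(family = family, random_effects = isTRUE(random_effects),
         offset_column = offset_column,
         covariate_columns = as.character(covariate_columns),
         quadrature_points = quadrature_points,
         rel_tol = rel_tol, grad_tol = grad_tol,
         max_iter = as.integer(max_iter)),
    class = "model_spec"
  )
}

# design matrix + log offset from a block table
.design <- function(spec, data) {
  miss <- setdiff(c(spec$offset_column, spec$covariate_columns), names(data))
  if (length(miss)) {
    stop("data is missing required column(s): ", paste(miss, collapse = ", "))
  }
  N <- data[[spec$offset_column]]
  if (any(N < 1)) {
    stop("offsets must be >= 1 (log of a zero offset is undefined)")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, spec$covariate_columns, drop = FALSE]))
  rownames(X) <- NULL
  list(X = X, log_n = log(N))
}

# ---- single-part likelihood and fit -------------------------------------
#
# theta layout: (coef ..., [log kappa], [log sigma2])

.part_negloglik <- function(theta, y, X, off, type, nb, truncated, re, nq,
                            cache) {
  p <- ncol(X)
  coefs <- theta[seq_len(p)]
  kappa <- if (nb) exp(min(theta[p + 1L], 20)) else NULL
  sigma2 <- if (re) exp(min(theta[length(theta)], 20)) else 0
  eta <- drop(X %*% coefs) + off
  if (any(!is.finite(eta)) || any(eta > 500)) return(1e10)
  part <- if (type == "binary") {
    .part_binomial()
  } else {
    .family_part(if (nb) "nb" else "poisson", kappa, truncated)
  }
  ll <- .agh_loglik(y, eta, sigma2, part, nq = nq, cache = cache)
  val <- sum(ll)
  if (!is.finite(val)) return(1e10)  # optimizer treats as rejection
  -val
}

.fd_gradient <- function(fn, par, h = 1e-5) {
  vapply(seq_along(par), function(j) {
    hj <- h * max(1, abs(par[j]))
    ej <- numeric(length(par)); ej[j] <- hj
    (fn(par + ej) - fn(par - ej)) / (2 * hj)
  }, numeric(1))
}

.fd_hessian <- function(fn, par, h = 1e-4) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    hj <- h * max(1, abs(par[j]))
    ej <- numeric(p); ej[j] <- hj
    H[, j] <- (.fd_gradient(fn, par + ej) - .fd_gradient(fn, par - ej)) /
      (2 * hj)
  }
  (H + t(H)) / 2
}

.fit_part <- function(y, X, off, type = c("count", "binary"),
                      nb = FALSE, truncated = FALSE, re = TRUE, nq = 7L,
                      control = list(), start = NULL) {
  type <- match.arg(type)
  p <- ncol(X)
  # centre covariates for optimizer/Hessian conditioning (year ~ 1900 would
  # otherwise make the intercept column nearly collinear with it)
  xbar <- c(0, colMeans(X[, -1, drop = FALSE]))
  Xc <- X
  if (p > 1) Xc[, -1] <- sweep(X[, -1, drop = FALSE], 2, xbar[-1])
  to_centered <- function(th) {
    th[1] <- th[1] + sum(th[seq_len(p)][-1] * xbar[-1])
    th
  }
  from_centered <- function(th) {
    th[1] <- th[1] - sum(th[seq_len(p)][-1] * xbar[-1])
    th
  }
  if (is.null(start)) {
    glm_fam <- if (type == "binary") binomial() else poisson()
    g0 <- suppressWarnings(
      glm.fit(Xc, y, offset = off, family = glm_fam,
              control = list(maxit = 100))
    )
    start <- coef(g0)
    start[!is.finite(start)] <- 0
    if (nb) start <- c(start, log(0.5))
    if (re) start <- c(start, log(0.5))
  } else {
    start <- to_centered(start)
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(th) .part_negloglik(th, y, Xc, off, type, nb, truncated, re,
                                     nq, cache)
  np <- length(start)
  # log-scale bounds on kappa/sigma2 are numerical guards, not constraints
  lower <- c(rep(-Inf, p), rep(-15, np - p))
  upper <- c(rep(Inf, p), rep(log(100), np - p))
  ctl <- list(rel.tol = control$rel_tol %||% 1e-10,
              iter.max = control$max_iter %||% 500, eval.max = 2000)
  opt <- nlminb(start, fn, lower = lower, upper = upper, control = ctl)
  par_c <- opt$par
  grad <- .fd_gradient(fn, par_c)
  # a warm start close to the optimum can trip rel.tol before the gradient is
  # flat; restart until the scaled gradient criterion holds (or give up)
  gtol <- (control$grad_tol %||% 1e-4) * max(1, abs(opt$objective))
  tries <- 0L
  while (max(abs(grad)) > gtol && tries < 3L) {
    # polish with a different algorithm, then let nlminb re-verify
    pol <- optim(par_c, fn, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-14))
    opt <- nlminb(pol$par, fn, lower = lower, upper = upper, control = ctl)
    if (opt$objective > pol$value) opt$par <- pol$par
    par_c <- opt$par
    grad <- .fd_gradient(fn, par_c)
    tries <- tries + 1L
  }
  # Covariance in centered space, mapped back through the (linear)
  # recentering.  A variance/dispersion parameter collapsed to the boundary
  # (kappa or sigma2 ~ 0) leaves a flat log-scale direction; such parameters
  # are frozen out of the observed information and their own SE reported NA,
  # instead of letting one flat direction void every standard error.
  se <- rep(NA_real_, np)
  frozen <- c(rep(FALSE, p), par_c[seq_len(np - p) + p] < log(1e-4))
  free <- which(!frozen)
  fn_free <- function(th_free) {
    th <- par_c; th[free] <- th_free; fn(th)
  }
  H <- tryCatch(.fd_hessian(fn_free, par_c[free]), error = function(e) NULL)
  singular <- TRUE
  if (!is.null(H) && all(is.finite(H))) {
    Vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vc) && all(diag(Vc) > 0)) {
      Vfull <- matrix(0, np, np)
      Vfull[free, free] <- Vc
      A <- diag(np)
      if (p > 1) A[1, 2:p] <- -xbar[-1]
      V <- A %*% Vfull %*% t(A)
      se <- sqrt(pmax(diag(V), 0))
      se[frozen] <- NA_real_
      singular <- FALSE
    }
  }
  if (singular) {
    warning("observed information is singular; standard errors set to NA")
  }
  par <- from_centered(par_c)
  coefs <- par[seq_len(p)]
  kappa <- if (nb) unname(exp(par[p + 1L])) else NULL
  sigma2 <- if (re) unname(exp(par[np])) else 0
  # empirical-Bayes modes at the optimum
  eta <- drop(X %*% coefs) + off
  part <- if (type == "binary") .part_binomial() else
    .family_part(if (nb) "nb" else "poisson", kappa, truncated)
  det <- .agh_loglik(y, eta, sigma2, part, nq = nq, details = TRUE)
  list(
    par = par, coefficients = setNames(coefs, colnames(X)),
    coef_se = setNames(se[seq_len(p)], colnames(X)),
    kappa = kappa,
    kappa_se = if (nb) se[p + 1L] * kappa else NULL,  # delta method
    sigma2 = if (re) sigma2 else 0,
    sigma2_se = if (re) se[np] * sigma2 else NULL,
    loglik = -opt$objective,
    n_params = np,
    # the gradient check is scaled by |logL|: at n ~ 1400 an absolute 1e-4
    # max-norm is below the finite-difference noise floor of the gradient.
    # nlminb's own code is advisory only -- restarted at an optimum it
    # reports "false convergence" even when the gradient criterion holds.
    converged = max(abs(grad)) < gtol,
    gradient_norm = max(abs(grad)),
    ranef = det$mode,
    message = opt$message
  )
}

# ---- public fitting interface -------------------------------------------

#' Fit a block count model by maximum marginal likelihood
#'
#' Fits the family requested in \code{spec} to a block table, integrating the
#' block random intercept(s) out by adaptive Gauss-Hermite quadrature.
#' Hurdle families are fitted as their two exact factors: a logistic model
#' for \code{P(Y_i = 0)} over all blocks and a zero-truncated count model
#' over the positive blocks.  Standard errors come from the inverse of the
#' numerically differentiated observed information; variance components and
#' the NB dispersion are optimized on the log scale and reported on the
#' natural scale with delta-method standard errors.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data a \code{block_table} (or plain data frame with the required
#'   columns).
#' @param start optional warm start: list of part parameter vectors from a
#'   previous fit's \code{$parts} (used heavily by the jackknife).
#' @return a \code{blockcount_fit} with elements \code{beta_hat},
#'   \code{alpha_hat} (hurdle), \code{kappa_hat}, \code{sigma2_hat},
#'   \code{sigma2_zero_hat}, \code{loglik}, \code{n_params}, \code{aic},
#'   \code{converged}, \code{gradient_norm}, and per-block empirical-Bayes
#'   random-effect estimates in \code{ranef}.
#' @export
fit_count_model <- function(spec, data, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  y <- data$y
  if (is.null(y)) stop("data must contain a `y` count column")
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  if (all(y == y[1])) stop("degenerate data: no variation in y")
  d <- .design(spec, data)
  ctl <- list(rel_tol = spec$rel_tol, max_iter = spec$max_iter,
              grad_tol = spec$grad_tol)
  nq <- spec$quadrature_points
  re <- spec$random_effects
  hurdle <- .is_hurdle(spec$family)
  nb <- .is_nb(spec$family)
  n <- length(y)

  parts <- list()
  if (!hurdle) {
    parts$count <- .fit_part(y, d$X, d$log_n, "count", nb = nb,
                             truncated = FALSE, re = re, nq = nq,
                             control = ctl, start = start$count)
  } else {
    if (!any(y == 0) || !any(y > 0)) {
      stop("hurdle models need at least one zero and one positive count")
    }
    z <- as.numeric(y == 0)  # logistic part models P(Y = 0)
    # the Bernoulli integrand is wide and skewed relative to its curvature at
    # the mode, and its likelihood surface in (alpha, sigma2_zero) is a flat
    # ridge: a low node count leaves quadrature error that creates spurious
    # optima at large sigma2_zero.  Nodes are cheap here, so use >= 25.
    parts$binary <- .fit_part(z, d$X, rep(0, n), "binary", nb = FALSE,
                              truncated = FALSE, re = re, nq = max(nq, 25L),
                              control = ctl, start = start$binary)
    pos <- y > 0
    parts$count <- .fit_part(y[pos], d$X[pos, , drop = FALSE],
                             d$log_n[pos], "count", nb = nb,
                             truncated = TRUE, re = re, nq = nq,
                             control = ctl, start = start$count)
  }

  loglik <- sum(vapply(parts, `[[`, numeric(1), "loglik"))
  n_params <- sum(vapply(parts, `[[`, numeric(1), "n_params"))
  ranef <- data.frame(block_id = data$block_id %||% seq_len(n))
  if (hurdle) {
    ranef$gamma_zero <- if (re) parts$binary$ranef else 0
    g <- numeric(n)  # zero blocks carry no count-part information: mode 0
    if (re) g[y > 0] <- parts$count$ranef
    ranef$gamma <- g
  } else {
    ranef$gamma <- if (re) parts$count$ranef else 0
  }

  structure(
    list(
      spec = spec, family = spec$family, n = n,
      beta_hat = parts$count$coefficients,
      beta_se = parts$count$coef_se,
      alpha_hat = if (hurdle) parts$binary$coefficients else NULL,
      alpha_se = if (hurdle) parts$binary$coef_se else NULL,
      kappa_hat = parts$count$kappa,
      kappa_se = parts$count$kappa_se,
      sigma2_hat = if (re) parts$count$sigma2 else NULL,
      sigma2_se = if (re) parts$count$sigma2_se else NULL,
      sigma2_zero_hat = if (hurdle && re) parts$binary$sigma2 else NULL,
      sigma2_zero_se = if (hurdle && re) parts$binary$sigma2_se else NULL,
      loglik = loglik, n_params = n_params,
      aic = aic(loglik, n_params),
      converged = all(vapply(parts, `[[`, logical(1), "converged")),
      gradient_norm = max(vapply(parts, `[[`, numeric(1), "gradient_norm")),
      ranef = ranef,
      parts = lapply(parts, `[[`, "par"),
      block_id = data$block_id %||% seq_len(n)
    ),
    class = "blockcount_fit"
  )
}

#' Marginal log-likelihood at given parameter values
#'
#' Evaluates the random-effects-integrated log-likelihood of a block table at
#' user-supplied parameters, without fitting.  With \code{sigma2 = 0} (and
#' \code{sigma2_zero = 0}) this is exactly the fixed-effects log-likelihood.
#' For hurdle families the value is the sum of the logistic factor and the
#' zero-truncated factor, which are independent.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param params list with \code{beta} and, as the family requires,
#'   \code{alpha}, \code{kappa}, \code{sigma2}, \code{sigma2_zero}.
#' @param data a block table.
#' @return the scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(spec, params, data) {
  stopifnot(inherits(spec, "model_spec"))
  d <- .design(spec, data)
  y <- data$y
  nq <- spec$quadrature_points
  sigma2 <- if (spec$random_effects) params$sigma2 %||% 0 else 0
  kappa <- if (.is_nb(spec$family)) params$kappa else NULL
  stopifnot(length(params$beta) == ncol(d$X))
  eta <- drop(d$X %*% params$beta) + d$log_n
  if (!.is_hurdle(spec$family)) {
    part <- .family_part(if (.is_nb(spec$family)) "nb" else "poisson",
                         kappa, truncated = FALSE)
    return(sum(.agh_loglik(y, eta, sigma2, part, nq = nq)))
  }
  stopifnot(length(params$alpha) == ncol(d$X))
  sigma2_zero <- if (spec$random_effects) params$sigma2_zero %||% 0 else 0
  z <- as.numeric(y == 0)
  eta0 <- drop(d$X %*% params$alpha)
  ll_bin <- sum(.agh_loglik(z, eta0, sigma2_zero, .part_binomial(), nq = nq))
  pos <- y > 0
  part <- .family_part(if (.is_nb(spec$family)) "nb" else "poisson",
                       kappa, truncated = TRUE)
  ll_cnt <- sum(.agh_loglik(y[pos], eta[pos], sigma2, part, nq = nq))
  ll_bin + ll_cnt
}

# ---- prediction ---------------------------------------------------------

# E over gamma ~ N(0, sigma2) of g(eta + gamma), by (non-adaptive) GH
.gh_expect <- function(eta, sigma2, g, nq = 31L) {
  if (sigma2 < 1e-12) return(g(eta))
  gh <- gauss_hermite(nq)
  w <- gh$weights / sqrt(pi)
  out <- 0
  for (k in seq_len(nq)) {
    out <- out + w[k] * g(eta + sqrt(2 * sigma2) * gh$nodes[k])
  }
  out
}

# mean of the zero-truncated base family with untruncated mean mu
.trunc_mean <- function(mu, kappa = NULL) {
  mu / (-expm1(if (is.null(kappa) || kappa < .KAPPA_POISSON_LIMIT) {
    -mu
  } else {
    -log1p(kappa * mu) / kappa
  }))
}

#' Expected counts from a fitted model
#'
#' \code{mode = "marginal"} integrates the random intercept(s) out: for the
#' log link this multiplies the fixed-effect mean by \code{exp(sigma2/2)};
#' hurdle means are composed as \code{E[1 - p0] * E[mu / (1 - f(0; mu))]}
#' with each expectation taken over its own intercept distribution.
#' \code{mode = "conditional"} plugs in the empirical-Bayes intercept
#' estimates and is only defined for the blocks the model was fitted to.
#'
#' @param fit a \code{blockcount_fit}.
#' @param data block table to predict for.
#' @param mode \code{"marginal"} or \code{"conditional"}.
#' @return numeric vector of expected counts, offset applied.
#' @export
predict_expected_counts <- function(fit, data,
                                    mode = c("marginal", "conditional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "blockcount_fit"))
  spec <- fit$spec
  d <- .design(spec, data)
  hurdle <- .is_hurdle(fit$family)
  kappa <- if (.is_nb(fit$family)) fit$kappa_hat else NULL
  sigma2 <- fit$sigma2_hat %||% 0
  eta <- drop(d$X %*% fit$beta_hat) + d$log_n

  if (mode == "conditional") {
    ids <- data$block_id %||% seq_len(nrow(data))
    idx <- match(ids, fit$block_id)
    if (anyNA(idx)) {
      stop("conditional predictions are only defined for fitted blocks; ",
           "use mode = \"marginal\" for new blocks")
    }
    g <- fit$ranef$gamma[idx]
    if (!hurdle) return(exp(eta + g))
    g0 <- fit$ranef$gamma_zero[idx]
    eta0 <- drop(d$X %*% fit$alpha_hat) + g0
    p0 <- plogis(eta0)
    return((1 - p0) * .trunc_mean(exp(eta + g), kappa))
  }

  if (!hurdle) return(exp(eta + sigma2 / 2))
  sigma2_zero <- fit$sigma2_zero_hat %||% 0
  eta0 <- drop(d$X %*% fit$alpha_hat)
  # P(Y > 0) averaged over the logistic-part intercept
  p_pos <- .gh_expect(eta0, sigma2_zero, function(g) 1 - plogis(g))
  # truncated-part mean averaged over the count-part intercept
  m_pos <- .gh_expect(eta, sigma2,
                      function(g) .trunc_mean(exp(g), kappa))
  p_pos * m_pos
}

#' @export
print.blockcount_fit <- function(x, ...) {
  cat(sprintf("blockcount fit: %s%s, n = %d\n", x$family,
              if (x$spec$random_effects) " + RE" else "", x$n))
  cat(sprintf("  logLik %.2f  AIC %.2f  (p = %d)%s\n",
              x$loglik, x$aic, x$n_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$beta_hat, se = x$beta_se)
  cat("  count part:\n")
  print(round(tab, 4))
  if (!is.null(x$alpha_hat)) {
    cat("  logistic part (logit P(Y = 0)):\n")
    print(round(data.frame(estimate = x$alpha_hat, se = x$alpha_se), 4))
  }
  if (!is.null(x$kappa_hat)) {
    cat(sprintf("  kappa = %.4f (se %.4f)\n", x$kappa_hat,
                x$kappa_se %||% NA))
  }
  if (!is.null(x$sigma2_hat)) {
    cat(sprintf("  sigma2 = %.4f (se %.4f)\n", x$sigma2_hat,
                x$sigma2_se %||% NA))
  }
  if (!is.null(x$sigma2_zero_hat)) {
    cat(sprintf("  sigma2_zero = %.4f (se %.4f)\n", x$sigma2_zero_hat,
                x$sigma2_zero_se %||% NA))
  }
  invisible(x)
}

#' @export
logLik.blockcount_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}
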