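# Probability mass functions for the four count families.
#
# The NB2 pmf is written out via log-gamma rather than delegated to dnbinom()
# because it, together with its zero-truncated form, is the computational core
# of the hurdle likelihoods; dnbinom() serves as an independent oracle in the
# test suite.

# below this, NB is numerically indistinguishable from its Poisson limit and
# the lgamma differences start losing precision
.KAPPA_POISSON_LIMIT <- 1e-6

#' Negative binomial (NB2) log probability mass
#'
#' Computes \code{log P(Y = y)} for the NB2 distribution with mean \code{mu}
#' and dispersion \code{kappa}, parameterized so that
#' \code{Var(Y) = mu (1 + kappa mu)}.  As \code{kappa -> 0} the distribution
#' converges to Poisson(\code{mu}); below a small threshold the Poisson
#' log-pmf is returned directly, which is both the analytic limit and the
#' numerically stable branch.
#'
#' @param y vector of non-negative integer counts.
#' @param mu positive mean(s), recycled against \code{y}.
#' @param kappa single non-negative dispersion; \code{kappa = 0} gives Poisson.
#' @return vector of log-probabilities.
#' @examples
#' nb_logpmf(0, mu = 2, kappa = 1)  # log(1/3)
#' @export
nb_logpmf <- function(y, mu, kappa) {
  stopifnot(length(kappa) == 1L, kappa >= 0, all(mu > 0))
  if (any(y < 0) || any(y != floor(y))) {
    stop("`y` must contain non-negative integers")
  }
  if (kappa < .KAPPA_POISSON_LIMIT) {
    return(dpois(y, lambda = mu, log = TRUE))
  }
  inv <- 1 / kappa
  km <- kappa * mu
  lgamma(y + inv) - lgamma(y + 1) - lgamma(inv) -
    inv * log1p(km) + y * (log(km) - log1p(km))
}

#' Poisson log probability mass
#'
#' Thin wrapper around \code{\link[stats]{dpois}} kept for symmetry with
#' \code{\link{nb_logpmf}}.
#'
#' @inheritParams nb_logpmf
#' @export
pois_logpmf <- function(y, mu) dpois(y, lambda = mu, log = TRUE)

# log(1 - P(0)) for the base family, stable when P(0) is close to 0 or 1.
# Poisson: 1 - exp(-mu); NB2: 1 - (1 + kappa mu)^(-1/kappa).
.log1m_p0 <- function(mu, kappa = NULL) {
  if (is.null(kappa) || kappa < .KAPPA_POISSON_LIMIT) {
    log(-expm1(-mu))
  } else {
    log(-expm1(-log1p(kappa * mu) / kappa))
  }
}

#' Zero-truncated Poisson/NB log probability mass
#'
#' Log pmf of the base family renormalized over \code{y >= 1}:
#' \code{log[f(y) / (1 - f(0))]}.  Stable for means far below 1, where
#' \code{1 - f(0)} is itself tiny (computed through \code{expm1}).
#'
#' @param y vector of positive integer counts.
#' @param mu positive mean(s) of the untruncated base distribution.
#' @param kappa NB dispersion, or \code{NULL} for the truncated Poisson.
#' @return vector of log-probabilities over the support \code{y >= 1}.
#' @export
truncated_logpmf <- function(y, mu, kappa = NULL) {
  if (any(y < 1)) stop("zero-truncated pmf is undefined at y = 0")
  base <- if (is.null(kappa)) pois_logpmf(y, mu) else nb_logpmf(y, mu, kappa)
  base - .log1m_p0(mu, kappa)
}

#' Hurdle log probability mass
#'
#' Two-part pmf: probability \code{p0} of a zero, and \code{(1 - p0)} spread
#' over the positives according to the zero-truncated base family.
#'
#' @param y vector of non-negative integer counts.
#' @param p0 probability of a zero count (clamped away from 0 and 1).
#' @param mu mean of the untruncated base distribution for the positive part.
#' @param kappa NB dispersion or \code{NULL} for the Poisson hurdle.
#' @return vector of log-probabilities.
#' @export
hurdle_logpmf <- function(y, p0, mu, kappa = NULL) {
  p0 <- .clamp_prob(p0)
  out <- numeric(length(y))
  zero <- y == 0
  p0 <- rep_len(p0, length(y))
  mu <- rep_len(mu, length(y))
  out[zero] <- log(p0[zero])
  if (any(!zero)) {
    out[!zero] <- log1p(-p0[!zero]) +
      truncated_logpmf(y[!zero], mu[!zero], kappa)
  }
  out
}

#' Variance inflation of the negative binomial family
#'
#' Ratio of variance to mean implied by the NB variance function
#' \code{Var(Y) = mu + kappa mu^r}, i.e. \code{1 + kappa mu^(r-1)}.  With the
#' linear variance function (\code{r = 1}) the inflation is \code{1 + kappa}
#' regardless of the mean; with \code{r = 2} it is the NB2 value
#' \code{1 + kappa mu}.
#'
#' @param kappa non-negative dispersion parameter.
#' @param mu positive mean (ignored when \code{r = 1}).
#' @param r variance-function exponent, default 1 (linear).
#' @return the variance/mean ratio.
#' @examples
#' variance_inflation(1.1424)            # 2.1424
#' variance_inflation(2, mu = 3, r = 2)  # 7
#' @export
variance_inflation <- function(kappa, mu = 1, r = 1) {
  stopifnot(kappa >= 0, all(mu > 0))
  1 + kappa * mu^(r - 1)
}

#' Akaike information criterion
#'
#' \code{AIC = -2 logL + 2 p} where \code{p} counts every free parameter,
#' including variance components and the NB dispersion.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters.
#' @export
aic <- function(loglik, n_params) {
  stopifnot(n_params >= 0)
  -2 * loglik + 2 * n_params
}
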