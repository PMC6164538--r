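# Adaptive Gauss-Hermite quadrature for one random intercept per block.
#
# Every mixed-model likelihood in the package reduces to a product over blocks
# of one-dimensional integrals
#     L_i = int f(y_i | eta_i + t) phi(t; 0, sigma^2) dt,
# because each census block contributes a single observation and its own
# latent intercept.  The integrand is mode-centred and curvature-scaled per
# block (adaptive GH); one node recovers the Laplace approximation.

#' Gauss-Hermite nodes and weights
#'
#' Physicists' rule for \code{int exp(-x^2) g(x) dx}, computed by the
#' Golub-Welsch eigendecomposition of the Jacobi matrix.
#'
#' @param n number of nodes (positive integer).
#' @return list with \code{nodes} and \code{weights}, nodes ascending.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1, n == floor(n))
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# ---- conditional log-likelihood "parts" ---------------------------------
# Each part supplies cll(y, g) and its derivative in g, where g is the full
# linear predictor (eta + gamma): log-mean scale for count parts, logit scale
# for the binary part.

.part_poisson <- function() {
  list(
    cll = function(y, g) y * g - exp(g) - lgamma(y + 1),
    cll_d = function(y, g) y - exp(g)
  )
}

.part_nb <- function(kappa) {
  if (kappa < .KAPPA_POISSON_LIMIT) return(.part_poisson())
  inv <- 1 / kappa
  list(
    cll = function(y, g) nb_logpmf(y, exp(g), kappa),
    cll_d = function(y, g) {
      km <- kappa * exp(g)
      y - (y + inv) * km / (1 + km)
    }
  )
}

.part_trunc_poisson <- function() {
  base <- .part_poisson()
  list(
    cll = function(y, g) {
      mu <- exp(g)
      base$cll(y, g) - log(-expm1(-mu))
    },
    cll_d = function(y, g) {
      mu <- exp(g)
      base$cll_d(y, g) - mu * exp(-mu) / (-expm1(-mu))
    }
  )
}

.part_trunc_nb <- function(kappa) {
  if (kappa < .KAPPA_POISSON_LIMIT) return(.part_trunc_poisson())
  base <- .part_nb(kappa)
  list(
    cll = function(y, g) {
      mu <- exp(g)
      base$cll(y, g) - log(-expm1(-log1p(kappa * mu) / kappa))
    },
    cll_d = function(y, g) {
      mu <- exp(g)
      lf0 <- -log1p(kappa * mu) / kappa
      base$cll_d(y, g) - exp(lf0) * mu / ((1 + kappa * mu) * (-expm1(lf0)))
    }
  )
}

# binary part: y is the 0/1 indicator being modelled, g the logit of P(y = 1)
.part_binomial <- function() {
  list(
    cll = function(y, g) y * g - (pmax(g, 0) + log1p(exp(-abs(g)))),
    cll_d = function(y, g) y - plogis(g)
  )
}

.family_part <- function(family, kappa = NULL, truncated = FALSE) {
  switch(family,
    poisson = if (truncated) .part_trunc_poisson() else .part_poisson(),
    nb = if (truncated) .part_trunc_nb(kappa) else .part_nb(kappa),
    binomial = .part_binomial(),
    stop("unknown family part: ", family)
  )
}

# ---- the integral -------------------------------------------------------

# Per-block marginal log-likelihood contributions with the random intercept
# integrated out.  `cache` (an environment) carries the previous posterior
# modes across optimizer iterations so the Newton mode search warm-starts.
.agh_loglik <- function(y, eta, sigma2, part, nq = 7L, cache = NULL,
                        details = FALSE) {
  n <- length(y)
  stopifnot(length(eta) == n)
  if (sigma2 < 1e-12) {
    ll <- part$cll(y, eta)
    if (details) {
      return(list(loglik = ll, mode = numeric(n), scale = numeric(n)))
    }
    return(ll)
  }
  m <- if (!is.null(cache) && length(cache$m %||% numeric(0)) == n) {
    cache$m
  } else {
    numeric(n)
  }
  fd <- 1e-4
  d2 <- rep(-1 / sigma2, n)
  for (iter in 1:40) {
    d <- part$cll_d(y, eta + m) - m / sigma2
    d[is.nan(d)] <- 0
    d <- pmin(pmax(d, -1e8), 1e8)
    d2 <- (part$cll_d(y, eta + m + fd) - part$cll_d(y, eta + m - fd)) /
      (2 * fd) - 1 / sigma2
    d2[!is.finite(d2)] <- -1e8
    d2 <- pmin(d2, -1e-8)
    step <- d / (-d2)
    step <- pmin(pmax(step, -2), 2)  # damp far-from-mode jumps
    m <- pmin(pmax(m + step, -50), 50)
    if (max(abs(step)) < 1e-9) break
  }
  if (!is.null(cache)) cache$m <- m
  s <- 1 / sqrt(-d2)
  gh <- gauss_hermite(nq)
  sq2 <- sqrt(2)
  H <- matrix(0, n, nq)
  ldnorm <- function(t) -0.5 * log(2 * pi * sigma2) - t^2 / (2 * sigma2)
  for (k in seq_len(nq)) {
    t_k <- m + sq2 * s * gh$nodes[k]
    H[, k] <- part$cll(y, eta + t_k) + ldnorm(t_k) +
      gh$nodes[k]^2 + log(gh$weights[k])
  }
  Mx <- apply(H, 1, max)
  ll <- Mx + log(rowSums(exp(H - Mx))) + 0.5 * log(2) + log(s)
  if (details) list(loglik = ll, mode = m, scale = s) else ll
}
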