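# Simulation configuration: the "stated world" the generator emulates.
#
# Defaults are calibrated to the published summary of an inner-city blood-lead
# surveillance dataset: ~1,400 census blocks; counts of children with elevated
# blood lead (mean 0.68, variance 2.32, max 13); screening-test offsets (mean
# 31.05, variance 430.03); covariates building year (mean 1923, var 308.6),
# town taxable value (mean $58,445, var 5.67e8) and soil lead (mean 185.8 ppm,
# var 12,660) with pairwise Pearson correlations 0.35 (year, tax), -0.54
# (year, soil) and -0.33 (tax, soil).  The regression coefficients default to
# the published NB-hurdle scale; the logistic part models the logit of
# P(Y = 0), so its coefficients carry the opposite sign of a fit that models
# P(Y >= 1).

.FAMILIES <- c("poisson", "nb", "hurdle_poisson", "hurdle_nb")

.is_hurdle <- function(family) family %in% c("hurdle_poisson", "hurdle_nb")
.is_nb <- function(family) family %in% c("nb", "hurdle_nb")

#' Simulation configuration for synthetic census-block data
#'
#' Bundles every parameter of the synthetic-data generator: the true
#' regression coefficients, dispersion and random-effect variances of the
#' count-generating process, the moments and correlation structure of the
#' three covariates, the offset distribution, the lattice layout, and the
#' master seed from which all per-stage random streams are derived.
#'
#' @param n_blocks number of census blocks to generate.
#' @param grid_shape integer \code{c(rows, cols)} lattice holding the blocks;
#'   defaults to the smallest near-square grid with \code{rows * cols >=
#'   n_blocks}.
#' @param family count-generating family: \code{"poisson"}, \code{"nb"},
#'   \code{"hurdle_poisson"} or \code{"hurdle_nb"}.
#' @param beta length-4 coefficient vector (intercept, building year, log
#'   taxable value in $1000s, log soil ppm) of the count / truncated part.
#' @param alpha length-4 coefficient vector of the logistic part modelling
#'   \code{logit P(Y = 0)}; ignored for non-hurdle families.
#' @param kappa NB2 dispersion (\code{Var = mu(1 + kappa mu)}); ignored for
#'   Poisson-type families.
#' @param sigma2 variance of the count-part random intercept.
#' @param sigma2_zero variance of the logistic-part random intercept (hurdle
#'   families only).
#' @param spatial_smoothing proper-CAR dependence parameter rho in [0, 1);
#'   0 gives iid random intercepts.
#' @param covariate_means,covariate_sds raw-scale moments of (building year,
#'   taxable value in dollars, soil lead in ppm).
#' @param covariate_corr 3x3 correlation matrix of the raw covariates.
#' @param value_floor,soil_floor positive floors below which raw taxable value
#'   / soil draws are resampled, keeping the log transforms finite without a
#'   point mass.
#' @param offset_mean,offset_var target moments of the integer screening-test
#'   offsets (negative-binomial shaped, floored at 1).
#' @param seed master seed; per-stage streams are derived from it so stages
#'   can be regenerated independently.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_blocks = 1393L,
                       grid_shape = NULL,
                       family = "hurdle_nb",
                       beta = c(24.003, -0.013, -0.927, 0.288),
                       alpha = c(-25.016, 0.014, 0.787, -0.621),
                       kappa = 1.259,
                       sigma2 = 0.346,
                       sigma2_zero = 0.687,
                       spatial_smoothing = 0,
                       covariate_means = c(1923, 58445, 185.8),
                       covariate_sds = sqrt(c(308.6, 567148162, 12660)),
                       covariate_corr = matrix(c(1, 0.35, -0.54,
                                                 0.35, 1, -0.33,
                                                 -0.54, -0.33, 1), 3, 3),
                       value_floor = 1000,
                       soil_floor = 1,
                       offset_mean = 31.05,
                       offset_var = 430.03,
                       seed = 1L) {
  family <- match.arg(family, .FAMILIES)
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1)
  if (is.null(grid_shape)) {
    rows <- ceiling(sqrt(n_blocks))
    grid_shape <- c(rows, ceiling(n_blocks / rows))
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || prod(grid_shape) < n_blocks) {
    stop("`grid_shape` must be c(rows, cols) with rows * cols >= n_blocks")
  }
  stopifnot(
    length(beta) == 4L, length(alpha) == 4L,
    kappa >= 0, sigma2 >= 0, sigma2_zero >= 0,
    spatial_smoothing >= 0, spatial_smoothing < 1,
    length(covariate_means) == 3L, length(covariate_sds) == 3L,
    all(covariate_sds > 0), value_floor > 0, soil_floor > 0,
    offset_mean > 0, offset_var > 0
  )
  if (!isTRUE(all.equal(covariate_corr, t(covariate_corr))) ||
      !isTRUE(all.equal(unname(diag(covariate_corr)), rep(1, 3)))) {
    stop("`covariate_corr` must be symmetric with unit diagonal")
  }
  ev <- eigen(covariate_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("`covariate_corr` must be positive-definite")
  }
  structure(
    list(
      n_blocks = n_blocks, grid_shape = grid_shape, family = family,
      beta = as.numeric(beta), alpha = as.numeric(alpha),
      kappa = kappa, sigma2 = sigma2, sigma2_zero = sigma2_zero,
      spatial_smoothing = spatial_smoothing,
      covariate_means = as.numeric(covariate_means),
      covariate_sds = as.numeric(covariate_sds),
      covariate_corr = covariate_corr,
      value_floor = value_floor, soil_floor = soil_floor,
      offset_mean = offset_mean, offset_var = offset_var,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# deterministic per-stage sub-seed, kept under 2^31
.stage_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 65521 + 1) * 7919 + stage * 104729) %%
               2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic census-block configuration\n")
  cat(sprintf("  blocks: %d on a %d x %d lattice\n",
              x$n_blocks, x$grid_shape[1], x$grid_shape[2]))
  cat(sprintf("  family: %s  (kappa = %.3g, sigma2 = %.3g%s)\n",
              x$family, x$kappa, x$sigma2,
              if (.is_hurdle(x$family)) {
                sprintf(", sigma2_zero = %.3g", x$sigma2_zero)
              } else ""))
  cat(sprintf("  spatial smoothing rho = %.3g, seed = %d\n",
              x$spatial_smoothing, x$seed))
  invisible(x)
}
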