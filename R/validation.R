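# Model-assessment battery: jackknife leave-one-out prediction with MPE/MAE,
# frequency-binned Pearson chi-square, Moran's I, Spearman observed vs
# predicted, and the multi-model comparison table.

#' Jackknife leave-one-out predictions
#'
#' For each selected block, refits the model on the remaining \code{n - 1}
#' blocks (warm-started from the full-data fit) and predicts the held-out
#' block with the marginal (random-effects-integrated) mean -- a held-out
#' block has no estimated intercept.  A seeded random subsample of leave-outs
#' keeps desk-scale runtime; the full leave-one-out is the default.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data block table.
#' @param subsample number of leave-outs to evaluate, or \code{NULL} for all
#'   blocks.
#' @param seed seed for the subsample draw.
#' @param full_fit optional pre-computed full-data fit (avoids refitting).
#' @return data frame with \code{block_id}, \code{y}, \code{yhat} (NA where a
#'   refit failed to converge) and \code{converged}; the number of failed
#'   refits is attached as attribute \code{n_failed}.
#' @export
jackknife <- function(spec, data, subsample = NULL, seed = 1L,
                      full_fit = NULL) {
  n <- nrow(data)
  stopifnot(n >= 3)
  if (is.null(full_fit)) full_fit <- fit_count_model(spec, data)
  idx <- seq_len(n)
  if (!is.null(subsample) && subsample < n) {
    set.seed(seed)
    idx <- sort(sample.int(n, subsample))
  }
  yhat <- rep(NA_real_, length(idx))
  ok <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f_i <- tryCatch(
      fit_count_model(spec, data[-i, , drop = FALSE], start = full_fit$parts),
      error = function(e) NULL
    )
    if (!is.null(f_i) && f_i$converged) {
      yhat[k] <- predict_expected_counts(f_i, data[i, , drop = FALSE],
                                         mode = "marginal")
      ok[k] <- TRUE
    }
  }
  out <- data.frame(
    block_id = (data$block_id %||% seq_len(n))[idx],
    y = data$y[idx], yhat = yhat, converged = ok,
    stringsAsFactors = FALSE
  )
  attr(out, "n_failed") <- sum(!ok)
  if (any(!ok)) {
    message(sum(!ok), " leave-one-out refit(s) failed to converge; ",
            "excluded from MPE/MAE")
  }
  out
}

#' Mean prediction error
#'
#' Mean of the signed errors \code{y_i - yhat_i}; positive values mean
#' under-prediction on average.  Pairs with a missing prediction are dropped.
#'
#' @param y observed counts.
#' @param yhat predictions (e.g. jackknife leave-one-out).
#' @export
mpe <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ok <- is.finite(yhat)
  if (!any(ok)) stop("no finite predictions")
  mean(y[ok] - yhat[ok])
}

#' Mean absolute error
#'
#' @inheritParams mpe
#' @export
mae <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ok <- is.finite(yhat)
  if (!any(ok)) stop("no finite predictions")
  mean(abs(y[ok] - yhat[ok]))
}

#' Pearson chi-square between observed and predicted count frequencies
#'
#' By default predictions are rounded to the nearest integer and both vectors
#' are tabulated into count categories (default 0, 1, 2, 3, 4, 5+); the
#' statistic is \code{sum (O_k - P_k)^2 / P_k} over categories with positive
#' predicted frequency.  Alternatively, a matrix of model-implied category
#' probabilities (one row per block, one column per category; see
#' \code{\link{predicted_category_probs}}) can be supplied, in which case the
#' predicted frequencies are the column sums of the probabilities --- the
#' proper model-based expected frequencies, free of rounding artifacts.
#' Categories whose predicted frequency falls below \code{min_expected} are
#' merged upward into the next category.  If any observations fall where the
#' predicted frequency is zero (after merging), the statistic is infinite and
#' a warning is raised.
#'
#' @param y observed counts.
#' @param yhat predicted (possibly fractional) counts; ignored when
#'   \code{predicted_probs} is given.
#' @param breaks upper category starts; \code{0:5} tabulates 0,1,2,3,4,5+.
#'   Use \code{0:max(y)} for singleton bins over the observed range.
#' @param min_expected merge threshold for small predicted frequencies.
#' @param predicted_probs optional \code{length(y) x length(breaks)} matrix of
#'   per-block category probabilities.
#' @return list with \code{chi2}, \code{df} (categories - 1), and the merged
#'   \code{table} of observed/predicted frequencies.
#' @export
frequency_chi2 <- function(y, yhat = NULL, breaks = 0:5, min_expected = 1,
                           predicted_probs = NULL) {
  breaks <- sort(unique(as.integer(breaks)))
  cut_counts <- function(v) {
    cat <- findInterval(v, breaks)   # 0 would mean below first break
    tabulate(cat, nbins = length(breaks))
  }
  if (is.null(predicted_probs)) {
    stopifnot(!is.null(yhat))
    ok <- is.finite(yhat)
    y <- y[ok]; yhat <- yhat[ok]
    stopifnot(length(y) > 0)
    O <- cut_counts(y)
    P <- cut_counts(pmax(0, round(yhat)))
  } else {
    stopifnot(nrow(predicted_probs) == length(y),
              ncol(predicted_probs) == length(breaks))
    O <- cut_counts(y)
    P <- colSums(predicted_probs)
  }
  # merge small predicted categories upward (top bin merges downward)
  k <- 1L
  while (k < length(P)) {
    if (P[k] < min_expected) {
      P[k + 1L] <- P[k + 1L] + P[k]
      O[k + 1L] <- O[k + 1L] + O[k]
      P <- P[-k]; O <- O[-k]
      breaks <- breaks[-k]
    } else k <- k + 1L
  }
  while (length(P) > 1L && P[length(P)] < min_expected) {
    m <- length(P)
    P[m - 1L] <- P[m - 1L] + P[m]
    O[m - 1L] <- O[m - 1L] + O[m]
    P <- P[-m]; O <- O[-m]
    breaks <- breaks[-m]
  }
  if (any(P == 0 & O > 0)) {
    warning("observations in categories with zero predicted frequency; ",
            "chi-square is infinite")
    chi2 <- Inf
  } else {
    nz <- P > 0
    chi2 <- sum((O[nz] - P[nz])^2 / P[nz])
  }
  list(chi2 = chi2, df = max(1L, sum(P > 0) - 1L),
       table = data.frame(category = breaks, observed = O, predicted = P))
}

#' Model-implied count-category probabilities per block
#'
#' For each block, the fitted model's probability of landing in each count
#' category (\code{breaks} starts, last category open-ended), using the
#' conditional (empirical-Bayes) intercepts.  Feed the result to
#' \code{\link{frequency_chi2}} for a rounding-free frequency comparison.
#'
#' @param fit a \code{blockcount_fit}.
#' @param data the block table the model was fitted to.
#' @param breaks category starts, as in \code{\link{frequency_chi2}}.
#' @return a \code{nrow(data) x length(breaks)} matrix of probabilities; rows
#'   sum to 1.
#' @export
predicted_category_probs <- function(fit, data, breaks = 0:5) {
  stopifnot(inherits(fit, "blockcount_fit"))
  breaks <- sort(unique(as.integer(breaks)))
  spec <- fit$spec
  d <- .design(spec, data)
  ids <- data$block_id %||% seq_len(nrow(data))
  idx <- match(ids, fit$block_id)
  if (anyNA(idx)) stop("category probabilities need the fitted blocks")
  hurdle <- .is_hurdle(fit$family)
  kappa <- if (.is_nb(fit$family)) fit$kappa_hat else NULL
  g <- fit$ranef$gamma[idx]
  mu <- exp(drop(d$X %*% fit$beta_hat) + d$log_n + g)
  ymax <- breaks[length(breaks)]
  grid <- 0:(ymax - 1L)
  pmf <- matrix(0, nrow(data), ymax)
  for (k in seq_along(grid)) {
    yk <- grid[k]
    pmf[, k] <- if (!hurdle) {
      exp(nb_logpmf(rep(yk, nrow(data)), mu, kappa %||% 0))
    } else {
      p0 <- plogis(drop(d$X %*% fit$alpha_hat) + fit$ranef$gamma_zero[idx])
      if (yk == 0) p0 else {
        exp(log1p(-p0) + truncated_logpmf(rep(yk, nrow(data)), mu, kappa))
      }
    }
  }
  probs <- matrix(0, nrow(data), length(breaks))
  probs[, seq_along(grid)] <- pmf
  probs[, length(breaks)] <- pmax(0, 1 - rowSums(pmf))
  probs
}

#' Moran's I with normal-approximation inference
#'
#' \code{I = (n / S0) * sum_ij w_ij (v_i - vbar)(v_j - vbar) /
#' sum_i (v_i - vbar)^2}, with expectation \code{-1/(n-1)} under no spatial
#' autocorrelation and the variance of the normality assumption; the p-value
#' is two-sided.
#'
#' @param values per-block numeric vector (counts, rates or residuals).
#' @param weights a \code{spatial_weights} aligned with \code{values}.
#' @return a \code{moran_result}: \code{I}, \code{expected_I}, \code{z},
#'   \code{p_value}, \code{scheme}.
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  stopifnot(n >= 3, n == length(weights$ids))
  v <- values - mean(values)
  if (all(v == 0)) stop("Moran's I is undefined for a constant vector")
  W <- .weights_matrix(weights)
  S0 <- sum(W)
  num <- drop(crossprod(v, W %*% v))
  I <- (n / S0) * num / sum(v^2)
  EI <- -1 / (n - 1)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VarI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  z <- (I - EI) / sqrt(VarI)
  structure(
    list(I = I, expected_I = EI, var_I = VarI, z = z,
         p_value = 2 * pnorm(-abs(z)),
         scheme = if (weights$row_standardized) "row-standardized" else
           "binary"),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.5f (E[I] = %.5f), Z = %.2f, p = %.4g [%s]\n",
              x$I, x$expected_I, x$z, x$p_value, x$scheme))
  invisible(x)
}

#' Spearman correlation between observed and predicted counts
#'
#' Rank correlation with average ranks for ties.  Returns \code{NA} with a
#' warning if either vector is constant.
#'
#' @inheritParams mpe
#' @export
spearman_obs_pred <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 3)
  ok <- is.finite(yhat)
  if (sd(y[ok]) == 0 || sd(yhat[ok]) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(y[ok], yhat[ok], method = "spearman")
}

#' Fit and validate several model families side by side
#'
#' Fits every requested family, computes AIC, and (optionally) runs the
#' jackknife to obtain MPE, MAE, the frequency chi-square, and the Spearman
#' observed-vs-predicted correlation, mirroring the classical comparison
#' table for such analyses.  The AIC winner is flagged along with whether its
#' lead over the runner-up exceeds 2.
#'
#' @param data block table.
#' @param families character vector of families to fit.
#' @param random_effects fit with block random intercepts?
#' @param jackknife_subsample leave-outs per model (\code{NULL} = full LOO;
#'   \code{0} skips validation entirely).
#' @param breaks category breaks for \code{\link{frequency_chi2}}.
#' @param quadrature_points nodes for the marginal likelihood.
#' @param seed seed for the jackknife subsample.
#' @return a \code{model_comparison}: data frame \code{table} (one row per
#'   family: minus2loglik, aic, delta_aic, n_params, converged, mpe, mae,
#'   chi2, spearman_rho), list of \code{fits}, list of per-model jackknife
#'   prediction frames, and \code{best} (family with smallest AIC).
#' @export
compare_models <- function(data, families = .FAMILIES, random_effects = TRUE,
                           jackknife_subsample = 0, breaks = 0:5,
                           quadrature_points = 7L, seed = 1L) {
  stopifnot(length(families) >= 1)
  families <- match.arg(families, .FAMILIES, several.ok = TRUE)
  fits <- list()
  jack <- list()
  rows <- list()
  for (fam in families) {
    spec <- model_spec(fam, random_effects = random_effects,
                       quadrature_points = quadrature_points)
    row <- data.frame(family = fam, minus2loglik = NA_real_, aic = NA_real_,
                      n_params = NA_integer_, converged = NA,
                      mpe = NA_real_, mae = NA_real_, chi2 = NA_real_,
                      spearman_rho = NA_real_, stringsAsFactors = FALSE)
    f <- tryCatch(fit_count_model(spec, data), error = function(e) {
      warning("fit failed for family ", fam, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(f)) {
      fits[[fam]] <- f
      row$minus2loglik <- -2 * f$loglik
      row$aic <- f$aic
      row$n_params <- f$n_params
      row$converged <- f$converged
      if (is.null(jackknife_subsample) || jackknife_subsample > 0) {
        jk <- jackknife(spec, data, subsample = jackknife_subsample,
                        seed = seed, full_fit = f)
        jack[[fam]] <- jk
        ok <- jk$converged
        row$mpe <- mpe(jk$y[ok], jk$yhat[ok])
        row$mae <- mae(jk$y[ok], jk$yhat[ok])
        row$chi2 <- frequency_chi2(jk$y[ok], jk$yhat[ok],
                                   breaks = breaks)$chi2
        row$spearman_rho <- spearman_obs_pred(jk$y[ok], jk$yhat[ok])
      }
    }
    rows[[fam]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  best <- tab$family[which.min(tab$aic)]
  second <- sort(tab$aic[is.finite(tab$aic)])
  structure(
    list(table = tab, fits = fits, jackknife = jack, best = best,
         decisive = length(second) >= 2 && (second[2] - second[1]) > 2),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (smaller AIC is better)\n")
  print(x$table, digits = 5)
  cat(sprintf("best by AIC: %s%s\n", x$best,
              if (x$decisive) " (delta AIC > 2)" else ""))
  invisible(x)
}
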