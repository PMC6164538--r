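# Readers/writers for the two interchange formats (block-table CSV and GAL
# adjacency) plus the end-to-end pipeline.

.REQUIRED_COLS <- c("block_id", "y", "n_tests", "x1", "x2", "x3")

#' Read a block table from CSV
#'
#' Comma-separated, UTF-8, '.' decimal, mandatory header with at least
#' \code{block_id,y,n_tests,x1,x2,x3}.  Counts must be non-negative integers,
#' offsets at least 1 (a zero offset has no log), log-scale covariates finite,
#' and block ids unique; violations are reported with the offending row and
#' column.
#'
#' @param path CSV file path.
#' @return a validated \code{block_table}.
#' @export
read_block_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.REQUIRED_COLS, names(df))
  if (length(miss)) {
    stop("block table is missing column(s): ", paste(miss, collapse = ", "))
  }
  as_block_table(df)
}

#' Validate a data frame as a block table
#'
#' @param df data frame with the block-table columns.
#' @return the validated \code{block_table}.
#' @export
as_block_table <- function(df) {
  fail <- function(row, col, why) {
    stop(sprintf("invalid block table: row %d, column %s: %s", row, col, why))
  }
  if (anyDuplicated(df$block_id)) {
    stop("duplicated block_id: ",
         df$block_id[duplicated(df$block_id)][1])
  }
  bad <- which(!is.finite(df$y) | df$y < 0 | df$y != floor(df$y))
  if (length(bad)) fail(bad[1], "y", "counts must be non-negative integers")
  bad <- which(!is.finite(df$n_tests) | df$n_tests < 1)
  if (length(bad)) {
    fail(bad[1], "n_tests",
         "offsets must be >= 1 (the offset enters as log N_i)")
  }
  for (col in c("x1", "x2", "x3")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) fail(bad[1], col, "covariates must be finite")
  }
  df$y <- as.integer(df$y)
  df$n_tests <- as.integer(df$n_tests)
  class(df) <- c("block_table", "data.frame")
  df
}

#' Write a block table to CSV
#'
#' @param data a \code{block_table}.
#' @param path output path.
#' @export
write_block_table <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spatial weights in GAL format
#'
#' Header line \code{"0 n <name> block_id"}, then per block a line
#' \code{"<id> <degree>"} followed by a line of neighbour ids.
#'
#' @param weights a \code{spatial_weights}.
#' @param path output path.
#' @param name dataset name recorded in the header.
#' @export
write_weights_gal <- function(weights, path, name = "blockcount") {
  stopifnot(inherits(weights, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(weights$ids)
  writeLines(sprintf("0 %d %s block_id", n, name), con)
  for (i in seq_len(n)) {
    nb <- weights$neighbours[[i]]
    writeLines(sprintf("%s %d", weights$ids[i], length(nb)), con)
    writeLines(paste(weights$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read spatial weights from a GAL file
#'
#' @param path GAL file path.
#' @param ids optional block ids the weights must align to (order taken from
#'   \code{ids}); an id present in the file but absent from \code{ids} is an
#'   error naming the id.
#' @param row_standardize row-standardize the weights after reading.
#' @return a \code{spatial_weights}.
#' @export
read_weights_gal <- function(path, ids = NULL, row_standardize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[2])
  if (is.na(n)) stop("malformed GAL header: ", lines[1])
  gal_ids <- character(n)
  nb_ids <- vector("list", n)
  ln <- 2L
  for (i in seq_len(n)) {
    hd <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    gal_ids[i] <- hd[1]
    deg <- as.integer(hd[2])
    nb <- if (deg > 0) strsplit(trimws(lines[ln + 1L]), "\\s+")[[1]] else
      character(0)
    if (length(nb) != deg) {
      stop("GAL degree mismatch for id ", hd[1], ": declared ", deg,
           ", found ", length(nb))
    }
    nb_ids[[i]] <- nb
    ln <- ln + 2L
  }
  if (is.null(ids)) {
    ids <- gal_ids
  } else {
    extra <- setdiff(gal_ids, ids)
    if (length(extra)) {
      stop("GAL id not present in the block table: ", extra[1])
    }
    missing_ids <- setdiff(ids, gal_ids)
    if (length(missing_ids)) {
      stop("block id missing from the GAL file: ", missing_ids[1])
    }
  }
  ord <- match(ids, gal_ids)
  neighbours <- lapply(ord, function(i) {
    idx <- match(nb_ids[[i]], ids)
    if (anyNA(idx)) {
      stop("GAL neighbour id not present in the block table: ",
           nb_ids[[i]][which(is.na(idx))[1]])
    }
    sort(idx)
  })
  new_spatial_weights(ids, neighbours, row_standardize)
}

# stable 31-bit polynomial hash of a config, for artifact provenance
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param data path to a block-table CSV, or \code{NULL} when simulating.
#' @param weights path to a GAL file, or \code{NULL}.
#' @param simulate a \code{\link{sim_config}} to generate data from, or
#'   \code{NULL} to read \code{data}.
#' @param out_dir output directory for artifacts.
#' @param families model families to fit.
#' @param random_effects fit block random intercepts?
#' @param jackknife_subsample leave-outs per model (0 skips validation).
#' @param quadrature_points adaptive GH nodes.
#' @param breaks frequency-table category breaks.
#' @param seed master seed recorded in every artifact.
#' @param verbose log stage progress?
#' @return a \code{run_config} list.
#' @export
run_config <- function(data = NULL, weights = NULL, simulate = NULL,
                       out_dir = ".", families = .FAMILIES,
                       random_effects = TRUE, jackknife_subsample = 0,
                       quadrature_points = 7L, breaks = 0:5, seed = 1L,
                       verbose = TRUE) {
  if (is.null(simulate) && is.null(data)) {
    stop("either a data CSV or a simulation config is required")
  }
  if (!is.null(data) && !file.exists(data)) stop("no such file: ", data)
  if (!is.null(weights) && !file.exists(weights)) {
    stop("no such file: ", weights)
  }
  structure(
    list(data = data, weights = weights, simulate = simulate,
         out_dir = out_dir, families = families,
         random_effects = random_effects,
         jackknife_subsample = jackknife_subsample,
         quadrature_points = as.integer(quadrature_points),
         breaks = breaks, seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

.fit_to_list <- function(f) {
  coef_block <- function(est, se) {
    z <- est / se
    list(estimate = unname(est), se = unname(se),
         p_value = unname(2 * pnorm(-abs(z))), term = names(est))
  }
  out <- list(
    family = f$family, random_effects = f$spec$random_effects, n = f$n,
    loglik = f$loglik, minus2loglik = -2 * f$loglik, aic = f$aic,
    n_params = f$n_params,
    convergence = list(converged = f$converged,
                       gradient_norm = f$gradient_norm),
    beta = coef_block(f$beta_hat, f$beta_se)
  )
  if (!is.null(f$alpha_hat)) out$alpha <- coef_block(f$alpha_hat, f$alpha_se)
  if (!is.null(f$kappa_hat)) {
    out$kappa <- list(estimate = f$kappa_hat, se = f$kappa_se)
  }
  if (!is.null(f$sigma2_hat)) {
    out$sigma2 <- list(estimate = f$sigma2_hat, se = f$sigma2_se)
  }
  if (!is.null(f$sigma2_zero_hat)) {
    out$sigma2_zero <- list(estimate = f$sigma2_zero_hat,
                            se = f$sigma2_zero_se)
  }
  out
}

#' Run the simulate -> fit -> validate pipeline
#'
#' Generates or loads a block table (and optional spatial weights), fits the
#' requested families, optionally jackknifes them, computes Moran's I on the
#' observed counts and on each model's conditional residuals when weights are
#' available, and writes all artifacts (data CSV/GAL when simulated, one fit
#' JSON per family, \code{report.json}, frequency tables) into
#' \code{out_dir}.  Every artifact embeds the package version, the config
#' hash, and the master seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return (invisibly) the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  weights <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    log_msg("simulating %d blocks from family %s", sim$n_blocks, sim$family)
    weights <- build_lattice_weights(sim$grid_shape, n_keep = sim$n_blocks)
    data <- simulate_block_data(sim, weights)
    write_block_table(data, file.path(config$out_dir, "data.csv"))
    write_weights_gal(weights, file.path(config$out_dir, "data.gal"))
  } else {
    data <- read_block_table(config$data)
    log_msg("read %d blocks (%.1f%% zeros) from %s", nrow(data),
            100 * mean(data$y == 0), config$data)
    if (!is.null(config$weights)) {
      weights <- read_weights_gal(config$weights, ids = data$block_id)
    }
  }
  t0 <- proc.time()[["elapsed"]]
  cmp <- compare_models(
    data, families = config$families,
    random_effects = config$random_effects,
    jackknife_subsample = config$jackknife_subsample,
    breaks = config$breaks,
    quadrature_points = config$quadrature_points,
    seed = config$seed
  )
  log_msg("fitted %d families in %.1fs; best by AIC: %s",
          length(cmp$fits), proc.time()[["elapsed"]] - t0, cmp$best)
  moran <- NULL
  if (!is.null(weights)) {
    moran <- list(observed = unclass(morans_i(data$y, weights)))
    for (fam in names(cmp$fits)) {
      res <- data$y - predict_expected_counts(cmp$fits[[fam]], data,
                                              mode = "conditional")
      moran[[paste0("residuals_", fam)]] <- unclass(morans_i(res, weights))
    }
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("blockcount")),
    seed = config$seed,
    config_hash = .config_hash(config[setdiff(names(config), "verbose")])
  )
  for (fam in names(cmp$fits)) {
    out <- c(list(meta = meta), .fit_to_list(cmp$fits[[fam]]))
    jsonlite::write_json(out, file.path(config$out_dir,
                                        paste0("fit_", fam, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  for (fam in names(cmp$jackknife)) {
    jk <- cmp$jackknife[[fam]]
    ok <- jk$converged
    ft <- frequency_chi2(jk$y[ok], jk$yhat[ok], breaks = config$breaks)$table
    write.csv(ft, file.path(config$out_dir,
                            paste0("frequency_", fam, ".csv")),
              row.names = FALSE)
  }
  report <- list(meta = meta, comparison = cmp$table, best = cmp$best,
                 decisive = cmp$decisive, moran = moran)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("report written to %s", file.path(config$out_dir, "report.json"))
  invisible(report)
}
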