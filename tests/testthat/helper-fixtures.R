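# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- make_paper_like_dataset()
  }
  .fixture_cache$fx
}

# a small hand-made block table for exact-arithmetic tests
toy_blocks <- function(y = c(3L, 0L, 1L), n_tests = c(2L, 4L, 1L)) {
  as_block_table(data.frame(
    block_id = paste0("t", seq_along(y)),
    y = y, n_tests = n_tests,
    x1 = 0, x2 = 0, x3 = 0
  ))
}

# covariate-free table of constant linear predictor, for simulate_counts tests
flat_covariates <- function(n, n_tests = 1L) {
  out <- data.frame(
    block_id = sprintf("f%06d", seq_len(n)),
    n_tests = as.integer(n_tests),
    x1 = 0, x2 = 0, x3 = 0
  )
  class(out) <- c("block_table", "data.frame")
  out
}
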