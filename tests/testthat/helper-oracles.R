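# Naive double-loop pixel oracles, deliberately independent of the
# vectorized implementations they check.

oracle_count <- function(mask) {
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) n <- n + 1L
    }
  }
  n
}

oracle_percent_area <- function(mask) {
  100 * oracle_count(mask) / (nrow(mask) * ncol(mask))
}

oracle_and_count <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) n <- n + 1L
    }
  }
  n
}

oracle_union <- function(masks) {
  out <- matrix(FALSE, nrow(masks[[1]]), ncol(masks[[1]]))
  for (m in masks) {
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(ncol(out))) {
        if (m[i, j]) out[i, j] <- TRUE
      }
    }
  }
  out
}

random_mask <- function(nr, nc, p = 0.3) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# tolerance honoring a printed value's own precision: max of rel_tol and
# half a unit in the last printed digit
expect_printed <- function(value, printed, digits, rel_tol = 0.01) {
  tol <- max(rel_tol * abs(printed), 0.5 * 10^(-digits))
  expect_lt(abs(value - printed), tol + 1e-12)
}
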