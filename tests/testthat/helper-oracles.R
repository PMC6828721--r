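# Independent brute-force oracles used across test files.

# two-pass mean / sample-sd, written without stats::sd on purpose
oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}

# Pearson correlation from raw sums (independent of stats::cor)
oracle_cor <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# build a small wide CSV fixture on disk and return its path
make_wide_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(rows, path)
  path
}
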