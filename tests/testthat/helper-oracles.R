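# Independent oracles used to check the package's fast implementations.

# direct double-loop convolution (independent of convolve_shifts)
conv_oracle <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

# brute-force isotopologue envelope: enumerate every atom-isotope assignment
# of a small formula and accumulate abundance by total mass shift
natural_dist_oracle <- function(formula, table, n_shifts) {
  f <- tracemet::as_chem_formula(formula)
  atoms <- rep(names(f), unclass(f))
  choices <- lapply(atoms, function(el) seq_along(table[[el]]) - 1L)
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  out <- numeric(n_shifts + 1L)
  for (r in seq_len(nrow(grid))) {
    shifts <- as.integer(grid[r, ])
    p <- prod(vapply(seq_along(atoms), function(i) {
      table[[atoms[i]]][shifts[i] + 1L]
    }, numeric(1)))
    s <- sum(shifts)
    if (s <= n_shifts) out[s + 1L] <- out[s + 1L] + p
  }
  out
}

# random valid MID over m+0..m+n under a fixed RNG state
random_mid <- function(n) {
  x <- stats::runif(n + 1L)
  x / sum(x)
}

# two-sided permutation p-value for a difference in means
perm_test_oracle <- function(a, b, n_perm = 20000) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
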