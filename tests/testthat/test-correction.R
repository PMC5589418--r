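mono_table <- isotope_table(
  list(C = 1, H = 1, N = 1, O = 1, Si = 1, S = 1),
  source = "mono-isotopic (synthetic)"
)

test_that("one-carbon correction matrix matches the hand-built form", {
  frag <- fragment_def("x", "C1", 1, n_measured_shifts = 1)
  M <- unclass(build_correction_matrix(frag))
  expect_equal(M, matrix(c(0.9893, 0.0107, 0, 1), 2, 2),
               ignore_attr = TRUE)
})

test_that("mono-isotopic abundances give an identity correction matrix", {
  for (frag in default_fragment_library()) {
    M <- unclass(build_correction_matrix(frag, table = mono_table))
    nb <- frag$n_backbone_carbons
    expect_equal(M[1:(nb + 1), ], diag(nb + 1), ignore_attr = TRUE,
                 label = frag$metabolite)
  }
})

test_that("matrix columns are shifted envelopes of the carbon-depleted pool", {
  tab <- default_isotope_table()
  frag <- fragment_def("x", "C3H2", 2, n_measured_shifts = 4)
  M <- unclass(build_correction_matrix(frag, tab))
  # column 1 (one tracer carbon): C2H2 natural envelope shifted by 1
  env <- natural_dist_oracle("C2H2", tab, 3)
  expect_equal(M[, 2], c(0, env), tolerance = 1e-12)
  # columns are probability envelopes: non-negative, sum at most 1
  expect_true(all(M >= 0))
  expect_true(all(colSums(M) <= 1 + 1e-12))
})

test_that("correction inverts the forward model exactly without noise", {
  frag <- fragment_def("x", "C1", 1, n_measured_shifts = 1)
  M <- build_correction_matrix(frag)
  raw <- as.numeric(unclass(M) %*% c(0.5, 0.5))
  expect_equal(raw, c(0.49465, 0.50535))
  expect_equal(as.numeric(correct_mid(raw, M)), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("an unlabeled fragment corrects to pure m+0", {
  for (frag in default_fragment_library()) {
    M <- build_correction_matrix(frag)
    raw <- unclass(M)[, 1]  # natural envelope of unlabeled material
    x <- as.numeric(correct_mid(raw, M))
    expect_equal(x, c(1, rep(0, frag$n_backbone_carbons)), tolerance = 1e-8,
                 label = frag$metabolite)
  }
})

test_that("round trip recovers random true MIDs for every library fragment", {
  set.seed(11)
  worst <- 0
  for (frag in default_fragment_library()) {
    M <- build_correction_matrix(frag)
    for (i in 1:100) {
      x <- random_mid(frag$n_backbone_carbons)
      raw <- as.numeric(unclass(M) %*% x)
      xhat <- as.numeric(correct_mid(raw, M))
      worst <- max(worst, max(abs(xhat - x)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("corrected output is a valid MID even for noisy input", {
  set.seed(3)
  frag <- default_fragment_library()[["glutamate"]]
  M <- build_correction_matrix(frag)
  for (i in 1:20) {
    x <- random_mid(frag$n_backbone_carbons)
    raw <- as.numeric(unclass(M) %*% x) * exp(rnorm(nrow(M), 0, 0.1))
    out <- as.numeric(correct_mid(raw, M))
    expect_true(all(out >= 0))
    expect_equal(sum(out), 1, tolerance = 1e-9)
  }
})

test_that("raising the true top-shift fraction raises its estimate", {
  frag <- default_fragment_library()[["glutamate"]]
  M <- build_correction_matrix(frag)
  top <- frag$n_backbone_carbons + 1L
  est <- vapply(seq(0, 0.9, by = 0.1), function(f) {
    x <- numeric(top); x[1] <- 1 - f; x[top] <- f
    as.numeric(correct_mid(as.numeric(unclass(M) %*% x), M))[top]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("correction rejects degenerate input", {
  frag <- fragment_def("x", "C1", 1, n_measured_shifts = 1)
  M <- build_correction_matrix(frag)
  expect_error(correct_mid(c(0, 0), M), "all-zero")
  expect_error(correct_mid(c(1, 0, 0), M), "length")
  expect_error(correct_mid(c(-1, 2), M), "non-negative")
})

test_that("tracer impurity is folded into the forward model columns", {
  frag <- fragment_def("x", "C1", 1, n_measured_shifts = 1, fragment_name = "f")
  M99 <- unclass(build_correction_matrix(frag, purity = 0.99))
  # fully 'labeled' column is now 1% pure 12C at m+0
  expect_equal(M99[, 2], c(0.01, 0.99))
  expect_error(build_correction_matrix(frag, purity = 0), "purity")
})

test_that("table-level correction reproduces per-fragment correction", {
  frag <- default_fragment_library()[["fumarate"]]
  M <- build_correction_matrix(frag)
  x <- c(0.3, 0.1, 0.1, 0.1, 0.4)
  raw <- as.numeric(unclass(M) %*% x)
  tab <- data.frame(sample_id = "s1", condition = "c", metabolite = "fumarate",
                    fragment_name = frag$fragment_name,
                    mass_shift = seq_along(raw) - 1L, value = raw)
  out <- correct_mid_table(tab)
  expect_equal(out$value, x, tolerance = 1e-8)
  expect_equal(out$mass_shift, 0:4)
  tab$metabolite <- "unknownium"
  expect_error(correct_mid_table(tab), "unknownium")
})
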