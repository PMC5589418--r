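test_that("fractional labeling reads the requested mass shift", {
  m <- mid(c(0.67, 0, 0, 0, 0, 0.33))
  expect_equal(fractional_labeling(m, 5), 0.33)
  expect_equal(fractional_labeling(mid(c(1, 0, 0, 0, 0, 0)), 5), 0)
  expect_equal(fractional_labeling(mid(c(0.4, 0.1, 0.1, 0.1, 0.1, 0.2)), 0), 0.4)
  expect_error(fractional_labeling(m, 6), "outside")
})

test_that("normalized contribution reproduces the worked glutamate example", {
  glu <- mid(c(0.73, 0, 0, 0, 0, 0.27))
  gln <- mid(c(0.67, 0, 0, 0, 0, 0.33))
  contrib <- normalized_contribution(glu, 5, gln, 5)
  expect_equal(contrib, 0.27 / 0.33, tolerance = 1e-12)
  # ~80% at reporting precision
  expect_equal(contrib, 0.8, tolerance = 0.025)
})

test_that("normalized contribution handles boundary cases", {
  gln <- mid(c(0.67, 0, 0, 0, 0, 0.33))
  expect_equal(normalized_contribution(gln, 5, gln, 5), 1)
  expect_equal(normalized_contribution(mid(c(1, 0, 0, 0, 0, 0)), 5, gln, 5), 0)
  expect_error(normalized_contribution(gln, 5, mid(c(1, 0, 0, 0, 0, 0)), 5),
               "undefined")
})

test_that("normalized contribution is scale-free in the labeled fractions", {
  for (k in c(0.5, 0.8, 1.5)) {
    a <- mid(c(1 - 0.2 * k, 0, 0, 0, 0, 0.2 * k))
    b <- mid(c(1 - 0.33 * k, 0, 0, 0, 0, 0.33 * k))
    expect_equal(normalized_contribution(a, 5, b, 5), 0.2 / 0.33,
                 tolerance = 1e-12)
  }
})

make_summary <- function(high_vals, low_vals, high = "hi", low = "lo") {
  # corrected table with aKG at the given contributions, gln enrichment 0.33
  rows <- list()
  add <- function(cond, vals) {
    for (i in seq_along(vals)) {
      sid <- paste0(cond, "_r", i)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, condition = cond, metabolite = "glutamine",
        fragment_name = "g", mass_shift = 0:5,
        value = c(0.67, 0, 0, 0, 0, 0.33))
      akg <- 0.33 * vals[i]
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, condition = cond,
        metabolite = "alpha-ketoglutarate", fragment_name = "a",
        mass_shift = 0:5, value = c(1 - akg, 0, 0, 0, 0, akg))
    }
  }
  add(high, high_vals)
  add(low, low_vals)
  condition_summary(do.call(rbind, rows))
}

test_that("condition contrast equals the difference of mean contributions", {
  s <- make_summary(c(0.6, 0.6, 0.6), c(0.2, 0.2, 0.2))
  cmp <- cystine_induced_increase(s, high = "hi", low = "lo")
  expect_equal(cmp$statistic, 0.4, tolerance = 1e-9)
  null <- make_summary(c(0.4, 0.5), c(0.4, 0.5))
  expect_equal(cystine_induced_increase(null, "hi", "lo")$statistic, 0,
               tolerance = 1e-9)
})

test_that("condition contrast is antisymmetric and names missing inputs", {
  s <- make_summary(c(0.55, 0.62, 0.58), c(0.21, 0.25, 0.28))
  a <- cystine_induced_increase(s, high = "hi", low = "lo")
  b <- cystine_induced_increase(s, high = "lo", low = "hi")
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_error(cystine_induced_increase(s, "hi", "lo", metabolite = "citrate"),
               "citrate")
})

test_that("contrast recovers the generator's ground-truth difference", {
  reps <- 10L
  hi <- simulate_labeling(
    condition_preset("serum_cystine", seed = 21,
                     fractions = c(glutamate = 0.7,
                                   "alpha-ketoglutarate" = 0.7)),
    n_replicates = reps)
  lo <- simulate_labeling(
    condition_preset("serum", seed = 22,
                     fractions = c(glutamate = 0.3,
                                   "alpha-ketoglutarate" = 0.3)),
    n_replicates = reps)
  corrected <- rbind(correct_mid_table(hi$raw), correct_mid_table(lo$raw))
  cmp <- cystine_induced_increase(condition_summary(corrected),
                                  high = "serum_cystine", low = "serum")
  sem <- sqrt(stats::var(cmp$contributions_high) / reps +
                stats::var(cmp$contributions_low) / reps)
  expect_lt(abs(cmp$statistic - 0.4), 2 * sem + 1e-3)
})

test_that("steady-state detection follows successive relative changes", {
  r <- steady_state_check(c(0, 2, 4, 8), c(0.30, 0.31, 0.305, 0.31),
                          rel_tol = 0.05)
  expect_true(r$steady)
  expect_identical(r$index, 2L)
  expect_equal(r$time, 2)
  const <- steady_state_check(1:4, rep(0.3, 4))
  expect_true(const$steady)
  expect_identical(const$index, 1L)
  dbl <- steady_state_check(1:4, c(0.1, 0.2, 0.4, 0.8), rel_tol = 0.05)
  expect_false(dbl$steady)
  expect_error(steady_state_check(1, 0.3), "two time points")
  expect_error(steady_state_check(c(1, 1), c(0.3, 0.3)), "increasing")
})

test_that("kinetic labeling from the generator reaches steady state", {
  spec <- condition_preset("serum", seed = 5, cv_intensity = 0)
  times <- c(1, 2, 4, 8, 24)
  sim <- simulate_labeling(spec, timepoints_hr = times, n_replicates = 1)
  corrected <- correct_mid_table(sim$raw)
  gln <- corrected[corrected$metabolite == "glutamine" &
                     corrected$mass_shift == 5, ]
  gln <- gln[order(sim$raw$time_hr[match(gln$sample_id, sim$raw$sample_id)]), ]
  r <- steady_state_check(times, gln$value, rel_tol = 0.05)
  expect_true(r$steady)
  expect_lte(r$time, 8)  # steady within 8 hours of culture
})

test_that("t-test matches the closed-form pooled-variance example", {
  tt <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, (2 - 5) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt((2 - 5) / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0213, tolerance = 1e-3)
})

test_that("t-test symmetry and degenerate conventions hold", {
  a <- c(0.1, 0.5, 0.3); b <- c(0.7, 0.9, 0.6)
  expect_equal(unpaired_t_test(a, b)$statistic,
               -unpaired_t_test(b, a)$statistic)
  expect_equal(unpaired_t_test(a, b)$p_value, unpaired_t_test(b, a)$p_value)
  same <- unpaired_t_test(c(1, 1), c(1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least two")
})

test_that("t-test p-value agrees with a permutation test on small samples", {
  set.seed(99)
  a <- rnorm(5, 0, 1)
  b <- rnorm(5, 1, 1)
  p_t <- unpaired_t_test(a, b)$p_value
  p_perm <- perm_test_oracle(a, b)
  expect_lt(abs(p_t - p_perm), 0.05)
})
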