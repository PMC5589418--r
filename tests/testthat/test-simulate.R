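test_that("generators are deterministic given spec and seed", {
  spec <- condition_preset("rpmi", seed = 77)
  a <- simulate_labeling(spec, n_replicates = 2)
  b <- simulate_labeling(spec, n_replicates = 2)
  expect_identical(a, b)
  expect_identical(simulate_growth(spec), simulate_growth(spec))
  expect_identical(simulate_media_exchange(spec),
                   simulate_media_exchange(spec))
  # different seeds give different noise
  spec2 <- condition_preset("rpmi", seed = 78)
  expect_false(identical(simulate_labeling(spec2, n_replicates = 2)$raw$value,
                         a$raw$value))
})

test_that("raw intensities are non-negative and true MIDs are conserved", {
  spec <- condition_preset("serum_cystine", seed = 13)
  sim <- simulate_labeling(spec)
  expect_true(all(sim$raw$value >= 0))
  expect_true(all(sim$truth$true_labeled_fraction >= 0 &
                    sim$truth$true_labeled_fraction <= 1))
})

test_that("noiseless steady-state labeling inverts through the pipeline", {
  spec <- condition_preset("rpmi", seed = 1, cv_intensity = 0)
  sim <- simulate_labeling(spec, n_replicates = 1)
  s <- condition_summary(correct_mid_table(sim$raw))
  truth <- spec$fractions
  for (met in setdiff(names(truth), "glutamine")) {
    est <- s$mean_contribution[s$metabolite == met]
    expect_equal(est, unname(truth[[met]]), tolerance = 1e-6, label = met)
  }
  # the worked steady-state numbers: g = 0.8, e = 0.33 gives m+5 = 0.264
  glu <- s[s$metabolite == "glutamate", ]
  expect_equal(glu$mean_labeling, 0.8 * 0.33, tolerance = 1e-6)
  expect_equal(glu$mean_contribution, 0.8, tolerance = 1e-6)
})

test_that("noisy labeling recovers ground truth within 2 SEM", {
  spec <- condition_preset("serum", seed = 19)  # CV 5%
  sim <- simulate_labeling(spec, n_replicates = 10)
  s <- condition_summary(correct_mid_table(sim$raw))
  reps <- attr(s, "replicates")
  for (met in c("glutamate", "alpha-ketoglutarate", "malate")) {
    v <- reps$contribution[reps$metabolite == met]
    sem <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - spec$fractions[[met]]), 2 * sem + 0.01)
  }
})

test_that("zero tracer-derived fractions leave metabolites unlabeled", {
  spec <- condition_preset("serum", seed = 23, cv_intensity = 0,
                           fractions = c(glutamine = 1, glutamate = 0,
                                         malate = 0))
  sim <- simulate_labeling(spec, n_replicates = 1)
  corrected <- correct_mid_table(sim$raw)
  for (met in c("glutamate", "malate")) {
    v <- corrected$value[corrected$metabolite == met]
    expect_equal(v[1], 1, tolerance = 1e-8, label = met)
    expect_equal(sum(v[-1]), 0, tolerance = 1e-8, label = met)
  }
})

test_that("kinetic mode halves the labeling at t = tau * ln 2", {
  spec <- condition_preset("serum", seed = 29, cv_intensity = 0)
  tau <- spec$tau_hours[["glutamate"]]
  sim <- simulate_labeling(spec, timepoints_hr = c(tau * log(2), 1e6),
                           n_replicates = 1)
  tr <- sim$truth[sim$truth$metabolite == "glutamate", ]
  half <- tr$true_labeled_fraction[tr$time_hr == tau * log(2)]
  full <- tr$true_labeled_fraction[tr$time_hr == 1e6]
  expect_equal(half, full / 2, tolerance = 1e-9)
})

test_that("growth generator inverts through the exponential fit", {
  spec <- condition_preset("serum", seed = 3, cv_counts = 0)
  sim <- simulate_growth(spec, days = 0:8)
  fit <- fit_exponential_growth(sim$growth$time_days, sim$growth$cell_count)
  expect_equal(fit$rate, spec$growth_rate, tolerance = 1e-9)
  expect_equal(fit$doubling_time_hours, 48, tolerance = 1e-6)
})

test_that("growth rate estimation is nearly unbiased over many curves", {
  spec <- condition_preset("serum", seed = 47)  # count CV 10%
  rates <- numeric(200)
  for (i in seq_len(200)) {
    s <- condition_preset("serum", seed = 1000L + i)
    sim <- simulate_growth(s, days = 0:8)
    rates[i] <- fit_exponential_growth(sim$growth$time_days,
                                       sim$growth$cell_count)$rate
  }
  expect_lt(abs(mean(rates) - spec$growth_rate) / spec$growth_rate, 0.01)
})

test_that("media exchange respects flux signs and floors at depletion", {
  spec <- condition_preset("rpmi", seed = 53)
  sim <- simulate_media_exchange(spec)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    rows <- sim$exchanges$metabolite == truth$metabolite[i]
    d <- sim$exchanges$conc_final_uM[rows] - sim$exchanges$conc_initial_uM[rows]
    expect_true(all(sign(d) == sign(truth$flux_fmol_per_cell_per_day[i])),
                label = truth$metabolite[i])
  }
  # a flux large enough to exhaust the pool warns and clips at zero
  poor <- condition_preset("serum", seed = 54,
                           media_conc = c(glutamine = 1),
                           fluxes = c(glutamine = -5000))
  expect_warning(out <- simulate_media_exchange(poor, n_replicates = 1),
                 "exhaustion")
  expect_true(all(out$exchanges$conc_final_uM >= 0))
})

test_that("preset ordering matches the biology: rpmi > serum contributions", {
  akg_contrib <- function(preset, seed) {
    spec <- condition_preset(preset, seed = seed)
    s <- condition_summary(correct_mid_table(simulate_labeling(spec)$raw))
    s$mean_contribution[s$metabolite == "alpha-ketoglutarate"]
  }
  n_runs <- 20L
  for (i in seq_len(n_runs)) {
    expect_gt(akg_contrib("rpmi", 200L + i), akg_contrib("serum", 300L + i))
  }
})
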