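test_that("generation is bitwise reproducible for identical spec and seed", {
  s1 <- synthetic_spec(seed = 11)
  s2 <- synthetic_spec(seed = 11)
  d1 <- gen_spectrum_effect(s1)
  d2 <- gen_spectrum_effect(s2)
  expect_identical(d1$matrix$areas, d2$matrix$areas)
  expect_identical(d1$effects_raw, d2$effects_raw)
  expect_identical(d1$truth$active_sets, d2$truth$active_sets)
  d3 <- gen_spectrum_effect(synthetic_spec(seed = 12))
  expect_false(identical(d1$matrix$areas, d3$matrix$areas))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(synthetic_spec(n_batches = 2), "n_batches")
  expect_error(synthetic_spec(n_peaks = 0), "n_peaks")
  expect_error(synthetic_spec(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_spec(active_sets = list(dpph = c(1, 80)),
                              n_peaks = 70), "active_sets")
  expect_error(synthetic_spec(active_sets = list(nosuch = 1:3)),
               "active_sets")
})

test_that("zero-noise linear link reproduces the stated combination exactly", {
  d <- tiny_dataset(seed = 4, n_peaks = 8, active = c(2, 5, 7), noise = 0)
  # frap family: raw = enc_a * L + enc_b with L the documented weighted sum
  # of expected-mean-normalised planted areas
  A <- d$matrix$areas
  act <- d$truth$active_index$frap
  # reconstruct L from the returned truth
  L <- d$truth$latent_activity$frap
  expect_equal(unname(d$effects_raw$frap), unname(55 * L + 100),
               tolerance = 1e-12)
  # activity table carries the identity transform for frap
  expect_equal(d$effects$activity$frap, d$effects_raw$frap)
  # L is exactly a positive linear combination of the planted areas alone
  fit <- lm(L ~ 0 + A[, act])
  expect_lt(max(abs(resid(fit))), 1e-9)
  expect_true(all(coef(fit) > 0))
})

test_that("areas are strictly positive and orientation metadata round-trips", {
  d <- gen_spectrum_effect(synthetic_spec(seed = 3))
  expect_true(all(d$matrix$areas > 0))
  meta <- d$effects$meta
  expect_setequal(meta$endpoint, default_endpoints()$endpoint)
  # decreasing-better endpoints must have activity anti-monotone in raw
  for (e in meta$endpoint[!meta$larger_raw_more_active]) {
    expect_equal(order(d$effects$activity[[e]]),
                 rev(order(d$effects_raw[[e]])))
  }
  for (e in meta$endpoint[meta$larger_raw_more_active]) {
    expect_equal(order(d$effects$activity[[e]]),
                 order(d$effects_raw[[e]]))
  }
})

test_that("IS peak is near-constant and never planted", {
  d <- gen_spectrum_effect(synthetic_spec(seed = 8))
  is_peak <- d$matrix$is_peak
  expect_false(is_peak %in% unlist(d$truth$active_sets))
  rsd <- dispersion_stats(d$matrix$areas[, is_peak])
  expect_lt(rsd, 5)
})

test_that("calibration tables are exactly linear except for failing peaks", {
  d <- gen_spectrum_effect(synthetic_spec(seed = 5))
  cal <- gen_calibration(d$matrix)
  rep0 <- linearity_screen(cal)
  expect_length(rep0$dropped, 0)
  expect_true(all(abs(rep0$stats$r_squared - 1) < 1e-12))
  expect_equal(sort(unique(cal$dilution)), c(2, 4, 8, 16, 32, 64))

  fail <- paste0("P", c(3, 11, 27, 31, 33, 40, 41, 45, 53, 57, 69))
  cal2 <- gen_calibration(d$matrix, failing_peaks = fail)
  rep2 <- linearity_screen(cal2)
  expect_setequal(rep2$dropped, fail)
  expect_length(rep2$retained, 59)
  expect_true(all(rep2$stats$r_squared[match(fail, rep2$stats$peak)] < 0.99))
  expect_error(gen_calibration(d$matrix, dilution_factors = numeric()),
               "dilution")
})

test_that("dose-response generator hits the 4PL midpoint at the IC50", {
  dr <- gen_dose_response(ic50 = 2.5, hill = 1.3, floor = 5, ceiling = 95)
  at_mid <- dr$response[dr$concentration == 2.5]
  expect_equal(at_mid, (5 + 95) / 2, tolerance = 1e-12)
  expect_error(gen_dose_response(ic50 = -1), "ic50")
  expect_error(gen_dose_response(ic50 = 1, concentrations = c(1, 2, 3)),
               "concentrations")
})

test_that("recovery metrics implement precision/recall set arithmetic", {
  d <- tiny_dataset(seed = 2, n_peaks = 10, active = c(3, 4, 5, 6))
  planted <- d$truth$active_sets$frap
  exact <- recovery_metrics(planted, d$truth, "frap")
  expect_equal(exact$recall, 1)
  expect_equal(exact$precision, 1)

  none <- recovery_metrics(setdiff(paste0("P", 1:10), planted),
                           d$truth, "frap")
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)

  empty <- recovery_metrics(character(), d$truth, "frap")
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)

  expect_error(recovery_metrics("P1", d$truth, "nosuch"), "endpoint")
})

test_that("half-overlapping selection gives recall 0.5 and precision 0.5", {
  d <- tiny_dataset(seed = 2, n_peaks = 10, active = c(3, 4, 5, 6))
  m <- recovery_metrics(paste0("P", 1:4), d$truth, "frap")
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 0.5)
})
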