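test_that("threshold crossing interpolates the exact analytic time", {
  # linear decay 1 -> 0 over 100 h sampled hourly: 0.6 crossed at 40 h
  t <- 0:100
  tr <- tiny_trace(t, 1 - t / 100)
  expect_equal(time_to_threshold(tr, "impedance", window = c(0, 100)), 40)
  # constant trace never crosses
  expect_true(is.na(time_to_threshold(tiny_trace(0:10, rep(1, 11)))))
  expect_error(time_to_threshold(tr, window = c(5, 5)),
               class = "actinospec_domain_error")
})

test_that("threshold crossing agrees with a dense-grid scan oracle", {
  set.seed(21)
  interval <- 11 / 60
  for (i in 1:50) {
    t <- seq(0, 60, by = interval)
    v <- 1 - cumsum(runif(length(t), 0, 0.01))   # random monotone decline
    v[1] <- 1
    tr <- tiny_trace(t, v)
    est <- time_to_threshold(tr, "impedance", window = c(0, 60))
    fine_t <- seq(0, 60, by = 1e-3)
    fine_v <- approx(t, v, xout = fine_t)$y
    j <- which(fine_v <= 0.6)[1]
    oracle <- if (is.na(j)) NA_real_ else fine_t[j]
    if (is.na(oracle)) {
      expect_true(is.na(est))
    } else {
      expect_lt(abs(est - oracle), interval)
    }
  }
})

test_that("a pointwise-lower trace crosses no later (monotone consistency)", {
  set.seed(22)
  t <- seq(0, 60, by = 11 / 60)
  for (i in 1:20) {
    a <- 1 - cumsum(runif(length(t), 0, 0.01)); a[1] <- 1
    gap <- cumsum(runif(length(t), 0, 0.002)); gap[1] <- 0
    b <- pmin(a + gap, 1)                       # b >= a pointwise, same start
    ta <- time_to_threshold(tiny_trace(t, a), window = c(0, 60))
    tb <- time_to_threshold(tiny_trace(t, b), window = c(0, 60))
    if (!is.na(ta) && !is.na(tb)) expect_lte(ta, tb)
    if (is.na(ta)) expect_true(is.na(tb))
  }
})

test_that("lamp-off truncation removes the recovery rise only", {
  t <- seq(0, 72, by = 1)
  tr <- tiny_trace(t, pmax(1 - 0.02 * t, 0.1) + ifelse(t > 68, 0.5, 0))
  cut <- truncate_at_lamp_off(tr, 68)
  expect_lte(max(cut$time_h), 68)
  short <- tiny_trace(0:60, rep(1, 61))
  expect_equal(nrow(truncate_at_lamp_off(short, 68)), 61)
  # a crossing before lamp-off is still detected although the trace
  # recovers above threshold afterwards
  v <- c(seq(1, 0.55, length.out = 60), rep(0.9, 13))
  rec <- tiny_trace(t, v)
  expect_false(is.na(time_to_threshold(rec, window = c(0, 68))))
})

test_that("per-well efficiencies are reciprocal doses, averaged per band", {
  t <- seq(0, 68, by = 11 / 60)
  mk <- function(well, cross) tibble::as_tibble(tiny_trace(
    t, pmax(1 - 0.4 * t / cross, 0.05), well = well))
  traces <- ecis_traces(dplyr::bind_rows(mk("A01", 20), mk("A02", 40)),
                        raw = FALSE)
  pm <- plate_map(c("A01", "A02"), "exposed", wavelength_nm = 350)
  doses <- tibble::tibble(well = c("A01", "A02"), irradiance_w_m2 = 2)
  sp <- build_action_spectrum(traces, pm, doses, reference_nm = 350)
  d20 <- dose_at(2, 20); d40 <- dose_at(2, 40)
  expect_equal(sp$efficiency, (1 / d20 + 1 / d40) / 2, tolerance = 1e-9)
  expect_equal(sp$n_wells, 2L)
  expect_equal(sp$n_censored, 0L)
  # halving the irradiance at identical crossing times doubles efficiency
  sp2 <- build_action_spectrum(traces, pm,
                               dplyr::mutate(doses, irradiance_w_m2 = 1),
                               reference_nm = 350)
  expect_equal(sp2$efficiency, sp$efficiency * 2, tolerance = 1e-9)
})

test_that("all-censored wavelengths report censoring, not efficiency", {
  t <- seq(0, 68, by = 0.5)
  traces <- ecis_traces(dplyr::bind_rows(
    tibble::as_tibble(tiny_trace(t, rep(1, length(t)), well = "A01")),
    tibble::as_tibble(tiny_trace(t, pmax(1 - 0.02 * t, 0.05), well = "A02"))),
    raw = FALSE)
  pm <- plate_map(c("A01", "A02"), "exposed", wavelength_nm = c(370, 400))
  doses <- tibble::tibble(well = c("A01", "A02"), irradiance_w_m2 = 5)
  sp <- build_action_spectrum(traces, pm, doses, reference_nm = 400)
  expect_true(is.na(sp$efficiency[sp$wavelength_nm == 370]))
  expect_equal(sp$n_censored[sp$wavelength_nm == 370], 1L)
  expect_equal(sp$normalised_efficiency[sp$wavelength_nm == 400], 1)
})

test_that("noiseless synthetic traces invert to the planted crossings", {
  pr <- preset("paper-profile")
  sim <- gen_ecis_traces(pr, noise_sd = 0, seed = 5)
  sp <- ecis_spectrum_pipeline(sim$traces, sim$map, sim$doses)
  pw <- attr(sp, "per_well")
  planted <- sim$truth$ecis_cross_h[
    match(pw$wavelength_nm, sim$truth$wavelength_nm)]
  expect_true(all(abs(pw$time_to_action_h - planted) < 11 / 60))
  # planted efficiency ratios recovered essentially exactly
  ratio <- sp$normalised_efficiency / sim$truth$ecis_efficiency[
    match(sp$wavelength_nm, sim$truth$wavelength_nm)]
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("dark-control synthetic traces are censored at the threshold", {
  pr <- preset("paper-profile")
  sim <- gen_ecis_traces(pr, seed = 6)
  nc <- control_trace(sim$traces, sim$map, "no_cell_control")
  dk_wells <- sim$map$well[sim$map$role == "dark_control"]
  dk <- control_trace(sim$traces, sim$map, "dark_control")
  one_dark <- ecis_traces(
    dplyr::filter(tibble::as_tibble(sim$traces), well == dk_wells[1]),
    raw = FALSE)
  sc <- scale_ecis(one_dark, nc, dk)
  expect_true(is.na(time_to_threshold(sc, "impedance")))
})
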