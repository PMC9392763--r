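make_hci_fixture <- function() {
  # 2 wavelengths x 2 ND x 2 wells + 2 dark wells, 3 features
  pm <- plate_map(
    well = well_labels(10),
    role = c(rep("exposed", 8), "dark_control", "dark_control"),
    wavelength_nm = c(rep(350, 4), rep(400, 4), NA, NA),
    nd_od = c(rep(c(0, 0, 0.4, 0.4), 2), 0, 0))
  vals <- matrix(10, 10, 3)
  vals[, 2] <- 20
  vals[, 3] <- 5
  rownames(vals) <- well_labels(10)
  ft <- tiny_feature_table(vals,
                           compartments = c("nucleus", "mitochondria", "pi_cm"),
                           kernels = c("ser_spot", "intensity", "count"))
  list(ft = ft, pm = pm)
}

test_that("well aggregation averages per condition and skips NaN", {
  fx <- make_hci_fixture()
  fx$ft$values[1, 1] <- 4; fx$ft$values[2, 1] <- 6
  fx$ft$values[3, 1] <- NaN; fx$ft$values[4, 1] <- 6
  agg <- aggregate_wells(fx$ft, fx$pm)
  full350 <- agg$conditions$wavelength_nm %in% 350 & agg$conditions$nd_od == 0
  nd350 <- agg$conditions$wavelength_nm %in% 350 & agg$conditions$nd_od == 0.4
  expect_equal(unname(agg$values[full350, 1]), 5)
  expect_equal(unname(agg$values[nd350, 1]), 6)
  # permuting well order leaves the aggregate unchanged
  perm <- sample(nrow(fx$ft$values))
  ft2 <- feature_table(fx$ft$values[perm, ], fx$ft$features)
  agg2 <- aggregate_wells(ft2, fx$pm)
  expect_equal(agg2$values, agg$values)
  # unmapped wells are an error
  pm_missing <- plate_map("A01", "exposed", 350)
  expect_error(aggregate_wells(fx$ft, pm_missing),
               class = "actinospec_domain_error")
})

test_that("dark normalisation divides by the dark-control feature means", {
  fx <- make_hci_fixture()
  agg <- normalize_to_dark(aggregate_wells(fx$ft, fx$pm))
  expect_true(all(agg$values == 1))
  # halving a condition's raw values halves its normalised value
  fx$ft$values[1:2, 1] <- 5  # both 350/full wells of feature 1
  agg2 <- normalize_to_dark(aggregate_wells(fx$ft, fx$pm))
  full350 <- agg2$conditions$wavelength_nm %in% 350 & agg2$conditions$nd_od == 0
  expect_equal(unname(agg2$values[full350, 1]), 0.5)
  # a zero dark control drops the feature with a warning
  fx$ft$values[9:10, 3] <- 0
  expect_warning(agg3 <- normalize_to_dark(aggregate_wells(fx$ft, fx$pm)),
                 "zero dark")
  expect_equal(ncol(agg3$values), 2)
  # rescaling a raw feature column changes nothing after normalisation
  fx <- make_hci_fixture()
  base <- normalize_to_dark(aggregate_wells(fx$ft, fx$pm))
  fx$ft$values[, 2] <- fx$ft$values[, 2] * 37
  resc <- normalize_to_dark(aggregate_wells(fx$ft, fx$pm))
  expect_equal(resc$values, base$values)
})

test_that("feature slope fits match the scalar OLS looped over columns", {
  pr <- preset("paper-profile")
  sim <- gen_feature_table(pr, n_features = 24, n_plates = 1,
                           noise_sd = 0.02, seed = 9)
  agg <- normalize_to_dark(aggregate_wells(sim$tables[[1]], sim$maps[[1]]))
  fc <- fit_feature_slopes(agg)
  ex <- agg$conditions$role == "exposed"
  for (w in c("290", "350", "400")) {
    i <- which(ex & agg$conditions$wavelength_nm == as.numeric(w))
    for (f in c(1, 13, 24)) {
      ref <- fit_irradiance_slope(tibble::tibble(
        irradiance = nd_transmittance(agg$conditions$nd_od[i]),
        viability_percent = agg$values[i, f]))
      expect_equal(unname(fc$coef[w, f]), ref$slope, tolerance = 1e-10)
      expect_equal(unname(fc$r_squared[w, f]), ref$r_squared,
                   tolerance = 1e-10)
    }
  }
})

test_that("noiseless feature tables invert to the planted coefficients", {
  pr <- preset("paper-profile")
  sim <- gen_feature_table(pr, noise_sd = 0, seed = 2)
  fc <- build_hci_coefficients(sim$tables, sim$maps)
  expect_equal(unname(fc$coef), unname(sim$truth), tolerance = 1e-9)
  # a feature constant in irradiance has slope zero
  agg <- normalize_to_dark(aggregate_wells(sim$tables[[1]], sim$maps[[1]]))
  agg$values[, 1] <- 1
  expect_equal(unname(fit_feature_slopes(agg)$coef[, 1]),
               rep(0, 12), tolerance = 1e-12)
})

test_that("group spectra respect compartment and kernel selectors", {
  pr <- preset("paper-profile")
  sim <- gen_feature_table(pr, n_features = 56, n_plates = 1, seed = 4)
  fc <- build_hci_coefficients(sim$tables, sim$maps)
  spot <- group_spectrum(fc, kernel = "ser_spot")
  expect_equal(spot$n_features[1],
               sum(fc$features$kernel == "ser_spot"))
  # one-feature selection reproduces that feature's own spectrum
  one_tag <- fc$features[3, ]
  fc_one <- fc
  fc_one$coef <- fc$coef[, 3, drop = FALSE]
  fc_one$features <- one_tag
  direct <- group_spectrum(fc_one, reference_nm = 400)
  expect_equal(direct$efficiency, unname(fc$coef[, 3]^2))
  expect_equal(direct$n_features[1], 1)
  # an empty selection names the selector (20 cyclic features never reach
  # the pi_cm compartment)
  sim20 <- gen_feature_table(pr, n_features = 20, n_plates = 1, seed = 4)
  fc20 <- build_hci_coefficients(sim20$tables, sim20$maps)
  expect_error(group_spectrum(fc20, compartment = "pi_cm",
                              reference_nm = 400),
               "pi_cm", class = "actinospec_domain_error")
})

test_that("the all-features spectrum is the count-weighted compartment mean", {
  pr <- preset("paper-profile")
  sim <- gen_feature_table(pr, seed = 8)
  fc <- build_hci_coefficients(sim$tables, sim$maps)
  all_sp <- group_spectrum(fc)
  comps <- c("nucleus", "mitochondria", "ros", "pi_cm")
  weights <- vapply(comps, function(cc) sum(fc$features$compartment == cc),
                    numeric(1))
  weighted <- Reduce(`+`, lapply(comps, function(cc)
    group_spectrum(fc, compartment = cc)$efficiency *
      sum(fc$features$compartment == cc)))
  expect_equal(all_sp$efficiency, weighted / sum(weights), tolerance = 1e-12)
})

test_that("the planted 350 nm spot effect shows everywhere except PI/Cm", {
  pr <- preset("paper-profile")
  sim <- gen_feature_table(pr, seed = 1)
  fc <- build_hci_coefficients(sim$tables, sim$maps)
  ratio <- function(cc) {
    g <- group_spectrum(fc, compartment = cc, kernel = "ser_spot")
    g$efficiency[g$wavelength_nm == 350] /
      mean(g$efficiency[g$wavelength_nm %in% c(330, 340, 360)])
  }
  for (cc in c("nucleus", "mitochondria", "ros"))
    expect_gt(ratio(cc), 1.4)
  expect_lt(ratio("pi_cm"), 1.4)
})

test_that("the blank item fits near-zero slopes from dark wells", {
  pr <- preset("paper-profile")
  sim <- gen_feature_table(pr, seed = 3)
  fc <- build_hci_coefficients(sim$tables, sim$maps, include_blank = TRUE)
  expect_true("blank" %in% rownames(fc$coef))
  expect_lt(mean(abs(fc$coef["blank", ])), 0.05)
  # the blank row never enters a group spectrum
  expect_false(any(is.na(group_spectrum(fc)$wavelength_nm)))
  expect_equal(nrow(group_spectrum(fc)), 12)
})
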