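test_that("plate map CSV parses exposed and control rows", {
  path <- tmp_csv(c("well,role,wavelength_nm,nd_od",
                    "A01,exposed,350,0.2",
                    "H12,dark_control,,"))
  pm <- read_plate_map(path)
  expect_s3_class(pm, "plate_map")
  expect_equal(pm$wavelength_nm[pm$well == "A01"], 350)
  expect_equal(pm$nd_od[pm$well == "A01"], 0.2)
  expect_true(is.na(pm$wavelength_nm[pm$well == "H12"]))
  expect_equal(pm$nd_od[pm$well == "H12"], 0)
  # roles are case-insensitive
  pm2 <- read_plate_map(tmp_csv(c("well,role,wavelength_nm,nd_od",
                                  "A01,Exposed,350,0")))
  expect_equal(pm2$role, "exposed")
})

test_that("plate map parser rejects invariant violations", {
  dup <- tmp_csv(c("well,role,wavelength_nm,nd_od",
                   "A01,exposed,350,0", "A01,exposed,360,0"))
  expect_error(read_plate_map(dup), "A01", class = "actinospec_format_error")
  role <- tmp_csv(c("well,role,wavelength_nm,nd_od", "A01,cosmic,350,0"))
  expect_error(read_plate_map(role), "cosmic",
               class = "actinospec_format_error")
  nowl <- tmp_csv(c("well,role,wavelength_nm,nd_od", "A01,exposed,,0"))
  expect_error(read_plate_map(nowl), "wavelength",
               class = "actinospec_format_error")
  badwell <- tmp_csv(c("well,role,wavelength_nm,nd_od", "Z99,exposed,350,0"))
  expect_error(read_plate_map(badwell), "Z99",
               class = "actinospec_format_error")
  expect_error(plate_map("A01", "exposed", 350, -0.2),
               class = "actinospec_format_error")
})

test_that("plate map round-trips through CSV", {
  pm <- tiny_map()
  path <- tempfile(fileext = ".csv")
  write_plate_map(pm, path)
  back <- read_plate_map(path, plate_id = attr(pm, "plate_id"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(pm),
               ignore_attr = TRUE)
})

test_that("long ECIS export splits into per-(well, frequency) traces", {
  path <- tmp_csv(c(
    "time_h,well,frequency_hz,z_ohm,r_ohm,c_farad",
    "0,A01,16000,1000,800,4e-9",
    "0.183,A01,16000,990,795,4.1e-9",
    "0.367,A01,16000,985,790,4.2e-9",
    "0,A01,4000,1500,1300,6e-9",
    "0.183,A01,4000,1490,1295,6.1e-9"))
  tr <- read_ecis_long(path)
  expect_equal(nrow(dplyr::distinct(tr, well, frequency_hz)), 2)
  expect_equal(sum(tr$frequency_hz == 16000), 3)
  expect_equal(tr$time_h[tr$frequency_hz == 16000],
               c(0, 0.183, 0.367))
})

test_that("ECIS parser enforces time monotonicity and positivity", {
  dup_t <- tmp_csv(c("time_h,well,frequency_hz,z_ohm,r_ohm,c_farad",
                     "0,A01,16000,1000,800,4e-9",
                     "0,A01,16000,990,795,4e-9"))
  expect_error(read_ecis_long(dup_t), "timestamp",
               class = "actinospec_format_error")
  neg <- tmp_csv(c("time_h,well,frequency_hz,z_ohm,r_ohm,c_farad",
                   "0,A01,16000,-5,800,4e-9"))
  expect_error(read_ecis_long(neg), class = "actinospec_format_error")
})

test_that("nanofarad capacitance flag converts units", {
  path <- tmp_csv(c("time_h,well,frequency_hz,z_ohm,r_ohm,c_farad",
                    "0,A01,16000,1000,800,4"))
  tr <- read_ecis_long(path, capacitance_unit = "nF")
  expect_equal(tr$c_farad, 4e-9)
})

test_that("feature table tags resolve from prefix, then sidecar", {
  path <- tmp_csv(c(
    paste("well", "nucleus__ser_spot__Hoechst SER Spot 1px",
          "mitochondria__intensity__MitoTracker Mean", sep = "\t"),
    paste("A01", "1.5", "200", sep = "\t"),
    paste("A02", "1.7", "210", sep = "\t")), ext = ".tsv")
  ft <- read_feature_table(path)
  expect_equal(ft$features$compartment, c("nucleus", "mitochondria"))
  expect_equal(ft$features$kernel, c("ser_spot", "intensity"))
  expect_equal(ft$features$name[1], "Hoechst SER Spot 1px")
  expect_equal(unname(ft$values["A02", 1]), 1.7)

  # untagged column resolved by sidecar
  path2 <- tmp_csv(c("well\tMystery Feature\tnucleus__count__Nuclei",
                     "A01\t3\t120"), ext = ".tsv")
  sidecar <- tmp_csv(c("column,compartment,kernel",
                       "Mystery Feature,ros,ser_edge"))
  ft2 <- read_feature_table(path2, sidecar = sidecar)
  expect_equal(ft2$features$compartment, c("ros", "nucleus"))
  # without the sidecar the error names the offending column
  expect_error(read_feature_table(path2), "Mystery Feature",
               class = "actinospec_format_error")
})

test_that("feature table round-trips through tagged TSV", {
  ft <- tiny_feature_table(
    matrix(c(1, 2, 3, 4), 2, dimnames = list(c("A01", "A02"), NULL)),
    compartments = c("nucleus", "pi_cm"),
    kernels = c("ser_spot", "count"))
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$values, ft$values, ignore_attr = TRUE)
  expect_equal(back$features$compartment, ft$features$compartment)
  expect_equal(back$features$kernel, ft$features$kernel)
})

test_that("spectra require a uniform 1-nm grid", {
  sp <- spectral_irradiance(290:405, rep(0.5, 116))
  expect_equal(nrow(sp), 116)
  expect_error(spectral_irradiance(seq(290, 404, by = 2), rep(0.5, 58)),
               "uniform", class = "actinospec_format_error")
  expect_error(spectral_irradiance(290:300, c(rep(0.5, 10), -1)),
               class = "actinospec_format_error")
  path <- tmp_csv(c("wavelength_nm,irradiance",
                    paste(290:300, 0.5, sep = ",")))
  expect_equal(read_spectrum(path)$irradiance, rep(0.5, 11))
})

test_that("spectrum results round-trip at full precision", {
  sp <- tibble::tibble(
    wavelength_nm = c(290, 405),
    efficiency = c(1.234567890123e-2, 9.876543210987e-7),
    normalised_efficiency = c(1.249999999999e4, 1),
    n_points = c(36L, 36L))
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$efficiency, sp$efficiency, tolerance = 1e-12)
  expect_equal(back$normalised_efficiency, sp$normalised_efficiency,
               tolerance = 1e-12)
  expect_equal(back$n_wells, c(36L, 36L))
  expect_equal(back$n_censored, c(0L, 0L))
})

test_that("gzip-compressed inputs are accepted by extension", {
  path <- tempfile(fileext = ".csv.gz")
  con <- gzfile(path, "w")
  writeLines(c("well,role,wavelength_nm,nd_od", "A01,exposed,350,0"), con)
  close(con)
  expect_equal(read_plate_map(path)$wavelength_nm, 350)
})
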