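# Synthetic-data generators: viability plates, ECIS traces and imaging
# feature tables with planted, documented wavelength-effect profiles.
# Truth is planted on the scaled/normalised scale and mapped back through
# the inverse of the scaling operations, so parameter-recovery tests
# exercise the scaling code paths too.

UVR_GRID <- seq(290, 400, by = 10)       # exposure bands, nm
ND_LEVELS <- c(0, 0.2, 0.4)              # neutral-density ladder

# planted raw plate-reader control levels (RFU)
VIA_DARK_RFU <- 45000
VIA_LYSED_RFU <- 5000

#' Planted wavelength-effect profiles
#'
#' An effect profile fixes, per wavelength band: the viability slope
#' (percent scaled viability per relative-irradiance unit, full intensity
#' = 1), the relative ECIS efficiency (reference 400 nm = 1), the target
#' 60%-crossing time of the normalised impedance trace, the trace shape
#' (biphasic for UV-A, monotonic for UV-B), the synthetic lamp's band
#' irradiance, and the latent imaging band.
#'
#' `"paper-profile"` plants: a 10% (350 nm) and 30% (380 nm) viability
#' decrease per ND-0.2 intensity step with a 20%-of-control mean UV-A
#' decrease at full intensity; ECIS efficiencies with a 100-fold plateau at
#' 320-350 nm rising to >= 1e4-fold in the UV-B band; three latent imaging
#' bands 290-320 / 330-360 / 370-400 nm; and an extra 350 nm elevation of
#' spot-kernel features in every compartment except PI/CellMask.
#' `"null"` plants no effect anywhere (K = 1). `"two-band"` plants a UV-B
#' vs UV-A contrast only.
#'
#' The lamp model: band irradiances are wavelength-dependent (weak UV-B
#' output) and chosen so that every planted impedance crossing falls
#' between 4 h and 60 h, inside the 68-h exposure window and well above the
#' 11-min sampling interval.
#'
#' @param name `"paper-profile"`, `"null"` or `"two-band"`.
#' @return a list of class `effect_profile`: `name`, `wavelengths` (tibble
#'   `wavelength_nm, viability_slope, ecis_efficiency, ecis_cross_h,
#'   biphasic, irradiance_w_m2, hci_band`), `spot_350`, `hci_delta`,
#'   `hci_spot_delta`, `hci_jitter_sd`, and the per-stage reference
#'   wavelengths.
#' @export
#' @examples
#' pr <- preset("paper-profile")
#' subset(pr$wavelengths, wavelength_nm == 400)$ecis_efficiency  # 1
preset <- function(name = c("paper-profile", "null", "two-band")) {
  name <- match.arg(name)
  wl <- c(UVR_GRID, 405)
  nd_step <- 1 - nd_transmittance(0.2)   # relative-intensity drop per ND 0.2
  if (name == "paper-profile") {
    d350 <- 10 / nd_step                 # full-intensity decrease, percent
    d380 <- 30 / nd_step
    d_other <- (20 * 9 - d350 - d380) / 7  # mean UV-A decrease = 20%
    # 405 nm reference slope anchored to the ~5-fold efficiency step
    # between 350 and 405 nm (efficiency = slope^2)
    slope <- c(`290` = -97, `300` = -95, `310` = -90,
               `320` = -d_other, `330` = -d_other, `340` = -d_other,
               `350` = -d350, `360` = -d_other, `370` = -d_other,
               `380` = -d380, `390` = -d_other, `400` = -d_other,
               `405` = -d350 / sqrt(5))
    eff <- c(`290` = 3e4, `300` = 1e4, `310` = 1e3,
             `320` = 100, `330` = 100, `340` = 100, `350` = 100,
             `360` = 30, `370` = 3, `380` = 10, `390` = 3, `400` = 1,
             `405` = NA)
    cross <- c(`290` = 4, `300` = 5, `310` = 6,
               `320` = 46, `330` = 47, `340` = 48, `350` = 49,
               `360` = 50, `370` = 52, `380` = 54, `390` = 56, `400` = 60,
               `405` = NA)
    band <- c(rep(1, 4), rep(2, 4), rep(3, 4), NA)
    spot <- TRUE
    delta <- 0.6
  } else if (name == "null") {
    slope <- setNames(rep(0, 13), wl)
    eff <- setNames(c(rep(1, 12), NA), wl)
    cross <- setNames(c(rep(60, 12), NA), wl)
    band <- rep(NA_real_, 13)
    spot <- FALSE
    delta <- 0
  } else { # two-band
    slope <- setNames(c(rep(-90, 3), rep(-15, 9), -2), wl)
    eff <- setNames(c(rep(1e4, 3), rep(10, 8), 1, NA), wl)
    cross <- setNames(c(5, 5, 5, rep(50, 8), 60, NA), wl)
    band <- c(rep(1, 4), rep(2, 8), NA)
    spot <- FALSE
    delta <- 0.6
  }
  irr <- 600 / (eff * cross)             # lamp model, W m^-2; 400 nm -> 10
  irr[13] <- 10                          # 405 nm reference band
  structure(list(
    name = name,
    wavelengths = tibble::tibble(
      wavelength_nm = wl,
      viability_slope = unname(slope),
      ecis_efficiency = unname(eff),
      ecis_cross_h = unname(cross),
      biphasic = wl >= 320 & wl <= 400,
      irradiance_w_m2 = unname(irr),
      hci_band = band),
    spot_350 = spot,
    hci_delta = delta, hci_spot_delta = if (spot) 0.15 else 0,
    hci_jitter_sd = 0.1,
    reference_viability_nm = 405, reference_ecis_nm = 400,
    reference_hci_nm = 400),
    class = "effect_profile")
}

#' @noRd
require_seed <- function(seed) {
  if (is.null(seed) || !is.finite(seed))
    as_error("generators require an explicit seed", "actinospec_domain_error")
  set.seed(as.integer(seed))
}

# -- Viability plates -------------------------------------------------------

#' Generate viability plates with a planted slope profile
#'
#' Scaled truth per exposed well: `v = 100 + slope(w) * I_rel + noise`,
#' with `I_rel = 10^(-OD)` the relative intensity. The truth is mapped back
#' through the inverse of the control scaling into raw RFU with planted
#' control levels, so [scale_viability_plate()] recovers it. One biological
#' replicate does not fit a 96-well plate (13 bands x 3 ND x 4 wells), so
#' each replicate is emitted as two physical plates (wavelength split),
#' each carrying its own dark and lysed control wells.
#'
#' @param profile an [preset()] effect profile.
#' @param n_plates biological replicates (default 3).
#' @param wells_per_condition technical replicates per (wavelength, ND)
#'   condition and replicate (default 4).
#' @param noise_sd_percent Gaussian noise sd on the scaled-viability scale
#'   (default 2).
#' @param seed required RNG seed.
#' @return list `plates` (list of [viability_plate]), `maps` (matching
#'   [plate_map]s), `truth` (the profile's wavelength table).
#' @export
gen_viability_plates <- function(profile, n_plates = 3,
                                 wells_per_condition = 4,
                                 noise_sd_percent = 2, seed = NULL) {
  require_seed(seed)
  wls <- profile$wavelengths$wavelength_nm
  split_a <- wls[wls <= 340]
  split_b <- wls[wls > 340]
  plates <- list(); maps <- list()
  for (r in seq_len(n_plates)) {
    for (half in list(A = split_a, B = split_b)) {
      cond <- expand.grid(wavelength_nm = half, nd_od = ND_LEVELS,
                          KEEP.OUT.ATTRS = FALSE)
      cond <- cond[rep(seq_len(nrow(cond)), each = wells_per_condition), ]
      n_ctrl <- 4L
      n_wells <- nrow(cond) + 2L * n_ctrl
      labs <- well_labels(n_wells)
      well <- labs[seq_len(nrow(cond))]
      ctrl <- labs[nrow(cond) + seq_len(2L * n_ctrl)]
      pm <- plate_map(
        well = c(well, ctrl),
        role = c(rep("exposed", nrow(cond)),
                 rep("dark_control", n_ctrl), rep("lysed_control", n_ctrl)),
        wavelength_nm = c(cond$wavelength_nm, rep(NA, 2L * n_ctrl)),
        nd_od = c(cond$nd_od, rep(0, 2L * n_ctrl)),
        plate_id = sprintf("rep%d_plate%s",
                           r, if (identical(half, split_a)) "A" else "B"),
        replicate_id = r)
      slope <- profile$wavelengths$viability_slope[
        match(cond$wavelength_nm, wls)]
      v <- c(100 + slope * nd_transmittance(cond$nd_od),
             rep(100, n_ctrl), rep(0, n_ctrl))
      v <- v + rnorm(length(v), 0, noise_sd_percent)
      rfu <- VIA_LYSED_RFU + v / 100 * (VIA_DARK_RFU - VIA_LYSED_RFU)
      plates[[length(plates) + 1L]] <-
        viability_plate(c(well, ctrl), rfu,
                        plate_id = attr(pm, "plate_id"))
      maps[[length(maps) + 1L]] <- pm
    }
  }
  list(plates = plates, maps = maps, truth = profile$wavelengths)
}

# -- ECIS traces ------------------------------------------------------------

#' @noRd
ecis_template <- function(t, cross_h, biphasic, lamp_off_h) {
  floor_v <- 0.05
  v <- if (biphasic) {
    # media-change bump, early drop to a 0.75 plateau (>= 5 sd above the
    # 0.6 threshold at 2% multiplicative noise, so plateau dips cannot
    # trigger spurious crossings), then a precipitous late decline
    # (-0.05/h) timed to cross 0.6 at cross_h
    t_dec <- cross_h - 3
    knots_t <- c(0, 2, 6, t_dec)
    knots_v <- c(1, 1.06, 0.78, 0.75)
    late <- t > t_dec
    out <- approx(knots_t, knots_v, xout = pmin(t, t_dec), rule = 2)$y
    out[late] <- 0.75 - 0.05 * (t[late] - t_dec)
    out
  } else {
    # monotonic UV-B decline crossing 0.6 at cross_h
    1 - 0.4 * t / cross_h
  }
  v <- pmax(v, floor_v)
  # post-douse recovery rise
  post <- t > lamp_off_h
  if (any(post)) {
    v_off <- v[which(post)[1] - 1L]
    v[post] <- v_off + 0.08 * (t[post] - lamp_off_h)
  }
  v
}

#' Generate ECIS traces with planted crossing times
#'
#' Emits raw impedance/resistance/capacitance traces for exposed wells,
#' dark-control and no-cell-control wells at one frequency. The planted
#' normalised truth has a media-change bump and biphasic decline for UV-A
#' (early drop to a 0.70 plateau, late decline crossing 0.6 at the
#' profile's target time), a monotonic decline for UV-B, and a post-douse
#' recovery rise; it is mapped to raw ohms/farads through the inverse of
#' the control scaling (common multiplicative drift included), with
#' multiplicative Gaussian measurement noise.
#'
#' @param profile an [preset()] effect profile.
#' @param wells_per_wavelength exposed wells per band (default 4).
#' @param duration_h,interval_min recording span and sampling interval
#'   (defaults 72 h, 11 min).
#' @param lamp_off_h lamp-off time (default 68 h).
#' @param noise_sd multiplicative noise sd (default 0.02).
#' @param frequency_hz measurement frequency (default 16 kHz).
#' @param seed required RNG seed.
#' @return list `traces` (raw [ecis_traces]), `map` ([plate_map]), `doses`
#'   (tibble `well, irradiance_w_m2`), `truth` (wavelength table).
#' @export
gen_ecis_traces <- function(profile, wells_per_wavelength = 4,
                            duration_h = 72, interval_min = 11,
                            lamp_off_h = 68, noise_sd = 0.02,
                            frequency_hz = 16000, seed = NULL) {
  require_seed(seed)
  wt <- profile$wavelengths[!is.na(profile$wavelengths$ecis_efficiency), ]
  t <- seq(0, duration_h, by = interval_min / 60)
  n_exp <- nrow(wt) * wells_per_wavelength
  labs <- well_labels(n_exp + 4L)
  exp_wells <- labs[seq_len(n_exp)]
  dark_wells <- labs[n_exp + 1:2]
  nc_wells <- labs[n_exp + 3:4]
  pm <- plate_map(
    well = c(exp_wells, dark_wells, nc_wells),
    role = c(rep("exposed", n_exp), rep("dark_control", 2),
             rep("no_cell_control", 2)),
    wavelength_nm = c(rep(wt$wavelength_nm, each = wells_per_wavelength),
                      rep(NA, 4)),
    nd_od = 0, plate_id = "ecis_plate")

  drift <- 1 + 0.001 * t                 # shared multiplicative drift
  base <- list(z_ohm = c(nc = 300, dark = 1500),
               r_ohm = c(nc = 250, dark = 1200),
               c_farad = c(nc = 2e-9, dark = 5e-9))
  f0 <- 0.9                              # cells sit at 90% of the dark level at t0

  make_raw <- function(g, which) {       # inverse of the control scaling
    b <- base[[which]]
    nc <- b["nc"] * drift
    dk <- b["dark"] * drift
    nc + f0 * g * (dk - nc)
  }
  noisy <- function(x) x * (1 + rnorm(length(x), 0, noise_sd))

  rows <- purrr::map_dfr(seq_len(nrow(pm)), function(i) {
    w <- pm$well[i]
    role <- pm$role[i]
    g <- if (role == "exposed") {
      j <- match(pm$wavelength_nm[i], wt$wavelength_nm)
      ecis_template(t, wt$ecis_cross_h[j], wt$biphasic[j], lamp_off_h)
    } else if (role == "dark_control") {
      rep(1, length(t))
    } else {
      NULL                               # no-cell wells carry no monolayer
    }
    tibble::tibble(
      time_h = t, well = w, frequency_hz = frequency_hz,
      z_ohm = noisy(if (is.null(g)) base$z_ohm["nc"] * drift
                    else make_raw(g, "z_ohm")),
      r_ohm = noisy(if (is.null(g)) base$r_ohm["nc"] * drift
                    else make_raw(g, "r_ohm")),
      c_farad = noisy(if (is.null(g)) base$c_farad["nc"] * drift
                      else make_raw(g, "c_farad")))
  })
  doses <- tibble::tibble(
    well = exp_wells,
    irradiance_w_m2 = wt$irradiance_w_m2[
      match(pm$wavelength_nm[match(exp_wells, pm$well)], wt$wavelength_nm)])
  list(traces = ecis_traces(rows, raw = TRUE), map = pm, doses = doses,
       truth = wt)
}

# -- Imaging feature tables -------------------------------------------------

#' @noRd
feature_schema <- function(n_features) {
  combos <- expand.grid(kernel = FEATURE_KERNELS,
                        compartment = FEATURE_COMPARTMENTS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- rep(seq_len(nrow(combos)), length.out = n_features)
  tibble::tibble(
    column = sprintf("%s__%s__feature_%03d",
                     combos$compartment[i], combos$kernel[i],
                     seq_len(n_features)),
    name = sprintf("feature_%03d", seq_len(n_features)),
    compartment = combos$compartment[i],
    kernel = combos$kernel[i])
}

#' Generate an imaging feature table with planted band structure
#'
#' Plants a per-feature slope truth on the fraction-of-dark scale:
#' each feature is driven by one latent wavelength band (`slope = -delta`
#' where the band matches, 0 elsewhere, plus Gaussian jitter), and - for
#' profiles with the 350 nm spot effect - spot-kernel features of the
#' nucleus, mitochondria and ROS compartments (not PI/CellMask) receive an
#' extra negative slope at 350 nm. Well values are
#' `dark_level(f) * (1 + slope(w, f) * I_rel + noise)`, so the
#' aggregate -> dark-normalise -> slope-fit pipeline recovers the truth.
#'
#' @param profile an [preset()] effect profile.
#' @param n_features number of features (default 380).
#' @param n_plates biological replicates (default 3).
#' @param wells_per_condition wells per (wavelength, ND) and replicate
#'   (default 2; 12 bands x 3 ND x 2 + 4 dark wells = 76 wells per plate).
#' @param noise_sd well-level noise sd on the fraction-of-dark scale
#'   (default 0.02).
#' @param seed required RNG seed.
#' @return list `tables` (list of [feature_table]), `maps` (matching
#'   [plate_map]s), `truth` (wavelength x feature slope matrix),
#'   `features` (schema tibble), `bands` (named latent band per
#'   wavelength).
#' @export
gen_feature_table <- function(profile, n_features = 380, n_plates = 3,
                              wells_per_condition = 2, noise_sd = 0.02,
                              seed = NULL) {
  require_seed(seed)
  schema <- feature_schema(n_features)
  wt <- profile$wavelengths[profile$wavelengths$wavelength_nm %in% UVR_GRID, ]
  n_bands <- length(unique(stats::na.omit(wt$hci_band)))
  driver <- if (n_bands > 0) sample(seq_len(n_bands), n_features,
                                    replace = TRUE) else rep(0L, n_features)
  band_of <- wt$hci_band
  S <- matrix(rnorm(nrow(wt) * n_features, 0, profile$hci_jitter_sd),
              nrow(wt), n_features,
              dimnames = list(wt$wavelength_nm, schema$column))
  if (n_bands > 0) {
    hit <- outer(band_of, driver, `==`)
    hit[is.na(hit)] <- FALSE
    S <- S - profile$hci_delta * hit
  }
  if (profile$spot_350 && "350" %in% rownames(S)) {
    spot <- schema$kernel == "ser_spot" &
      schema$compartment %in% c("nucleus", "mitochondria", "ros")
    S["350", spot] <- S["350", spot] - profile$hci_spot_delta
  }
  dark_level <- exp(rnorm(n_features, log(1000), 0.5))

  cond <- expand.grid(wavelength_nm = wt$wavelength_nm, nd_od = ND_LEVELS,
                      KEEP.OUT.ATTRS = FALSE)
  cond <- cond[rep(seq_len(nrow(cond)), each = wells_per_condition), ]
  n_dark <- 4L
  labs <- well_labels(nrow(cond) + n_dark)
  tables <- list(); maps <- list()
  for (r in seq_len(n_plates)) {
    pm <- plate_map(
      well = labs,
      role = c(rep("exposed", nrow(cond)), rep("dark_control", n_dark)),
      wavelength_nm = c(cond$wavelength_nm, rep(NA, n_dark)),
      nd_od = c(cond$nd_od, rep(0, n_dark)),
      plate_id = sprintf("hci_rep%d", r), replicate_id = r)
    irel <- nd_transmittance(cond$nd_od)
    wi <- match(cond$wavelength_nm, wt$wavelength_nm)
    vals <- 1 + S[wi, , drop = FALSE] * irel +
      matrix(rnorm(nrow(cond) * n_features, 0, noise_sd),
             nrow(cond), n_features)
    dark_vals <- 1 + matrix(rnorm(n_dark * n_features, 0, noise_sd),
                            n_dark, n_features)
    raw <- sweep(rbind(vals, dark_vals), 2, dark_level, "*")
    rownames(raw) <- labs
    tables[[r]] <- feature_table(raw, schema)
    maps[[r]] <- pm
  }
  list(tables = tables, maps = maps, truth = S, features = schema,
       bands = setNames(wt$hci_band, wt$wavelength_nm))
}
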