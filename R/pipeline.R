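# End-to-end orchestration: plain-text run config, stage drivers, manifest.

#' Default run configuration
#'
#' All tunables of the end-to-end run, with their defaults. No hidden
#' defaults: the effective configuration is echoed into the run manifest.
#'
#' @return named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    preset = "paper-profile",
    seed = 1L,
    out_dir = "results",
    n_plates = 3L,
    wells_per_condition = 4L,
    viability_noise_sd_percent = 2,
    reference_viability_nm = 405,
    ecis_wells_per_wavelength = 4L,
    ecis_noise_sd = 0.02,
    ecis_parameter = "impedance",
    ecis_frequency_hz = 16000,
    ecis_fraction = 0.6,
    lamp_off_h = 68,
    reference_ecis_nm = 400,
    hci_n_features = 380L,
    hci_wells_per_condition = 2L,
    hci_noise_sd = 0.02,
    reference_hci_nm = 400,
    cluster_k_max = 8L,
    cluster_reps = 500L,
    cluster_null_sims = 100L,
    cluster_exclude_blank = TRUE
  )
}

#' Read / write a plain-text run configuration
#'
#' `key = value` lines; `#` starts a comment. Values are coerced to
#' numeric/logical where possible, so a config round-trips losslessly.
#'
#' @param path config file.
#' @return named list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- default_run_config()
  for (p in kv) {
    if (length(p) != 2)
      as_error(paste0("malformed config line: ", paste(p, collapse = "=")),
               "actinospec_format_error")
    key <- trimws(p[1]); val <- trimws(p[2])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false"))
                    as.logical(toupper(val))
                  else val
  }
  cfg
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' ECIS stage: raw traces to action spectrum
#'
#' Aggregates the control wells, control-scales and t0-normalises the
#' exposed traces, and builds the action spectrum.
#'
#' @param traces raw [ecis_traces].
#' @param map matching [plate_map] with `no_cell_control` and
#'   `dark_control` wells.
#' @param doses tibble `well, irradiance_w_m2`.
#' @param parameter,frequency_hz,fraction,lamp_off_h,reference_nm see
#'   [build_action_spectrum()].
#' @return an `action_spectrum`.
#' @export
ecis_spectrum_pipeline <- function(traces, map, doses,
                                   parameter = "impedance",
                                   frequency_hz = 16000, fraction = 0.6,
                                   lamp_off_h = 68, reference_nm = 400) {
  nc <- control_trace(traces, map, "no_cell_control", frequency_hz)
  dk <- control_trace(traces, map, "dark_control", frequency_hz)
  pm <- tibble::as_tibble(map)
  ex <- dplyr::filter(tibble::as_tibble(traces),
                      .data$well %in% pm$well[pm$role == "exposed"],
                      .data$frequency_hz == !!frequency_hz)
  scaled <- scale_ecis(ecis_traces(ex, raw = FALSE,
                                   processing = attr(traces, "processing")),
                       nc, dk)
  build_action_spectrum(scaled, map, doses, parameter = parameter,
                        frequency_hz = frequency_hz, fraction = fraction,
                        lamp_off_h = lamp_off_h, reference_nm = reference_nm)
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    as_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             "actinospec_stage_error")
  })
}

#' Run the full pipeline on a synthetic preset
#'
#' simulate -> viability spectrum -> ECIS action spectrum -> imaging
#' spectra -> consensus clustering, writing all outputs (CSV/JSON) and a
#' run manifest under `config$out_dir`. Deterministic: identical
#' (config, seed) gives byte-identical outputs. Stage seeds are derived
#' from `config$seed` by fixed offsets and echoed in the manifest.
#'
#' @param config configuration list (see [default_run_config()]); missing
#'   entries take their defaults.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config = list()) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(viability = cfg$seed + 1L, ecis = cfg$seed + 2L,
                hci = cfg$seed + 3L, cluster = cfg$seed + 4L)
  paths <- list()
  profile <- stage("simulate", preset(cfg$preset))

  via <- stage("viability", {
    sim <- gen_viability_plates(profile, n_plates = cfg$n_plates,
                                wells_per_condition = cfg$wells_per_condition,
                                noise_sd_percent = cfg$viability_noise_sd_percent,
                                seed = seeds$viability)
    build_viability_spectrum(sim$plates, sim$maps,
                             reference_nm = cfg$reference_viability_nm)
  })
  paths$viability_spectrum <- file.path(cfg$out_dir, "viability_spectrum.csv")
  write_spectrum_csv(via, paths$viability_spectrum)

  ecis <- stage("ecis", {
    sim <- gen_ecis_traces(profile,
                           wells_per_wavelength = cfg$ecis_wells_per_wavelength,
                           lamp_off_h = cfg$lamp_off_h,
                           noise_sd = cfg$ecis_noise_sd,
                           frequency_hz = cfg$ecis_frequency_hz,
                           seed = seeds$ecis)
    ecis_spectrum_pipeline(sim$traces, sim$map, sim$doses,
                           parameter = cfg$ecis_parameter,
                           frequency_hz = cfg$ecis_frequency_hz,
                           fraction = cfg$ecis_fraction,
                           lamp_off_h = cfg$lamp_off_h,
                           reference_nm = cfg$reference_ecis_nm)
  })
  paths$ecis_spectrum <- file.path(cfg$out_dir, "ecis_action_spectrum.csv")
  write_spectrum_csv(ecis, paths$ecis_spectrum)

  hci <- stage("hci", {
    sim <- gen_feature_table(profile, n_features = cfg$hci_n_features,
                             n_plates = cfg$n_plates,
                             wells_per_condition = cfg$hci_wells_per_condition,
                             noise_sd = cfg$hci_noise_sd, seed = seeds$hci)
    coeffs <- build_hci_coefficients(sim$tables, sim$maps,
                                     include_blank = TRUE)
    groups <- c(list(all = group_spectrum(coeffs,
                                          reference_nm = cfg$reference_hci_nm)),
                setNames(lapply(FEATURE_COMPARTMENTS, function(cc)
                  group_spectrum(coeffs, compartment = cc,
                                 reference_nm = cfg$reference_hci_nm)),
                  FEATURE_COMPARTMENTS))
    list(coeffs = coeffs, groups = groups)
  })
  for (g in names(hci$groups)) {
    paths[[paste0("hci_spectrum_", g)]] <-
      file.path(cfg$out_dir, sprintf("hci_spectrum_%s.csv", g))
    write_spectrum_csv(hci$groups[[g]], paths[[paste0("hci_spectrum_", g)]])
  }

  clus <- stage("cluster", {
    X <- hci$coeffs$coef
    if (cfg$cluster_exclude_blank) X <- X[rownames(X) != "blank", , drop = FALSE]
    select_k(X, k_range = 2:cfg$cluster_k_max, reps = cfg$cluster_reps,
             B = cfg$cluster_null_sims, seed = seeds$cluster)
  })
  paths$cluster_report <- file.path(cfg$out_dir, "cluster_report.json")
  bands <- map_clusters(clus$assignments)
  jsonlite::write_json(list(
    selected_k = clus$selected_k,
    scores = clus$scores,
    assignments = as.list(clus$assignments),
    bands = bands), paths$cluster_report, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (k in names(clus$consensus)) {
    p <- file.path(cfg$out_dir, sprintf("consensus_k%s.csv", k))
    utils::write.csv(clus$consensus[[k]], p)
    paths[[paste0("consensus_k", k)]] <- p
  }

  manifest <- list(package_version = as.character(utils::packageVersion("actinospec")),
                   config = cfg, stage_seeds = seeds, outputs = paths)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
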