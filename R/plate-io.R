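# Tabular interchange formats and core domain containers.
#
# All tables are UTF-8 CSV (or TSV for feature tables) with '.' decimal
# separator; gzip-compressed variants are accepted by file extension
# (readr decompresses transparently).

WELL_ROLES <- c("exposed", "dark_control", "lysed_control",
                "no_cell_control", "media_only")

FEATURE_COMPARTMENTS <- c("nucleus", "mitochondria", "ros", "pi_cm")
FEATURE_KERNELS <- c("intensity", "ser_spot", "ser_ridge", "ser_edge",
                     "ser_other", "star_morphology", "count")

# -- PlateMap ---------------------------------------------------------------

#' Construct a plate map
#'
#' A plate map assigns each well of a fixed 96-well plate (labels A01..H12)
#' to an exposure role, a UVR wavelength band and a neutral-density (ND)
#' filter. Exposed wells carry a band centre in nm (10-nm bands, 290-405);
#' control wells carry no wavelength.
#'
#' @param well character well labels (A01..H12).
#' @param role one of `"exposed"`, `"dark_control"`, `"lysed_control"`,
#'   `"no_cell_control"`, `"media_only"` per well (case-insensitive).
#' @param wavelength_nm band centre in nm for exposed wells, `NA` otherwise.
#' @param nd_od optical density of the neutral-density filter (0 = full
#'   intensity).
#' @param plate_id,replicate_id plate identifier and biological replicate
#'   index, stored as attributes.
#' @return a tibble of class `plate_map` with columns
#'   `well`, `role`, `wavelength_nm`, `nd_od`.
#' @export
#' @examples
#' plate_map(c("A01", "H12"), c("exposed", "dark_control"),
#'           wavelength_nm = c(350, NA), nd_od = c(0.2, 0))
plate_map <- function(well, role, wavelength_nm = NA_real_, nd_od = 0,
                      plate_id = "plate", replicate_id = 1L) {
  pm <- tibble::tibble(
    well = as.character(well),
    role = tolower(as.character(role)),
    wavelength_nm = as.numeric(wavelength_nm),
    nd_od = as.numeric(nd_od)
  )
  pm$nd_od[is.na(pm$nd_od)] <- 0
  attr(pm, "plate_id") <- plate_id
  attr(pm, "replicate_id") <- as.integer(replicate_id)
  class(pm) <- c("plate_map", class(tibble::tibble()))
  validate_plate_map(pm)
}

#' @noRd
validate_plate_map <- function(pm) {
  bad_label <- pm$well[!is_valid_well(pm$well)]
  if (length(bad_label) > 0)
    as_error(paste0("invalid well label(s): ", paste(bad_label, collapse = ", ")),
             "actinospec_format_error")
  dup <- pm$well[duplicated(pm$well)]
  if (length(dup) > 0)
    as_error(paste0("duplicate well label(s): ", paste(unique(dup), collapse = ", ")),
             "actinospec_format_error")
  bad_role <- setdiff(unique(pm$role), WELL_ROLES)
  if (length(bad_role) > 0)
    as_error(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")),
             "actinospec_format_error")
  exp <- pm$role == "exposed"
  if (any(exp & is.na(pm$wavelength_nm))) {
    off <- pm$well[exp & is.na(pm$wavelength_nm)]
    as_error(paste0("exposed well(s) lacking wavelength: ",
                    paste(off, collapse = ", ")), "actinospec_format_error")
  }
  if (any(!exp & !is.na(pm$wavelength_nm))) {
    off <- pm$well[!exp & !is.na(pm$wavelength_nm)]
    as_error(paste0("control well(s) carrying a wavelength: ",
                    paste(off, collapse = ", ")), "actinospec_format_error")
  }
  wl <- pm$wavelength_nm[exp]
  if (any(wl < 290 | wl > 405))
    as_error("wavelength_nm outside [290, 405]", "actinospec_format_error")
  if (any(pm$nd_od < 0))
    as_error("nd_od must be >= 0", "actinospec_format_error")
  pm
}

#' Read a plate map from CSV
#'
#' Expects header columns `well, role, wavelength_nm, nd_od`; roles are
#' parsed case-insensitively, empty `nd_od` is taken as 0 and empty
#' `wavelength_nm` as absent (controls).
#'
#' @param path CSV file (optionally gzip-compressed).
#' @param plate_id,replicate_id identifiers attached to the map; default
#'   `plate_id` is the file name.
#' @return a [plate_map].
#' @export
read_plate_map <- function(path, plate_id = basename(path), replicate_id = 1L) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    role = readr::col_character(),
    wavelength_nm = readr::col_double(),
    nd_od = readr::col_double()
  ), progress = FALSE)
  plate_map(df$well, df$role, df$wavelength_nm, df$nd_od,
            plate_id = plate_id, replicate_id = replicate_id)
}

#' Write a plate map to CSV
#' @param map a [plate_map].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path, progress = FALSE)
  invisible(path)
}

# -- ViabilityPlate ---------------------------------------------------------

#' Construct a viability plate
#'
#' Raw fluorescence readings (RFU; Ex 520 / Em 580 resazurin-reduction
#' endpoint) per well of one physical plate.
#'
#' @param well character well labels.
#' @param rfu non-negative raw fluorescence values.
#' @param plate_id plate identifier.
#' @return a tibble of class `viability_plate` with columns `well`, `rfu`.
#' @export
viability_plate <- function(well, rfu, plate_id = "plate") {
  if (any(rfu < 0, na.rm = TRUE))
    as_error("viability readings must be non-negative", "actinospec_format_error")
  vp <- tibble::tibble(well = as.character(well), rfu = as.numeric(rfu))
  if (anyDuplicated(vp$well))
    as_error("duplicate well in viability plate", "actinospec_format_error")
  attr(vp, "plate_id") <- plate_id
  class(vp) <- c("viability_plate", class(tibble::tibble()))
  vp
}

#' Read a viability plate from CSV (columns `well, rfu`)
#' @param path CSV file.
#' @param plate_id plate identifier (default: file name).
#' @return a [viability_plate].
#' @export
read_viability_plate <- function(path, plate_id = basename(path)) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), rfu = readr::col_double()
  ), progress = FALSE)
  viability_plate(df$well, df$rfu, plate_id = plate_id)
}

#' Write a viability plate to CSV
#' @param plate a [viability_plate].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_viability_plate <- function(plate, path) {
  readr::write_csv(tibble::as_tibble(plate), path, progress = FALSE)
  invisible(path)
}

# -- EcisTrace --------------------------------------------------------------

#' Construct a set of ECIS traces
#'
#' Long-format container for electric cell-substrate impedance sensing time
#' series: one row per (well, frequency, time point) with impedance (Z, ohm),
#' resistance (R, ohm) and capacitance (C, farad). A "trace" is one
#' (well, frequency) series.
#'
#' @param df data frame with columns
#'   `well, frequency_hz, time_h, z_ohm, r_ohm, c_farad`.
#' @param raw if `TRUE` (raw instrument data) all electrical values must be
#'   strictly positive; scaled/normalised traces set this to `FALSE`.
#' @param processing character vector recording processing steps applied
#'   (kept as an attribute and extended by the scaling operations).
#' @return a tibble of class `ecis_traces`, sorted by well, frequency, time.
#' @export
ecis_traces <- function(df, raw = TRUE, processing = character()) {
  need <- c("well", "frequency_hz", "time_h", "z_ohm", "r_ohm", "c_farad")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    as_error(paste0("ECIS table lacks column(s): ", paste(miss, collapse = ", ")),
             "actinospec_format_error")
  tr <- tibble::as_tibble(df)[need]
  tr <- dplyr::arrange(tr, .data$well, .data$frequency_hz, .data$time_h)
  if (any(tr$frequency_hz <= 0))
    as_error("frequency_hz must be positive", "actinospec_format_error")
  key <- paste(tr$well, tr$frequency_hz)
  dup <- tapply(tr$time_h, key, function(t) any(diff(t) <= 0))
  if (any(unlist(dup))) {
    off <- names(dup)[unlist(dup)]
    as_error(paste0("non-increasing or duplicated timestamps in trace(s): ",
                    paste(off, collapse = "; ")), "actinospec_format_error")
  }
  if (raw && any(c(tr$z_ohm, tr$r_ohm, tr$c_farad) <= 0, na.rm = TRUE))
    as_error("raw electrical values must be > 0", "actinospec_format_error")
  attr(tr, "processing") <- processing
  class(tr) <- unique(c("ecis_traces", class(tr)))
  tr
}

#' Read long-format ECIS exports
#'
#' Expects a long CSV with columns
#' `time_h, well, frequency_hz, z_ohm, r_ohm, c_farad`; one trace is formed
#' per (well, frequency) and sorted by time. Vendors exporting capacitance
#' in nanofarad can be accommodated with `capacitance_unit = "nF"`.
#'
#' @param path CSV file (optionally gzip-compressed).
#' @param capacitance_unit `"farad"` (default) or `"nF"`.
#' @param expected_interval_min if non-`NULL`, warn when the median sampling
#'   interval deviates from this value by more than `interval_tol`
#'   (fractional tolerance). The instrument default is 11 min.
#' @param interval_tol fractional tolerance on the sampling interval.
#' @return an [ecis_traces] tibble.
#' @export
read_ecis_long <- function(path, capacitance_unit = c("farad", "nF"),
                           expected_interval_min = NULL, interval_tol = 0.25) {
  capacitance_unit <- match.arg(capacitance_unit)
  df <- readr::read_csv(path, col_types = readr::cols(
    time_h = readr::col_double(), well = readr::col_character(),
    frequency_hz = readr::col_double(), z_ohm = readr::col_double(),
    r_ohm = readr::col_double(), c_farad = readr::col_double()
  ), progress = FALSE)
  if (capacitance_unit == "nF") df$c_farad <- df$c_farad * 1e-9
  tr <- ecis_traces(df, raw = TRUE)
  if (!is.null(expected_interval_min)) {
    iv <- stats::median(unlist(tapply(tr$time_h, paste(tr$well, tr$frequency_hz),
                                      diff))) * 60
    if (abs(iv - expected_interval_min) > interval_tol * expected_interval_min)
      rlang::warn(sprintf(
        "median sampling interval %.2f min differs from expected %.2f min",
        iv, expected_interval_min))
  }
  tr
}

#' Write ECIS traces to long CSV
#' @param traces an [ecis_traces] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ecis_long <- function(traces, path) {
  readr::write_csv(tibble::as_tibble(traces), path, progress = FALSE)
  invisible(path)
}

# -- FeatureTable -----------------------------------------------------------

#' Construct a high-content-imaging feature table
#'
#' A well-by-feature matrix of imaging readouts. Every feature carries
#' exactly one probe-compartment tag (`nucleus`, `mitochondria`, `ros`,
#' `pi_cm`) and one kernel tag (`intensity`, `ser_spot`, `ser_ridge`,
#' `ser_edge`, `ser_other`, `star_morphology`, `count`).
#'
#' @param values numeric matrix, rows = wells (rownames = well labels),
#'   columns = features (colnames = feature column ids).
#' @param features tibble with columns `column, name, compartment, kernel`,
#'   one row per column of `values`, in the same order.
#' @return a list of class `feature_table` with elements `values`, `features`.
#' @export
feature_table <- function(values, features) {
  values <- as.matrix(values)
  features <- tibble::as_tibble(features)
  if (ncol(values) != nrow(features))
    as_error("feature tag table does not match the value matrix",
             "actinospec_format_error")
  if (!all(c("column", "name", "compartment", "kernel") %in% names(features)))
    as_error("feature tags need columns: column, name, compartment, kernel",
             "actinospec_format_error")
  bad_c <- setdiff(unique(features$compartment), FEATURE_COMPARTMENTS)
  bad_k <- setdiff(unique(features$kernel), FEATURE_KERNELS)
  if (length(bad_c) > 0 || length(bad_k) > 0)
    as_error(paste0("unknown compartment/kernel tag(s): ",
                    paste(c(bad_c, bad_k), collapse = ", ")),
             "actinospec_format_error")
  colnames(values) <- features$column
  structure(list(values = values, features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d wells x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(dplyr::count(x$features, .data$compartment, .data$kernel))
  invisible(x)
}

#' @noRd
parse_feature_tags <- function(cols) {
  parts <- strsplit(cols, "__", fixed = TRUE)
  ok <- vapply(parts, length, 1L) >= 3L
  comp <- ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_)
  kern <- ifelse(ok, vapply(parts, `[`, "", 2L), NA_character_)
  name <- ifelse(ok, vapply(parts, function(p) paste(p[-(1:2)], collapse = "__"),
                            ""), cols)
  ok <- ok & comp %in% FEATURE_COMPARTMENTS & kern %in% FEATURE_KERNELS
  tibble::tibble(column = cols, name = name,
                 compartment = ifelse(ok, comp, NA_character_),
                 kernel = ifelse(ok, kern, NA_character_))
}

#' Read a feature table
#'
#' Wide, tab- or comma-delimited table whose first column holds well labels
#' and whose remaining header cells encode features. Tags are resolved from
#' the column-name prefix convention `compartment__kernel__name` first and
#' from an optional sidecar CSV (`column, compartment, kernel`) second.
#'
#' @param path delimited file (delimiter inferred from extension: `.tsv`/
#'   `.txt` tab, otherwise comma).
#' @param sidecar optional path of a tag sidecar CSV.
#' @return a [feature_table].
#' @export
read_feature_table <- function(path, sidecar = NULL) {
  delim <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  wells <- as.character(df[[1]])
  vals <- as.matrix(df[-1])
  tags <- parse_feature_tags(colnames(vals))
  if (!is.null(sidecar)) {
    sc <- readr::read_csv(sidecar, col_types = readr::cols(), progress = FALSE)
    i <- match(tags$column, sc$column)
    fill <- is.na(tags$compartment) & !is.na(i)
    tags$compartment[fill] <- sc$compartment[i[fill]]
    tags$kernel[fill] <- sc$kernel[i[fill]]
  }
  untagged <- tags$column[is.na(tags$compartment) | is.na(tags$kernel)]
  if (length(untagged) > 0)
    as_error(paste0("untaggable feature column(s): ",
                    paste(untagged, collapse = ", ")),
             "actinospec_format_error")
  rownames(vals) <- wells
  feature_table(vals, tags)
}

#' Write a feature table (prefix-tagged wide TSV)
#' @param ft a [feature_table].
#' @param path output file (`.tsv` recommended).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  cols <- with(ft$features, paste(compartment, kernel, name, sep = "__"))
  df <- tibble::as_tibble(ft$values, .name_repair = "minimal")
  names(df) <- cols
  df <- dplyr::bind_cols(tibble::tibble(well = rownames(ft$values)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# -- SpectralIrradiance -----------------------------------------------------

#' Construct / read a spectroradiometer spectrum
#'
#' Spectral irradiance on a strictly increasing, uniform wavelength grid
#' (1-nm spacing by default, as acquired by a double-monochromator
#' spectroradiometer).
#'
#' @param wavelength_nm wavelength grid in nm.
#' @param irradiance spectral irradiance in W m^-2 nm^-1 (values >= 0).
#' @param spacing_nm required grid spacing.
#' @return a tibble of class `spectral_irradiance`.
#' @export
spectral_irradiance <- function(wavelength_nm, irradiance, spacing_nm = 1) {
  d <- diff(wavelength_nm)
  if (length(d) == 0 || any(d <= 0) ||
      any(abs(d - spacing_nm) > 1e-9 * spacing_nm))
    as_error(sprintf("wavelength grid must be uniform at %g nm", spacing_nm),
             "actinospec_format_error")
  if (any(irradiance < 0))
    as_error("spectral irradiance must be >= 0", "actinospec_format_error")
  sp <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                       irradiance = as.numeric(irradiance))
  class(sp) <- c("spectral_irradiance", class(tibble::tibble()))
  sp
}

#' @rdname spectral_irradiance
#' @param path 2-column CSV (`wavelength_nm`, irradiance).
#' @export
read_spectrum <- function(path, spacing_nm = 1) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  spectral_irradiance(df[[1]], df[[2]], spacing_nm = spacing_nm)
}

# -- Spectrum results -------------------------------------------------------

#' Write a response/action spectrum result to CSV
#'
#' Emits the interchange columns `wavelength_nm, efficiency,
#' normalised_efficiency, n_wells, n_censored` at full double precision.
#' Response spectra (which have no censoring) write `n_censored = 0` and use
#' their per-wavelength point count as `n_wells`.
#'
#' @param spectrum a `response_spectrum` or `action_spectrum` tibble.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  n_col <- intersect(c("n_wells", "n_points", "n_features"), names(spectrum))
  out <- tibble::tibble(
    wavelength_nm = spectrum$wavelength_nm,
    efficiency = spectrum$efficiency,
    normalised_efficiency = spectrum$normalised_efficiency,
    n_wells = if (length(n_col) > 0) as.integer(spectrum[[n_col[1]]])
              else NA_integer_,
    n_censored = if ("n_censored" %in% names(spectrum))
                   as.integer(spectrum$n_censored) else 0L
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a spectrum result CSV written by [write_spectrum_csv()]
#' @param path CSV file.
#' @return a tibble with the interchange columns.
#' @export
read_spectrum_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    wavelength_nm = readr::col_double(), efficiency = readr::col_double(),
    normalised_efficiency = readr::col_double(),
    n_wells = readr::col_integer(), n_censored = readr::col_integer()
  ), progress = FALSE)
}
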