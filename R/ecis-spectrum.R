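# ECIS action spectra: time to the 60%-of-t0 common action, dose to action,
# reciprocal-dose efficiency, reference normalisation.

ECIS_PARAMETERS <- c(impedance = "z_ohm", resistance = "r_ohm",
                     capacitance = "c_farad")

#' Truncate ECIS traces at lamp-off
#'
#' Samples after the lamp is doused are removed so the post-exposure
#' recovery rise (cells re-adhering to the electrodes) cannot create
#' spurious crossings. A no-op for traces ending before `lamp_off_h`.
#'
#' @param traces an [ecis_traces] tibble.
#' @param lamp_off_h lamp-off time in hours (default 68).
#' @return the truncated [ecis_traces].
#' @export
truncate_at_lamp_off <- function(traces, lamp_off_h = 68) {
  out <- dplyr::filter(tibble::as_tibble(traces), .data$time_h <= lamp_off_h)
  ecis_traces(out, raw = FALSE, processing = attr(traces, "processing"))
}

#' Time to the common-action threshold of one trace
#'
#' First time a t0-normalised trace reaches the fraction-of-t0 level,
#' linearly interpolated between the bracketing samples (11-min sampling in
#' the study design). The first crossing counts even if the trace later
#' recovers. Returns `NA` (censored) if the level is never reached inside
#' the window.
#'
#' @param trace a single (well, frequency) [ecis_traces]; must be
#'   t0-normalised (first sample 1).
#' @param parameter `"impedance"`, `"resistance"` or `"capacitance"`.
#' @param fraction common-action level as a fraction of the t0 value
#'   (default 0.6, i.e. a 60% decrease threshold at 0.6 x t0).
#' @param window `c(t_start, t_stop)` in hours; only samples inside the
#'   window are considered (default `[0, 68]`, the lamp-on period).
#' @param direction `"decrease"` (default): first drop to
#'   `fraction * v(t0)`. `"increase"`: first rise to `v(t0) / fraction`,
#'   for parameters (e.g. capacitance at high frequency) that move upwards
#'   on cell loss.
#' @return crossing time in hours, or `NA_real_` if censored.
#' @export
time_to_threshold <- function(trace, parameter = c("impedance", "resistance",
                                                   "capacitance"),
                              fraction = 0.6, window = c(0, 68),
                              direction = c("decrease", "increase")) {
  parameter <- match.arg(parameter)
  direction <- match.arg(direction)
  tr <- tibble::as_tibble(trace)
  if (dplyr::n_distinct(tr$well, tr$frequency_hz) != 1)
    as_error("time_to_threshold expects a single (well, frequency) trace",
             "actinospec_domain_error")
  if (window[2] <= window[1])
    as_error("empty threshold window", "actinospec_domain_error")
  tr <- tr[tr$time_h >= window[1] & tr$time_h <= window[2], ]
  if (nrow(tr) == 0)
    as_error("no samples inside the threshold window",
             "actinospec_domain_error")
  v <- tr[[ECIS_PARAMETERS[parameter]]]
  t <- tr$time_h
  thr <- if (direction == "decrease") fraction * v[1] else v[1] / fraction
  hit <- if (direction == "decrease") v <= thr else v >= thr
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  t[i - 1] + (thr - v[i - 1]) * (t[i] - t[i - 1]) / (v[i] - v[i - 1])
}

#' Build an ECIS action spectrum
#'
#' Per exposed well at the analysis frequency: time to the common action
#' (60% of t0 by default, within the lamp-on window), dose to action
#' (irradiance x time), efficiency = 1/dose. Per wavelength: the mean
#' efficiency over uncensored wells, then normalisation to the reference
#' wavelength. Wavelengths whose wells are all censored are reported with
#' undefined efficiency and their censored count.
#'
#' @param traces t0-normalised (typically control-scaled) [ecis_traces].
#' @param map the matching [plate_map].
#' @param doses tibble `well, irradiance_w_m2` for the exposed wells (e.g.
#'   from [well_doses()]).
#' @param parameter,fraction,direction see [time_to_threshold()].
#' @param frequency_hz analysis frequency (default 16 kHz).
#' @param lamp_off_h end of the exposure window in hours (default 68).
#' @param reference_nm reference wavelength for normalisation (default 400).
#' @return an `action_spectrum` tibble: `wavelength_nm, time_to_action_h,
#'   dose_to_action_j_m2, efficiency, normalised_efficiency, n_wells,
#'   n_censored`, with `parameter`, `frequency_hz` and `reference_nm`
#'   attributes.
#' @export
build_action_spectrum <- function(traces, map, doses,
                                  parameter = c("impedance", "resistance",
                                                "capacitance"),
                                  frequency_hz = 16000, fraction = 0.6,
                                  lamp_off_h = 68, reference_nm = 400,
                                  direction = c("decrease", "increase")) {
  parameter <- match.arg(parameter)
  direction <- match.arg(direction)
  tr <- dplyr::filter(tibble::as_tibble(traces),
                      .data$frequency_hz == !!frequency_hz)
  if (nrow(tr) == 0)
    as_error(sprintf("no traces at %g Hz", frequency_hz),
             "actinospec_domain_error")
  pm <- tibble::as_tibble(map)
  ds <- tibble::as_tibble(doses)
  ex <- dplyr::filter(pm, .data$role == "exposed",
                      .data$well %in% unique(tr$well))
  per_well <- purrr::map_dfr(seq_len(nrow(ex)), function(i) {
    w <- ex$well[i]
    one <- tr[tr$well == w, ]
    tta <- time_to_threshold(
      ecis_traces(one, raw = FALSE), parameter = parameter,
      fraction = fraction, window = c(0, lamp_off_h), direction = direction)
    irr <- ds$irradiance_w_m2[match(w, ds$well)]
    if (is.na(irr))
      as_error(paste0("no dose entry for exposed well ", w),
               "actinospec_domain_error")
    dose <- if (is.na(tta)) NA_real_ else dose_at(irr, tta)
    tibble::tibble(well = w, wavelength_nm = ex$wavelength_nm[i],
                   time_to_action_h = tta, dose_to_action_j_m2 = dose,
                   efficiency = 1 / dose)
  })
  sp <- dplyr::summarise(
    dplyr::group_by(per_well, .data$wavelength_nm),
    time_to_action_h = mean(.data$time_to_action_h, na.rm = TRUE),
    dose_to_action_j_m2 = mean(.data$dose_to_action_j_m2, na.rm = TRUE),
    efficiency = mean(.data$efficiency, na.rm = TRUE),
    n_wells = dplyr::n(),
    n_censored = sum(is.na(.data$time_to_action_h)),
    .groups = "drop")
  sp$efficiency[sp$n_censored == sp$n_wells] <- NA_real_
  sp$time_to_action_h[is.nan(sp$time_to_action_h)] <- NA_real_
  sp$dose_to_action_j_m2[is.nan(sp$dose_to_action_j_m2)] <- NA_real_
  sp <- normalize_spectrum(sp, reference_nm)
  attr(sp, "parameter") <- parameter
  attr(sp, "frequency_hz") <- frequency_hz
  attr(sp, "per_well") <- per_well
  class(sp) <- unique(c("action_spectrum", class(sp)))
  sp
}
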