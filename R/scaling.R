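# Control-based scaling and t0 normalisation shared by all stages.

#' Min-max scale a measurement between control references
#'
#' `((x - min_ref) / (max_ref - min_ref)) * 100`: 0 corresponds to the
#' positive (fully affected) control, 100 to the negative (untreated)
#' control. Values outside the control range are retained (they may fall
#' outside 0-100); clipping would bias downstream slope fits.
#'
#' @param x measurement(s).
#' @param min_ref positive-control reference (maps to 0).
#' @param max_ref negative-control reference (maps to 100); must exceed
#'   `min_ref`.
#' @return percent-of-control-range values.
#' @export
minmax_scale <- function(x, min_ref, max_ref) {
  if (any(max_ref <= min_ref))
    as_error("degenerate controls: max_ref must exceed min_ref",
             "actinospec_degenerate_error")
  (x - min_ref) / (max_ref - min_ref) * 100
}

#' Scale a viability plate between lysed and dark controls
#'
#' The positive reference is the mean raw fluorescence of the plate's lysed
#' control wells, the negative reference the mean of its dark (no-UVR)
#' control wells; every well is min-max scaled between them.
#'
#' @param plate a [viability_plate].
#' @param map the matching [plate_map] (well-matched by label).
#' @return tibble `well, role, wavelength_nm, nd_od, viability_percent`.
#' @export
scale_viability_plate <- function(plate, map) {
  df <- dplyr::inner_join(tibble::as_tibble(plate), tibble::as_tibble(map),
                          by = "well")
  lysed <- df$rfu[df$role == "lysed_control"]
  dark <- df$rfu[df$role == "dark_control"]
  if (length(lysed) == 0 || length(dark) == 0)
    as_error("plate needs at least one lysed_control and one dark_control well",
             "actinospec_domain_error")
  df$viability_percent <- minmax_scale(df$rfu, mean(lysed), mean(dark))
  dplyr::select(df, "well", "role", "wavelength_nm", "nd_od",
                "viability_percent")
}

#' Normalise ECIS traces to time zero
#'
#' Divides each electrical parameter of each (well, frequency) trace by its
#' value at the first sample, so every trace starts at exactly 1 and becomes
#' unitless. Invariant to any constant rescaling of the raw trace.
#'
#' @param traces an [ecis_traces] tibble (values at t0 must be non-zero and,
#'   for raw traces, positive).
#' @return an [ecis_traces] tibble with `"t0_normalised"` appended to its
#'   processing record.
#' @export
t0_normalize <- function(traces) {
  tr <- tibble::as_tibble(traces)
  norm1 <- function(v) {
    if (!is.finite(v[1]) || v[1] <= 0)
      as_error("t0 value must be > 0 for t0 normalisation",
               "actinospec_domain_error")
    v / v[1]
  }
  tr <- dplyr::group_by(tr, .data$well, .data$frequency_hz)
  tr <- dplyr::mutate(tr,
    z_ohm = norm1(.data$z_ohm),
    r_ohm = norm1(.data$r_ohm),
    c_farad = norm1(.data$c_farad))
  tr <- dplyr::ungroup(tr)
  ecis_traces(tr, raw = FALSE,
              processing = c(attr(traces, "processing"), "t0_normalised"))
}

#' @noRd
align_control <- function(times, ctrl, col, max_gap_h) {
  mids <- head(ctrl$time_h, -1) + diff(ctrl$time_h) / 2
  i <- findInterval(times, mids) + 1L
  i <- pmin(pmax(i, 1L), nrow(ctrl))
  if (any(abs(ctrl$time_h[i] - times) > max_gap_h))
    as_error("control trace does not cover the data trace (alignment gap)",
             "actinospec_alignment_error")
  ctrl[[col]][i]
}

#' Scale ECIS traces between no-cell and dark controls
#'
#' Per time point, each parameter is min-max scaled between the no-cell
#' (positive) and dark (negative) control traces on a fraction scale (0 =
#' no-cell, 1 = dark; no x100), then t0-normalised. Controls are aligned to
#' each data sample by nearest time with a maximum gap of one sampling
#' interval. The order of operations (scale, then t0) is recorded in the
#' output's processing attribute; `t0_first = TRUE` reverses it for
#' sensitivity analysis.
#'
#' @param traces data [ecis_traces] (any number of wells; must share the
#'   controls' frequency).
#' @param no_cell_ctrl,dark_ctrl single-trace [ecis_traces] (one well each,
#'   e.g. from [control_trace()]).
#' @param max_gap_h maximum alignment gap in hours (default one 11-min
#'   interval).
#' @param t0_first normalise to t0 before control scaling instead of after.
#' @return an [ecis_traces] tibble on the fraction scale, t0-normalised.
#' @export
scale_ecis <- function(traces, no_cell_ctrl, dark_ctrl,
                       max_gap_h = 11 / 60, t0_first = FALSE) {
  tr <- tibble::as_tibble(traces)
  nc <- tibble::as_tibble(no_cell_ctrl)
  dk <- tibble::as_tibble(dark_ctrl)
  if (dplyr::n_distinct(nc$well) != 1 || dplyr::n_distinct(dk$well) != 1)
    as_error("control traces must each contain a single well",
             "actinospec_domain_error")
  if (max(nc$time_h) + max_gap_h < max(tr$time_h) ||
      max(dk$time_h) + max_gap_h < max(tr$time_h))
    as_error("control trace shorter than data trace",
             "actinospec_alignment_error")
  if (t0_first) {
    tr <- t0_normalize(ecis_traces(tr, raw = FALSE,
                                   processing = attr(traces, "processing")))
    nc <- t0_normalize(ecis_traces(nc, raw = FALSE))
    dk <- t0_normalize(ecis_traces(dk, raw = FALSE))
  }
  scale_col <- function(x, times, col) {
    lo <- align_control(times, nc, col, max_gap_h)
    hi <- align_control(times, dk, col, max_gap_h)
    if (any(hi <= lo))
      as_error("controls are degenerate (dark <= no-cell) at some time point",
               "actinospec_degenerate_error")
    (x - lo) / (hi - lo)
  }
  out <- dplyr::group_by(tibble::as_tibble(tr), .data$well, .data$frequency_hz)
  out <- dplyr::mutate(out,
    z_ohm = scale_col(.data$z_ohm, .data$time_h, "z_ohm"),
    r_ohm = scale_col(.data$r_ohm, .data$time_h, "r_ohm"),
    c_farad = scale_col(.data$c_farad, .data$time_h, "c_farad"))
  out <- dplyr::ungroup(out)
  steps <- c(attr(traces, "processing"),
             if (t0_first) c("t0_normalised", "control_scaled")
             else "control_scaled")
  out <- ecis_traces(out, raw = FALSE, processing = steps)
  if (t0_first) out else t0_normalize(out)
}

#' Average the control wells of a role into a single control trace
#'
#' @param traces raw [ecis_traces] containing the control wells.
#' @param map the matching [plate_map].
#' @param role control role to aggregate (`"no_cell_control"` or
#'   `"dark_control"`).
#' @param frequency_hz frequency to select.
#' @return a single-well [ecis_traces] (well label = role) whose values are
#'   the per-time arithmetic means over the role's wells.
#' @export
control_trace <- function(traces, map, role, frequency_hz = 16000) {
  wells <- tibble::as_tibble(map)$well[tibble::as_tibble(map)$role == role]
  tr <- dplyr::filter(tibble::as_tibble(traces),
                      .data$well %in% wells,
                      .data$frequency_hz == !!frequency_hz)
  if (nrow(tr) == 0)
    as_error(paste0("no traces found for control role ", role),
             "actinospec_domain_error")
  agg <- dplyr::summarise(
    dplyr::group_by(tr, .data$time_h),
    z_ohm = mean(.data$z_ohm), r_ohm = mean(.data$r_ohm),
    c_farad = mean(.data$c_farad), .groups = "drop")
  agg$well <- role
  agg$frequency_hz <- frequency_hz
  ecis_traces(agg, raw = FALSE, processing = attr(traces, "processing"))
}
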