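# Viability response spectrum: per-wavelength irradiance-viability OLS,
# squared slopes, reference-wavelength normalisation.

#' Construct a response spectrum container
#' @noRd
response_spectrum <- function(df, reference_nm = NA_real_) {
  df <- tibble::as_tibble(df)
  attr(df, "reference_nm") <- reference_nm
  class(df) <- unique(c("response_spectrum", class(df)))
  df
}

#' Ordinary least squares of scaled viability on irradiance
#'
#' Fits `viability ~ irradiance` by OLS on all replicate points (technical
#' and biological replicates pooled, not on condition means).
#'
#' @param points data frame with columns `irradiance` (any consistent unit)
#'   and `viability_percent`; needs >= 3 points spanning >= 2 distinct
#'   irradiances.
#' @return list `slope` (percent viability per irradiance unit),
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_irradiance_slope <- function(points) {
  x <- points$irradiance
  y <- points$viability_percent
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    as_error("need at least 3 points for a slope fit",
             "actinospec_domain_error")
  if (length(unique(x)) < 2)
    as_error("all irradiances identical: singular design",
             "actinospec_domain_error")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(x))
}

#' Squared-slope efficiency with sign bookkeeping
#'
#' Damage slopes are negative (viability falls with irradiance); squaring
#' makes efficiencies positive so spectra can be plotted logarithmically.
#' Positive ("protective") slopes are flagged: their square would masquerade
#' as toxicity on a log spectrum, so they are excluded from normalised
#' spectra by default and surfaced in diagnostics.
#'
#' @param slope finite regression slope.
#' @return list `efficiency` (= slope^2) and `sign_flag` (`"negative"`,
#'   `"zero"` or `"protective"`).
#' @export
slope_to_efficiency <- function(slope) {
  if (!is.finite(slope)) as_error("slope must be finite",
                                  "actinospec_domain_error")
  list(efficiency = slope^2,
       sign_flag = if (slope > 0) "protective"
                   else if (slope < 0) "negative" else "zero")
}

#' Normalise a spectrum to a reference wavelength
#'
#' Divides every efficiency by the efficiency at the reference wavelength,
#' so the reference maps to exactly 1. Shared by the viability, ECIS and
#' imaging stages. Idempotent.
#'
#' @param spectrum a spectrum tibble with columns `wavelength_nm` and
#'   `efficiency` (a `normalised_efficiency` column is added/overwritten).
#' @param reference_nm reference wavelength; must be present with a
#'   positive, non-missing efficiency. The viability stage uses 405 nm, the
#'   ECIS and imaging stages 400 nm by convention.
#' @return the spectrum with `normalised_efficiency` and a `reference_nm`
#'   attribute.
#' @export
normalize_spectrum <- function(spectrum, reference_nm = 405) {
  i <- which(spectrum$wavelength_nm == reference_nm)
  if (length(i) != 1)
    as_error(sprintf("reference wavelength %g nm not present", reference_nm),
             "actinospec_domain_error")
  ref <- spectrum$efficiency[i]
  if (!is.finite(ref) || ref <= 0)
    as_error("reference efficiency is zero or undefined",
             "actinospec_domain_error")
  spectrum$normalised_efficiency <- spectrum$efficiency / ref
  attr(spectrum, "reference_nm") <- reference_nm
  spectrum
}

#' Build the viability response spectrum
#'
#' Pipeline over one or more plates: control-scale each plate between its
#' lysed and dark controls, pool all exposed replicate wells per wavelength,
#' fit scaled viability against irradiance by OLS, square the slopes, and
#' normalise to the reference wavelength. Wavelengths observed at fewer
#' than two irradiance levels are excluded with a warning; wavelengths with
#' protective (positive) slopes keep their efficiency in the table but are
#' excluded from the normalised column by default.
#'
#' @param plates list of [viability_plate]s.
#' @param maps list of matching [plate_map]s (same length/order).
#' @param irradiance `"relative"` (default) uses `10^(-nd_od)` as the
#'   regression axis (full intensity = 1) so slopes read as percent per
#'   full-intensity unit; `"absolute"` uses `doses`.
#' @param doses optional tibble `well, irradiance_w_m2` (per plate: a list
#'   matching `plates`) for the absolute axis.
#' @param reference_nm reference wavelength (default 405).
#' @param keep_protective include protective wavelengths in normalisation
#'   (default `FALSE`).
#' @return a `response_spectrum` tibble: `wavelength_nm, slope, slope_sign,
#'   efficiency, normalised_efficiency, n_points, r_squared`.
#' @export
build_viability_spectrum <- function(plates, maps,
                                     irradiance = c("relative", "absolute"),
                                     doses = NULL, reference_nm = 405,
                                     keep_protective = FALSE) {
  irradiance <- match.arg(irradiance)
  if (inherits(plates, "viability_plate")) plates <- list(plates)
  if (inherits(maps, "plate_map")) maps <- list(maps)
  stopifnot(length(plates) == length(maps))
  pts <- purrr::map2_dfr(seq_along(plates), plates, function(i, plate) {
    scaled <- scale_viability_plate(plate, maps[[i]])
    ex <- dplyr::filter(scaled, .data$role == "exposed")
    if (nrow(ex) == 0) return(ex[0, ])
    ex$irradiance <- if (irradiance == "relative") {
      nd_transmittance(ex$nd_od)
    } else {
      if (is.null(doses)) as_error("absolute axis requires doses",
                                   "actinospec_domain_error")
      d <- tibble::as_tibble(doses[[i]])
      d$irradiance_w_m2[match(ex$well, d$well)]
    }
    ex
  })
  if (nrow(pts) == 0) {
    return(response_spectrum(tibble::tibble(
      wavelength_nm = numeric(), slope = numeric(), slope_sign = character(),
      efficiency = numeric(), normalised_efficiency = numeric(),
      n_points = integer(), r_squared = numeric()), reference_nm))
  }
  fits <- dplyr::group_modify(
    dplyr::group_by(pts, .data$wavelength_nm),
    function(g, key) {
      if (length(unique(g$irradiance)) < 2) {
        rlang::warn(sprintf(
          "wavelength %g nm has < 2 irradiance levels; excluded",
          key$wavelength_nm))
        return(tibble::tibble())
      }
      f <- fit_irradiance_slope(
        tibble::tibble(irradiance = g$irradiance,
                       viability_percent = g$viability_percent))
      e <- slope_to_efficiency(f$slope)
      tibble::tibble(slope = f$slope, slope_sign = e$sign_flag,
                     efficiency = e$efficiency,
                     n_points = f$n, r_squared = f$r_squared)
    })
  fits <- dplyr::ungroup(fits)
  sp <- normalize_spectrum(fits, reference_nm)
  if (!keep_protective)
    sp$normalised_efficiency[sp$slope_sign == "protective"] <- NA_real_
  response_spectrum(
    dplyr::select(sp, "wavelength_nm", "slope", "slope_sign", "efficiency",
                  "normalised_efficiency", "n_points", "r_squared"),
    reference_nm)
}
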