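# Dosimetry: ND attenuation, band irradiance, dose arithmetic.
# Units throughout: time in hours, irradiance in W m^-2, dose in J m^-2
# (SI seconds enter only through the single conversion in dose_at()).

#' Transmittance of a neutral-density filter
#'
#' @param od optical density (>= 0). The exposure design uses OD 0 (full
#'   intensity), 0.2 and 0.4.
#' @return fractional transmittance `10^(-od)` in (0, 1].
#' @export
#' @examples
#' nd_transmittance(0.2)            # ~0.631
#' 1 / nd_transmittance(0.2)        # the "1.6-fold" intensity step
nd_transmittance <- function(od) {
  if (any(od < 0)) as_error("optical density must be >= 0",
                            "actinospec_domain_error")
  10^(-od)
}

#' Band-integrated irradiance from a source spectrum
#'
#' Trapezoidal integral of spectral irradiance over
#' `[centre - width/2, centre + width/2]`; the band must lie inside the
#' spectrum's wavelength grid. Band edges falling between grid points are
#' handled by linear interpolation of the spectrum at the edges.
#'
#' @param spectrum a [spectral_irradiance].
#' @param centre_nm band centre in nm.
#' @param width_nm band width in nm (default 10, the nominal bandpass width).
#' @return band irradiance in W m^-2.
#' @export
band_irradiance <- function(spectrum, centre_nm, width_nm = 10) {
  lo <- centre_nm - width_nm / 2
  hi <- centre_nm + width_nm / 2
  wl <- spectrum$wavelength_nm
  if (lo < min(wl) || hi > max(wl))
    as_error("band extends outside the spectrum grid",
             "actinospec_domain_error")
  inside <- wl > lo & wl < hi
  x <- c(lo, wl[inside], hi)
  y <- approx(wl, spectrum$irradiance, xout = x)$y
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Radiant exposure (dose) from irradiance and duration
#'
#' @param irradiance_w_m2 irradiance in W m^-2 (>= 0), assumed constant over
#'   the exposure (continuous lamp).
#' @param time_h exposure duration in hours (>= 0).
#' @return dose in J m^-2: `irradiance_w_m2 * time_h * 3600`.
#' @export
#' @examples
#' dose_at(10, 40)   # 1.44e6 J m^-2
dose_at <- function(irradiance_w_m2, time_h) {
  if (any(irradiance_w_m2 < 0) || any(time_h < 0))
    as_error("irradiance and time must be >= 0", "actinospec_domain_error")
  irradiance_w_m2 * time_h * 3600
}

#' Per-well exposure doses from a plate map
#'
#' Combines per-wavelength full-intensity band irradiances with each well's
#' ND attenuation and the exposure duration.
#'
#' @param map a [plate_map].
#' @param band_irradiance_w_m2 named numeric vector: full-intensity band
#'   irradiance (W m^-2) per wavelength (names = band centre in nm).
#' @param duration_h exposure duration in hours.
#' @return tibble `well, wavelength_nm, nd_od, irradiance_w_m2, duration_h,
#'   dose_j_m2` for exposed wells.
#' @export
well_doses <- function(map, band_irradiance_w_m2, duration_h) {
  ex <- dplyr::filter(tibble::as_tibble(map), .data$role == "exposed")
  full <- band_irradiance_w_m2[as.character(ex$wavelength_nm)]
  if (any(is.na(full)))
    as_error("band irradiance missing for some exposed wavelengths",
             "actinospec_domain_error")
  irr <- unname(full) * nd_transmittance(ex$nd_od)
  tibble::tibble(
    well = ex$well, wavelength_nm = ex$wavelength_nm, nd_od = ex$nd_od,
    irradiance_w_m2 = irr, duration_h = duration_h,
    dose_j_m2 = dose_at(irr, duration_h)
  )
}
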