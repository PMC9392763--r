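# High-content-imaging response spectra: per-condition feature aggregation,
# dark-control normalisation, per-feature irradiance slopes, group spectra
# by probe compartment and texture kernel.

#' Aggregate a feature table to per-condition means
#'
#' Arithmetic mean of each feature over the wells of every
#' (wavelength, ND) exposure condition, plus one row per control role.
#' Missing well values are skipped (mean of available wells).
#'
#' @param table a [feature_table].
#' @param map the matching [plate_map]; every exposed well of the table
#'   must be mapped.
#' @return a list of class `hci_aggregate`: `values` (conditions x features
#'   matrix), `conditions` (tibble `role, wavelength_nm, nd_od`),
#'   `features` (tag tibble).
#' @export
aggregate_wells <- function(table, map) {
  pm <- tibble::as_tibble(map)
  wells <- rownames(table$values)
  idx <- match(wells, pm$well)
  if (any(is.na(idx)))
    as_error(paste0("unmapped well(s) in feature table: ",
                    paste(wells[is.na(idx)], collapse = ", ")),
             "actinospec_domain_error")
  cond <- pm[idx, c("role", "wavelength_nm", "nd_od")]
  key <- paste(cond$role, cond$wavelength_nm, cond$nd_od, sep = "|")
  groups <- split(seq_along(key), key)
  vals <- t(vapply(groups, function(i) {
    colMeans(table$values[i, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(table$values))))
  first <- vapply(groups, `[`, 1L, 1L)
  conditions <- cond[first, ]
  o <- order(conditions$role != "exposed", conditions$wavelength_nm,
             conditions$nd_od)
  structure(list(values = vals[o, , drop = FALSE],
                 conditions = tibble::as_tibble(conditions[o, ]),
                 features = table$features),
            class = "hci_aggregate")
}

#' Normalise aggregated features to the dark control
#'
#' Divides every condition's feature mean by the dark-control mean of the
#' same feature. Features whose dark-control value is zero are dropped with
#' a warning (their fraction-of-dark is undefined).
#'
#' @param agg an `hci_aggregate` from [aggregate_wells()] containing a
#'   `dark_control` row.
#' @return the aggregate on the fraction-of-dark scale (dark row = 1).
#' @export
normalize_to_dark <- function(agg) {
  i <- which(agg$conditions$role == "dark_control")
  if (length(i) == 0)
    as_error("no dark_control condition present", "actinospec_domain_error")
  dark <- colMeans(agg$values[i, , drop = FALSE])
  zero <- !is.finite(dark) | dark == 0
  if (any(zero)) {
    rlang::warn(paste0("dropping feature(s) with zero dark control: ",
                       paste(agg$features$column[zero], collapse = ", ")))
  }
  keep <- !zero
  agg$values <- sweep(agg$values[, keep, drop = FALSE], 2, dark[keep], "/")
  agg$features <- agg$features[keep, ]
  agg
}

#' Per-feature irradiance slopes of dark-normalised aggregates
#'
#' For every (wavelength, feature) cell, the OLS slope of the normalised
#' condition means against relative irradiance `10^(-nd_od)` over the
#' irradiance ladder (full, ND 0.2, ND 0.4 in the study design). This is
#' the per-column analogue of [fit_irradiance_slope()] on condition means,
#' computed in closed form.
#'
#' @param agg a dark-normalised `hci_aggregate` (see [normalize_to_dark()]);
#'   aggregates from several biological replicates can be averaged first
#'   with [combine_aggregates()].
#' @param blank optional list `values` (dark-well x feature matrix of
#'   fraction-of-dark values), used to fit a null "blank" item: dark wells
#'   are assigned the irradiance ladder cyclically in well order, giving
#'   near-zero slopes. Reported as row `"blank"`.
#' @return a list of class `feature_coefficients`: `coef` (wavelength x
#'   feature slope matrix, rownames = wavelength or `"blank"`), `r_squared`
#'   (same shape), `n_levels` (irradiance levels per wavelength),
#'   `features` (tag tibble).
#' @export
fit_feature_slopes <- function(agg, blank = NULL) {
  ex <- agg$conditions$role == "exposed"
  if (!any(ex))
    as_error("no exposed conditions to fit", "actinospec_domain_error")
  cond <- agg$conditions[ex, ]
  vals <- agg$values[ex, , drop = FALSE]
  wls <- sort(unique(cond$wavelength_nm))
  fit_rows <- function(Y, x) {
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0)
      as_error("all irradiances identical: singular design",
               "actinospec_domain_error")
    slope <- colSums(Y * xc) / sxx
    fitted <- outer(xc, slope)
    resid <- sweep(Y, 2, colMeans(Y)) - fitted
    ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2 <- ifelse(ss_tot > 0, 1 - colSums(resid^2) / ss_tot, NA_real_)
    list(slope = slope, r2 = r2)
  }
  out <- lapply(wls, function(w) {
    i <- which(cond$wavelength_nm == w)
    if (length(unique(cond$nd_od[i])) < 2)
      as_error(sprintf("wavelength %g nm has < 2 irradiance levels", w),
               "actinospec_domain_error")
    fit_rows(vals[i, , drop = FALSE], nd_transmittance(cond$nd_od[i]))
  })
  coef <- do.call(rbind, lapply(out, `[[`, "slope"))
  r2 <- do.call(rbind, lapply(out, `[[`, "r2"))
  rn <- as.character(wls)
  n_levels <- vapply(wls, function(w)
    length(unique(cond$nd_od[cond$wavelength_nm == w])), 1L)
  if (!is.null(blank)) {
    ladder <- sort(unique(nd_transmittance(cond$nd_od)), decreasing = TRUE)
    x <- ladder[(seq_len(nrow(blank$values)) - 1L) %% length(ladder) + 1L]
    b <- fit_rows(blank$values, x)
    coef <- rbind(coef, b$slope)
    r2 <- rbind(r2, b$r2)
    rn <- c(rn, "blank")
    n_levels <- c(n_levels, length(ladder))
  }
  rownames(coef) <- rn
  rownames(r2) <- rn
  structure(list(coef = coef, r_squared = r2,
                 n_levels = setNames(n_levels, rn), features = agg$features),
            class = "feature_coefficients")
}

#' Average dark-normalised aggregates over biological replicates
#'
#' @param aggs list of dark-normalised `hci_aggregate`s sharing conditions
#'   and features.
#' @return one `hci_aggregate` of condition-matched means.
#' @export
combine_aggregates <- function(aggs) {
  if (length(aggs) == 1) return(aggs[[1]])
  ref <- aggs[[1]]
  keyf <- function(a) paste(a$conditions$role, a$conditions$wavelength_nm,
                            a$conditions$nd_od, sep = "|")
  k0 <- keyf(ref)
  for (a in aggs[-1]) {
    if (!identical(sort(k0), sort(keyf(a))) ||
        !identical(ref$features$column, a$features$column))
      as_error("aggregates do not share conditions/features",
               "actinospec_domain_error")
  }
  stacks <- lapply(aggs, function(a) a$values[match(k0, keyf(a)), , drop = FALSE])
  ref$values <- Reduce(`+`, stacks) / length(stacks)
  ref
}

#' Group response spectrum from feature coefficients
#'
#' Per wavelength, the mean of squared slopes over the selected features
#' (averaging after squaring keeps opposing signs from cancelling), then
#' normalisation to the reference wavelength. `compartment`/`kernel`
#' `NULL` means "all" for that tag; any `"blank"` coefficient row is
#' excluded from the spectrum.
#'
#' @param coeffs a `feature_coefficients`.
#' @param compartment optional compartment filter (`"nucleus"`,
#'   `"mitochondria"`, `"ros"`, `"pi_cm"`).
#' @param kernel optional kernel filter (e.g. `"ser_spot"`, `"count"`).
#' @param reference_nm reference wavelength (default 400).
#' @return a `response_spectrum` tibble `wavelength_nm, efficiency,
#'   normalised_efficiency, n_features`.
#' @export
group_spectrum <- function(coeffs, compartment = NULL, kernel = NULL,
                           reference_nm = 400) {
  sel <- rep(TRUE, nrow(coeffs$features))
  if (!is.null(compartment))
    sel <- sel & coeffs$features$compartment %in% compartment
  if (!is.null(kernel))
    sel <- sel & coeffs$features$kernel %in% kernel
  if (!any(sel))
    as_error(sprintf("no features match selector (compartment = %s, kernel = %s)",
                     paste(compartment %||% "all", collapse = "/"),
                     paste(kernel %||% "all", collapse = "/")),
             "actinospec_domain_error")
  rows <- rownames(coeffs$coef) != "blank"
  sq <- coeffs$coef[rows, sel, drop = FALSE]^2
  sp <- tibble::tibble(
    wavelength_nm = as.numeric(rownames(coeffs$coef)[rows]),
    efficiency = unname(rowMeans(sq)),
    n_features = sum(sel))
  sp <- normalize_spectrum(sp, reference_nm)
  response_spectrum(sp, reference_nm)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end imaging coefficients from feature tables
#'
#' Convenience pipeline over biological replicates: aggregate each plate's
#' wells, normalise to the plate's dark control, average the normalised
#' aggregates, and fit per-feature irradiance slopes (optionally with the
#' blank-control null item).
#'
#' @param tables list of [feature_table]s (one per plate).
#' @param maps list of matching [plate_map]s.
#' @param include_blank add a `"blank"` coefficient row fitted from the
#'   dark-control wells (default `FALSE`).
#' @return a `feature_coefficients`.
#' @export
build_hci_coefficients <- function(tables, maps, include_blank = FALSE) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  if (inherits(maps, "plate_map")) maps <- list(maps)
  stopifnot(length(tables) == length(maps))
  aggs <- purrr::map2(tables, maps,
                      function(tb, pm) normalize_to_dark(aggregate_wells(tb, pm)))
  agg <- combine_aggregates(aggs)
  blank <- NULL
  if (include_blank) {
    mats <- purrr::map2(tables, maps, function(tb, pm) {
      pm <- tibble::as_tibble(pm)
      dw <- intersect(rownames(tb$values),
                      pm$well[pm$role == "dark_control"])
      v <- tb$values[dw, agg$features$column, drop = FALSE]
      sweep(v, 2, colMeans(v, na.rm = TRUE), "/")
    })
    blank <- list(values = do.call(rbind, mats))
  }
  fit_feature_slopes(agg, blank = blank)
}
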