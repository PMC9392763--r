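# Small in-code fixtures shared across test files.

# write a CSV string to a temp file and return its path
tmp_csv <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a minimal valid plate map: 2 exposed wells, one dark, one lysed
tiny_map <- function() {
  plate_map(well = c("A01", "A02", "H11", "H12"),
            role = c("exposed", "exposed", "dark_control", "lysed_control"),
            wavelength_nm = c(350, 350, NA, NA),
            nd_od = c(0, 0.2, 0, 0))
}

# build a single-well ECIS trace tibble from time/value vectors
# (z = r = value, capacitance scaled into farads)
tiny_trace <- function(time_h, value, well = "A01", frequency_hz = 16000,
                       raw = FALSE) {
  ecis_traces(tibble::tibble(
    well = well, frequency_hz = frequency_hz, time_h = time_h,
    z_ohm = value, r_ohm = value, c_farad = value * 1e-9), raw = raw)
}

# feature table with explicit values, prefix-tagged columns
tiny_feature_table <- function(values, compartments, kernels) {
  n <- ncol(values)
  schema <- tibble::tibble(
    column = sprintf("%s__%s__f%02d", compartments, kernels, seq_len(n)),
    name = sprintf("f%02d", seq_len(n)),
    compartment = compartments, kernel = kernels)
  feature_table(values, schema)
}
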