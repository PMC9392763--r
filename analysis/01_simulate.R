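#!/usr/bin/env Rscript
# Stage 1 -- simulate the study's raw data from the documented preset.
#
# Emits, under results/simulated/: viability plates + plate maps (3
# biological replicates, two physical plates each), one ECIS plate (12
# bands x 4 wells at 16 kHz, plus controls) with its dose table, and three
# imaging feature-table plates (380 tagged features). All downstream
# stages read only these files.

library(actinospec)

seed <- as.integer(Sys.getenv("ACTINOSPEC_SEED", "42"))
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
profile <- preset("paper-profile")

message("simulating viability plates (seed ", seed, ")")
via <- gen_viability_plates(profile, seed = seed)
for (i in seq_along(via$plates)) {
  id <- attr(via$maps[[i]], "plate_id")
  write_viability_plate(via$plates[[i]],
                        file.path(out, sprintf("viability_%s.csv", id)))
  write_plate_map(via$maps[[i]],
                  file.path(out, sprintf("viability_%s_map.csv", id)))
}

message("simulating ECIS traces")
ecis <- gen_ecis_traces(profile, seed = seed + 1L)
write_ecis_long(ecis$traces, file.path(out, "ecis_traces.csv.gz"))
write_plate_map(ecis$map, file.path(out, "ecis_map.csv"))
readr::write_csv(ecis$doses, file.path(out, "ecis_doses.csv"))

message("simulating imaging feature tables")
hci <- gen_feature_table(profile, seed = seed + 2L)
for (i in seq_along(hci$tables)) {
  id <- attr(hci$maps[[i]], "plate_id")
  write_feature_table(hci$tables[[i]],
                      file.path(out, sprintf("features_%s.tsv", id)))
  write_plate_map(hci$maps[[i]],
                  file.path(out, sprintf("features_%s_map.csv", id)))
}

message("wrote ", length(list.files(out)), " files under ", out)
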