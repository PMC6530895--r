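#!/usr/bin/env Rscript
# Ground-truth characterisation: select the TVG form from the calibration
# sphere, correct the ground-truthing transect, detect schools with the
# conservative minima (3 m length, 1.5 m thickness), and compare the
# detected morphology against the planted truth.
#
# Requires analysis/01_simulate_inputs.R to have been run.

suppressMessages(library(echoprey))

in_dir <- file.path("scratch", "analysis", "input")
out_dir <- file.path("results", "ground_truth")

cfg <- pipeline_config(
  out_dir = out_dir, preset = "ground_truth", seed = 20150522,
  ping_csv = file.path(in_dir, "ground_truth_pings.csv"),
  sphere_csv = file.path(in_dir, "sphere_pings.csv"),
  sphere_track_csv = file.path(in_dir, "sphere_track.csv"),
  ctd = list(temperature = 13, salinity = 35, pH = 8, frequency_khz = 200,
             depth = 10)
)
res <- run_ground_truth(cfg)

truth <- read.csv(file.path(in_dir, "ground_truth_truth.csv"))
message(sprintf("TVG: selected %dlog; correlation map: %s",
                res$tvg_fit$xi_selected,
                paste(names(res$tvg_fit$correlation_by_xi),
                      round(res$tvg_fit$correlation_by_xi, 3),
                      sep = "=", collapse = ", ")))
message(sprintf("schools: %d detected vs %d planted", nrow(res$schools),
                nrow(truth)))
cmp <- merge(
  data.frame(planted_depth = truth$center_depth, length_true = truth$length,
             thickness_true = truth$thickness, key = round(truth$center_depth)),
  data.frame(key = round(res$schools$D), L = res$schools$L,
             T = res$schools$T, Lc = res$schools$Lc, Tc = res$schools$Tc),
  by = "key"
)
write.csv(cmp[, -1], file.path(out_dir, "recovery_vs_truth.csv"),
          row.names = FALSE)
message(sprintf("mean |L - true| = %.2f m, mean |T - true| = %.2f m",
                mean(abs(cmp$L - cmp$length_true)),
                mean(abs(cmp$T - cmp$thickness_true))))
message("outputs in ", out_dir)
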