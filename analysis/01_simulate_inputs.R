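#!/usr/bin/env Rscript
# Simulate the full synthetic field campaign that the later analysis steps
# consume: a ground-truthing transect with planted schools of known
# morphology, a calibration-sphere drop, and a set of predator-prey survey
# transects with predator counts generated from the prey field.
#
# Outputs (CSV bundles) go under scratch/analysis/input/.

suppressMessages(library(echoprey))

seed <- 20150522
in_dir <- file.path("scratch", "analysis", "input")
dir.create(file.path(in_dir, "survey_pings"), recursive = TRUE,
           showWarnings = FALSE)

message("-- ground-truthing transect: 4 planted schools, seabed at 25 m")
cast <- ctd_cast(temperature = 13, salinity = 35, pH = 8,
                 frequency_khz = 200, depth = 10)
alpha <- absorption_coefficient(cast)
gt_scene <- synthetic_scene(
  schools = list(true_school(150, 8, 18, 3, core_db = -20),
                 true_school(420, 14, 30, 4, core_db = -24),
                 true_school(700, 19, 6, 2, core_db = -28),
                 true_school(900, 6, 10, 2.5, core_db = -26)),
  n_pings = 1100, seabed_depth = 25, noise_floor_db = -60, noise_sd_db = 2,
  tvg_exponent_true = 10, absorption_true = alpha, rng_seed = seed
)
gt <- render_echogram(gt_scene)
write_ping_csv(gt$records, file.path(in_dir, "ground_truth_pings.csv"))
write.csv(gt$truth, file.path(in_dir, "ground_truth_truth.csv"),
          row.names = FALSE)

message("-- calibration-sphere drop: 300 on-axis observations, 3-35 m")
set.seed(seed)
drop <- make_sphere_drop(runif(300, 3.2, 35), tvg_exponent_true = 10,
                         absorption_true = alpha, noise_sd_db = 1,
                         seed = seed)
write_ping_csv(drop$records, file.path(in_dir, "sphere_pings.csv"))
write.csv(drop$annotations, file.path(in_dir, "sphere_track.csv"),
          row.names = FALSE)

message("-- predator-prey surveys: 40 transects over 4 regions")
set.seed(seed + 1)
n_surveys <- 40
regions <- rep(c("AK", "BF", "LL", "ME"), each = 10)
dates <- rep(as.Date(c("2015-02-10", "2015-09-10", "2016-02-10",
                       "2016-09-10")), length.out = n_surveys)
n_schools <- rpois(n_surveys, ifelse(format(dates, "%m") == "02", 3, 1))
truth_rows <- list()
for (k in seq_len(n_surveys)) {
  sc <- random_scene(n_schools = n_schools[k], n_pings = 420,
                     seabed_depth = 22, max_range = 26,
                     noise_floor_db = -60, rng_seed = seed + 10 + k,
                     survey_id = sprintf("SV%03d", k))
  r <- render_echogram(sc)
  write_ping_csv(r$records,
                 file.path(in_dir, "survey_pings", sprintf("SV%03d.csv", k)))
  if (nrow(r$truth)) {
    r$truth$survey_id <- sprintf("SV%03d", k)
    truth_rows[[k]] <- r$truth
  }
}
truth <- do.call(rbind, truth_rows)
write.csv(truth, file.path(in_dir, "survey_truth.csv"), row.names = FALSE)

# predator counts driven by the *planted* prey field: counts scale with the
# number and size of schools actually in the water
area_per_survey <- vapply(sprintf("SV%03d", seq_len(n_surveys)), function(id) {
  sum(truth$area_ellipse[truth$survey_id == id])
}, numeric(1))
distance_km <- 420 * 0.3 / 1000
mu_dolphin <- exp(log(2) + 0.004 * area_per_survey) * distance_km
mu_penguin <- exp(log(0.8) + 0.003 * area_per_survey) * distance_km
surveys <- data.frame(
  survey_id = sprintf("SV%03d", seq_len(n_surveys)),
  region = regions, date = dates, distance_km = distance_km,
  dolphin = rnbinom(n_surveys, size = 1.5, mu = mu_dolphin),
  penguin = rnbinom(n_surveys, size = 0.8, mu = mu_penguin)
)
write.csv(surveys, file.path(in_dir, "survey_table.csv"), row.names = FALSE)

message("wrote ", in_dir, ": ground-truth transect (", gt_scene$n_pings,
        " pings), sphere drop (300 pings), ", n_surveys,
        " survey transects, ", nrow(truth), " planted survey schools")
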