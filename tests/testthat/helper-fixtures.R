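# Fixtures built in code: toy echograms with exactly known geometry, and
# standard synthetic scenes reused across test files.

# Echogram constructed directly from a dB matrix (bypasses 8-bit storage).
# Depth of bin i is i * dz so no bin sits at depth 0.
toy_echogram <- function(intensity, dx = 0.30, dz = 0.15,
                         meta = list(frequency_khz = 200, pulse_ms = 0.2,
                                     beam_deg = 12, sound_speed = 1500)) {
  structure(list(
    intensity = intensity,
    depth = seq_len(ncol(intensity)) * dz,
    along_track = (seq_len(nrow(intensity)) - 1) * dx,
    lat = rep(0, nrow(intensity)),
    lon = rep(0, nrow(intensity)),
    utc_ms = seq_len(nrow(intensity)) * 100,
    survey_id = "toy",
    meta = meta
  ), class = "echogram")
}

# Quiet background one cell shy of the analysis threshold; regions painted
# on top. Background below -35 so only painted cells are candidates.
toy_canvas <- function(n_pings, n_bins, background = -60) {
  matrix(background, n_pings, n_bins)
}

paint_rect <- function(mat, pings, bins, value = -25) {
  mat[pings, bins] <- value
  mat
}

full_domain <- function(eg) {
  structure(list(mask = matrix(TRUE, nrow(eg$intensity), ncol(eg$intensity)),
                 nearfield_depth = 0,
                 bottom_line = rep(max(eg$depth) + 1, nrow(eg$intensity)),
                 backstep = 0),
            class = "analysis_domain")
}

# Standard two-school scene used by preprocessing/detection tests.
standard_scene <- function(noise_floor_db = -65, seed = 20150522, ...) {
  synthetic_scene(
    schools = list(true_school(200, 10, 20, 3, core_db = -22),
                   true_school(500, 15, 8, 2.5, core_db = -25)),
    n_pings = 700, seabed_depth = 25,
    noise_floor_db = noise_floor_db, rng_seed = seed, ...
  )
}

# Render a scene and run it through TVG correction, bottom pick, domain
# and noise removal with the scene's own true TVG parameters.
preprocessed_scene <- function(scene) {
  r <- render_echogram(scene)
  eg <- pings_to_echogram(r$records)
  fit <- tvg_fit(scene$tvg_exponent_true, scene$absorption_true)
  egc <- apply_tvg(eg, fit)
  bottom <- detect_bottom(egc)
  domain <- build_analysis_domain(egc, bottom)
  egn <- remove_background_noise(egc, fit)
  list(echogram = egn, corrected = egc, domain = domain, bottom = bottom,
       truth = r$truth, fit = fit, records = r$records, scene = scene)
}

# One sphere drop -> extracted regions, at the study's depth span.
sphere_regions_fixture <- function(xi, alpha = 0.05, noise_sd_db = 0,
                                   n = 120, seed = 42) {
  set.seed(seed)
  drop <- make_sphere_drop(runif(n, 3.2, 35), xi, alpha,
                           noise_sd_db = noise_sd_db, seed = seed)
  eg <- pings_to_echogram(drop$records)
  extract_sphere_regions(eg, drop$annotations)
}
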