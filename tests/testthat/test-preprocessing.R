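test_that("the bottom pick lands on the planted seabed and survives dropouts", {
  pre <- preprocessed_scene(standard_scene())
  dz <- diff(pre$corrected$depth)[1]
  expect_true(all(abs(pre$bottom - 25) <= 2 * dz))

  # one-ping dropout: erase the seabed on ping 50 and repick
  egc <- pre$corrected
  bed_bins <- which(egc$depth >= 24 & egc$depth <= 27)
  egc$intensity[50, bed_bins] <- -60
  line <- detect_bottom(egc)
  expect_true(all(abs(line - 25) <= 2 * dz))

  # flat echogram below threshold: no pickable seabed anywhere
  flat <- toy_echogram(toy_canvas(20, 100, background = -60))
  expect_error(detect_bottom(flat), "unusable transect")
})

test_that("the bottom pick is invariant to a constant dB offset", {
  pre <- preprocessed_scene(standard_scene())
  shifted <- pre$corrected
  shifted$intensity <- shifted$intensity + 13
  expect_equal(as.numeric(detect_bottom(shifted)),
               as.numeric(detect_bottom(pre$corrected)))
})

test_that("the analysis domain is the band between near-field and backstepped seabed", {
  eg <- toy_echogram(toy_canvas(10, 200))  # depth 0.15..30 m
  dom <- build_analysis_domain(eg, bottom_line = rep(25, 10), backstep = 0.3)
  in_band <- eg$depth > 3 & eg$depth < 25 - 0.3
  expect_equal(dom$mask[1, ], in_band)
  expect_equal(sum(dom$mask), 10 * sum(in_band))
  # masking is idempotent: reapplying the same rule changes nothing
  dom2 <- build_analysis_domain(eg, dom$bottom_line, dom$backstep)
  expect_identical(dom$mask, dom2$mask)

  expect_error(build_analysis_domain(eg, rep(25, 10), backstep = -1),
               "non-negative")
  expect_warning(build_analysis_domain(eg, rep(2, 10), backstep = 0.3),
                 "empty")
})

test_that("background noise matching the receiver model is removed almost entirely", {
  pre <- preprocessed_scene(synthetic_scene(schools = list(), n_pings = 300,
                                            noise_floor_db = -55,
                                            noise_sd_db = 2, rng_seed = 6))
  vals <- pre$echogram$intensity[pre$domain$mask]
  expect_gte(mean(vals <= -999, na.rm = TRUE), 0.99)
})

test_that("noise subtraction barely touches strong signal and is idempotent", {
  fit <- tvg_fit(10, 0.05)
  eg <- toy_echogram(toy_canvas(60, 120, background = -999))
  tvg <- 10 * log10(eg$depth) + 2 * 0.05 * eg$depth
  # exact receiver-model noise at -45 dB source level, plus a 20 dB school
  eg$intensity <- matrix(rep(-45 + tvg, each = 60), 60, 120)
  school_bins <- 40:60
  eg$intensity[20:35, school_bins] <-
    -25 + rep(tvg[school_bins], each = 16)  # 20 dB above local noise
  cleaned <- remove_background_noise(eg, fit)
  expect_equal(attr(cleaned, "noise_at_source_db"), -45, tolerance = 0.01)
  # school cells shifted by less than 0.05 dB
  delta <- cleaned$intensity[20:35, school_bins] -
    eg$intensity[20:35, school_bins]
  expect_lt(max(abs(delta)), 0.05)
  # all pure-noise cells at the floor
  noise_cells <- cleaned$intensity[1:19, ]
  expect_true(all(noise_cells <= -999))
  # idempotent on its own output
  twice <- remove_background_noise(cleaned, fit)
  expect_lt(max(abs(twice$intensity - cleaned$intensity), na.rm = TRUE), 0.01)
  expect_identical(dim(twice$intensity), dim(eg$intensity))
})

test_that("a noise-free echogram passes through unchanged", {
  fit <- tvg_fit(10, 0.05)
  eg <- toy_echogram(toy_canvas(30, 100, background = -999))
  eg$intensity[10:20, 30:50] <- -22
  out <- remove_background_noise(eg, fit)
  expect_equal(out$intensity, eg$intensity, tolerance = 1e-9)
})

test_that("an oversized averaging window is rejected", {
  eg <- toy_echogram(toy_canvas(5, 10))
  expect_error(remove_background_noise(eg, tvg_fit(10, 0.05),
                                       cell = c(10, 5)),
               "larger than")
})
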