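test_that("rendering is bit-identical under a fixed seed", {
  sc <- standard_scene()
  r1 <- render_echogram(sc)
  r2 <- render_echogram(sc)
  expect_identical(r1$records$samples, r2$records$samples)
  expect_identical(r1$truth, r2$truth)
  expect_equal(unique(r1$truth$rng_seed), sc$rng_seed)
  # different seed changes the noise field
  r3 <- render_echogram(standard_scene(seed = 1))
  expect_false(identical(r1$records$samples, r3$records$samples))
})

test_that("an empty scene has no in-domain sample above the threshold after preprocessing", {
  pre <- preprocessed_scene(synthetic_scene(schools = list(), n_pings = 300,
                                            noise_floor_db = -60,
                                            rng_seed = 3))
  vals <- pre$echogram$intensity[pre$domain$mask]
  vals <- vals[!is.na(vals) & vals > -999]
  expect_true(length(vals) == 0 || max(vals) < -35)
})

test_that("planted-school truth is conserved in the ideal field", {
  sc <- synthetic_scene(
    schools = list(true_school(100, 10, 12, 3, core_db = -20),
                   true_school(300, 18, 6, 2, core_db = -28)),
    n_pings = 400, seabed_depth = 25, rng_seed = 5
  )
  f <- scene_ideal_field(sc)
  sup <- which(f$intensity >= sc$support_threshold &
                 outer(rep(TRUE, nrow(f$intensity)), f$depth < 24),
               arr.ind = TRUE)
  for (k in seq_along(sc$schools)) {
    s <- sc$schools[[k]]
    xc <- (s$center_ping - 1) * sc$cell_along
    near <- abs(f$x[sup[, 1]] - xc) <= s$length / 2 + sc$cell_along &
      abs(f$depth[sup[, 2]] - s$center_depth) <= s$thickness / 2 + sc$cell_vert
    cells <- sup[near, , drop = FALSE]
    expect_gt(nrow(cells), 0)
    # above-threshold support spans the ellipse's bounding box to one cell
    expect_equal(diff(range(f$x[cells[, 1]])), s$length,
                 tolerance = 2 * sc$cell_along)
    expect_equal(diff(range(f$depth[cells[, 2]])), s$thickness,
                 tolerance = 2 * sc$cell_vert)
  }
  # and no above-threshold support away from schools (above the seabed)
  away <- rep(TRUE, nrow(sup))
  for (s in sc$schools) {
    xc <- (s$center_ping - 1) * sc$cell_along
    away <- away & !(abs(f$x[sup[, 1]] - xc) <= s$length / 2 + sc$cell_along &
                       abs(f$depth[sup[, 2]] - s$center_depth) <=
                         s$thickness / 2 + sc$cell_vert)
  }
  expect_equal(sum(away), 0)
})

test_that("scenes reject schools outside the water column", {
  expect_error(
    synthetic_scene(schools = list(true_school(50, 2.5, 5, 2)), n_pings = 100),
    "outside water column"
  )
  expect_error(
    synthetic_scene(schools = list(true_school(50, 24.5, 5, 2)),
                    n_pings = 100, seabed_depth = 25),
    "outside water column"
  )
  expect_error(true_school(10, 10, -5, 2), "positive")
})

test_that("sphere drops obey the closed-form spreading loss and region count", {
  d <- make_sphere_drop(c(5, 20), 10, 0, noise_sd_db = 0, sphere_level = 6.9)
  reg <- extract_sphere_regions(pings_to_echogram(d$records), d$annotations)
  # 10log spreading: -10*log10(20/5) dB between the two depths
  # (envelope offset cancels; tolerance covers 8-bit quantisation)
  expect_equal(diff(reg$mean_intensity), -10 * log10(20 / 5), tolerance = 0.1)

  d300 <- make_sphere_drop(seq(3.5, 35, length.out = 300), 10, 0.05, seed = 1)
  expect_equal(nrow(d300$annotations), 300)

  expect_error(make_sphere_drop(c(2, 10), 10, 0.05), "near-field")
  expect_error(make_sphere_drop(40, 10, 0.05), "<= 35")

  # determinism
  d1 <- make_sphere_drop(c(5, 10, 20), 20, 0.05, seed = 7)
  d2 <- make_sphere_drop(c(5, 10, 20), 20, 0.05, seed = 7)
  expect_identical(d1$records$samples, d2$records$samples)
})

test_that("survey simulation reproduces the study layout and NB behaviour", {
  d <- simulate_surveys(seed = 2)
  expect_equal(nrow(d), 136)
  expect_true(all(c("survey_id", "region", "season", "distance_km",
                    "c_scha", "prop_track", "dolphin", "penguin") %in% names(d)))
  tab <- table(d$region, d$season)
  expect_equal(unname(tab["AK", "summer"]), 19)
  expect_equal(unname(tab["AK", "winter"]), 20)
  expect_equal(sum(tab[, "summer"]), 67)
  expect_equal(sum(tab[, "winter"]), 69)
  # counts are non-negative integers and overdispersed
  for (col in c("dolphin", "penguin")) {
    expect_true(all(d[[col]] >= 0 & d[[col]] == round(d[[col]])))
    expect_gt(stats::var(d[[col]]), mean(d[[col]]))
  }
  # determinism
  expect_identical(d, simulate_surveys(seed = 2))

  expect_error(true_predator_model(0, nb_dispersion = -1), "positive")
  expect_error(simulate_surveys(n_surveys = 3), ">=")
})

test_that("the null simulation recovers exp(intercept) as the mean rate", {
  m <- true_predator_model(intercept = log(2), nb_dispersion = 5)
  d <- simulate_surveys(n_surveys = 2000, regions = c("A", "B"),
                        true_model = list(count = m), seed = 4)
  rate <- mean(d$count / d$distance_km)
  expect_equal(rate, 2, tolerance = 0.1)
})
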