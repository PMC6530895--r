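gt_params <- shapes_params(preset = "ground_truth")

test_that("presets encode the study's minimum school dimensions", {
  expect_equal(gt_params$min_school_length, 3)
  expect_equal(gt_params$min_school_thickness, 1.5)
  sr <- shapes_params(preset = "survey_results")
  expect_equal(c(sr$min_school_length, sr$min_school_thickness), c(5, 2))
  sm <- shapes_params(preset = "survey_methods")
  expect_equal(c(sm$min_school_length, sm$min_school_thickness), c(5, 3))
  expect_equal(sr$threshold, -35)
  expect_error(shapes_params(preset = "nope"), "unknown preset")
  expect_error(shapes_params(min_school_length = 0.5,
                             min_candidate_length = 1), ">=")
})

test_that("candidate detection finds 4-connected above-threshold patches", {
  mat <- paint_rect(toy_canvas(100, 120), 20:40, 30:50)
  eg <- toy_echogram(mat)
  cands <- detect_candidates(eg, full_domain(eg), gt_params)
  expect_length(cands, 1)

  # all-floor echogram
  eg0 <- toy_echogram(matrix(-999, 50, 60))
  expect_length(detect_candidates(eg0, full_domain(eg0), gt_params), 0)

  # two schools separated beyond both linking distances stay separate
  mat2 <- paint_rect(paint_rect(toy_canvas(200, 120), 10:40, 30:50),
                     120:150, 30:50)  # ~24 m apart horizontally
  eg2 <- toy_echogram(mat2)
  cands2 <- detect_candidates(eg2, full_domain(eg2), gt_params)
  expect_length(cands2, 2)
  expect_length(link_candidates(cands2, gt_params), 2)

  # diagonal contact is not connectivity
  mat3 <- toy_canvas(60, 60)
  mat3 <- paint_rect(mat3, 10:20, 10:20)
  mat3[21, 21] <- -25  # touches only diagonally
  eg3 <- toy_echogram(mat3)
  cands3 <- detect_candidates(eg3, NULL,
                              shapes_params(min_candidate_length = 0.1,
                                            min_candidate_thickness = 0.1,
                                            min_school_length = 0.1,
                                            min_school_thickness = 0.1))
  expect_length(cands3, 2)
})

test_that("linking merges candidates within the gap limits, transitively", {
  # two ~4 m candidates with a 2 m horizontal gap (links 5 m / 2 m)
  mat <- paint_rect(paint_rect(toy_canvas(120, 80), 10:22, 30:45), 30:42, 30:45)
  eg <- toy_echogram(mat)  # gap pings 23..29 ~ 2.1 m
  cands <- detect_candidates(eg, NULL, gt_params)
  expect_length(cands, 2)
  linked <- link_candidates(cands, gt_params)
  expect_length(linked, 1)
  m <- school_metrics(linked[[1]], eg)
  expect_equal(m$L, 33 * 0.3, tolerance = 1e-9)  # pings 10..42 inclusive

  # tighter horizontal link: no merge
  tight <- shapes_params(max_horizontal_link = 1, preset = "ground_truth")
  expect_length(link_candidates(cands, tight), 2)

  # chain a-b-c merges all three through b
  mat2 <- toy_canvas(200, 80)
  for (start in c(10, 38, 66)) mat2 <- paint_rect(mat2, start:(start + 12), 30:45)
  eg2 <- toy_echogram(mat2)
  cands2 <- detect_candidates(eg2, NULL, gt_params)
  expect_length(cands2, 3)
  expect_length(link_candidates(cands2, gt_params), 1)

  # order invariance
  for (perm in list(c(2, 1), c(2, 3, 1))) {
    cs <- if (length(perm) == 2) cands else cands2
    shuffled <- link_candidates(cs[perm], gt_params)
    straight <- link_candidates(cs, gt_params)
    norm <- function(l) {
      sorted <- lapply(l, function(m) m[order(m[, 1], m[, 2]), , drop = FALSE])
      unname(sorted[order(vapply(sorted, function(m) m[1, 1] * 1e6 + m[1, 2],
                                 numeric(1)))])
    }
    expect_equal(norm(shuffled), norm(straight))
  }
})

test_that("dimension filtering applies the minimum-size rule", {
  schools <- data.frame(L = c(6, 4, 6), T = c(2.5, 2.5, 1))
  kept <- filter_schools(schools, shapes_params(min_school_length = 5,
                                                min_school_thickness = 2))
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "n_discarded"), 2)
  all_kept <- filter_schools(schools,
                             shapes_params(min_school_length = 1e-9,
                                           min_school_thickness = 1e-9,
                                           min_candidate_length = 1e-9,
                                           min_candidate_thickness = 1e-9))
  expect_equal(nrow(all_kept), 3)
})

test_that("school metrics follow the rectangle and concavity oracles", {
  # 20 x 20 cell rectangle at 0.30 x 0.15 m -> L = 6, T = 3, A = 18
  mat <- paint_rect(toy_canvas(60, 60), 11:30, 21:40, value = -25)
  eg <- toy_echogram(mat)
  region <- which(mat > -35, arr.ind = TRUE)
  colnames(region) <- c("ping", "bin")
  m <- school_metrics(region, eg)
  expect_equal(m$L, 6)
  expect_equal(m$T, 3)
  expect_equal(m$A, 20 * 20 * 0.30 * 0.15)
  expect_equal(m$A, m$n_cells * 0.045)
  expect_equal(m$mean_intensity, -25)  # constant field
  expect_equal(m$D, mean(eg$depth[21:40]))

  # L-shaped region: area strictly below the bounding box product
  matL <- paint_rect(toy_canvas(60, 60), 11:30, 21:25, value = -25)
  matL <- paint_rect(matL, 11:15, 21:40, value = -25)
  regionL <- which(matL > -35, arr.ind = TRUE)
  colnames(regionL) <- c("ping", "bin")
  mL <- school_metrics(regionL, toy_echogram(matL))
  expect_lt(mL$A, mL$L * mL$T)
})

test_that("beam-geometry corrections match their closed forms", {
  school <- data.frame(L = 20, T = 3, A = 40, D = 10)
  meta <- list(beam_deg = 12, sound_speed = 1500, pulse_ms = 0.2)
  out <- beam_correct(school, meta)
  expect_equal(out$Lc, 20 - 2 * 10 * tan(6 * pi / 180), tolerance = 1e-12)
  expect_equal(out$Lc, 17.898, tolerance = 1e-3)
  expect_equal(out$Tc, 3 - 0.15, tolerance = 1e-12)
  expect_equal(out$Ac, 40 * (out$Lc * out$Tc) / (20 * 3), tolerance = 1e-12)
  expect_equal(out$Ac, 34.0, tolerance = 0.05)
  expect_true(out$valid)

  # identity limit: D = 0 and tau = 0
  out0 <- beam_correct(data.frame(L = 20, T = 3, A = 40, D = 0),
                       list(beam_deg = 12, sound_speed = 1500, pulse_ms = 0))
  expect_equal(c(out0$Lc, out0$Tc, out0$Ac), c(20, 3, 40), tolerance = 0)

  # non-positive corrected dimensions invalidate the school
  deep <- beam_correct(data.frame(L = 4, T = 3, A = 9, D = 30), meta)
  expect_false(deep$valid)
  expect_true(is.na(deep$Ac))
  zero <- beam_correct(data.frame(L = 0, T = 0, A = 0, D = 5), meta)
  expect_false(zero$valid)
})

test_that("beam-correction monotonicity properties hold on a random grid", {
  set.seed(41)
  meta <- list(beam_deg = 12, sound_speed = 1500, pulse_ms = 0.2)
  for (i in 1:50) {
    L <- runif(1, 5, 60); T <- runif(1, 2, 10)
    A <- runif(1, 0.3, 1) * L * T
    D <- sort(runif(2, 1, 20))
    lo <- beam_correct(data.frame(L = L, T = T, A = A, D = D[1]), meta)
    hi <- beam_correct(data.frame(L = L, T = T, A = A, D = D[2]), meta)
    expect_gt(lo$Lc, hi$Lc)           # Lc strictly decreasing in D
    expect_equal(lo$Tc, hi$Tc)        # Tc independent of D
    if (lo$valid) {
      ratio <- lo$Ac / A
      expect_true(ratio > 0 && ratio <= 1)
    }
  }
})

test_that("planted schools are recovered exactly once with small dimension error", {
  sc <- standard_scene()
  pre <- preprocessed_scene(sc)
  schools <- detect_schools(pre$echogram, pre$domain, gt_params)
  expect_equal(nrow(schools), nrow(pre$truth))
  dx <- sc$cell_along; dz <- sc$cell_vert
  phi <- 12 * pi / 180
  for (k in seq_len(nrow(pre$truth))) {
    tr <- pre$truth[k, ]
    match_row <- which(abs(schools$D - tr$center_depth) < 1.5)
    expect_length(match_row, 1)
    s <- schools[match_row, ]
    smear <- 2 * s$D * tan(phi / 2)
    expect_lte(abs(s$L - tr$length), 2 * dx + smear)
    expect_lte(abs(s$T - tr$thickness), 2 * dz)
    expect_lte(abs(s$D - tr$center_depth), 3 * dz)
  }
})

test_that("lowering the threshold never shrinks any school's area", {
  pre <- preprocessed_scene(standard_scene())
  prev_area <- -Inf
  for (thr in c(-30, -32.5, -35, -37.5, -40)) {
    p <- shapes_params(threshold = thr, preset = "ground_truth")
    schools <- detect_schools(pre$echogram, pre$domain, p)
    total <- sum(schools$A)
    expect_gte(total + 1e-9, prev_area)
    prev_area <- total
  }
})
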