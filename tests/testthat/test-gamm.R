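test_that("input contracts are enforced", {
  d <- simulate_surveys(seed = 1)
  bad <- d
  bad$dolphin <- bad$dolphin + 0.5
  expect_error(fit_nb_gamm(bad, "dolphin", "prop_track"), "integer")
  expect_error(fit_nb_gamm(d[1:10, ], "dolphin", "prop_track"), "at least 30")
  one_region <- d
  one_region$region <- "AK"
  expect_error(fit_nb_gamm(one_region, "dolphin", "prop_track"), "regions")
  flat <- d
  flat$prop_track <- 0.05
  expect_error(fit_nb_gamm(flat, "dolphin", "prop_track"), "variance")
})

test_that("the fitted smooth covers the generating effect at most points", {
  models <- default_predator_models()
  d <- simulate_surveys(n_surveys = 500,
                        regions = study_survey_layout()$region,
                        true_model = models, seed = 77)
  fit <- fit_nb_gamm(d, "dolphin", "prop_track")
  # across-the-function coverage at the observed predictor values, with
  # the model-constant uncertainty in the band; the fitted smooth is
  # centred by the sum-to-zero constraint, the truth is not, so the free
  # constant is aligned before comparing to the band
  crv <- smooth_curve(fit, at = sort(d$prop_track), se_with_mean = TRUE)
  truth <- models$dolphin$smooth_effect(crv$x)
  offset <- mean(truth - crv$smooth)
  covered <- (truth - offset) >= crv$lower & (truth - offset) <= crv$upper
  expect_gte(mean(covered), 0.9)
  # monotone truth: fitted smooth monotone non-decreasing over the
  # central 90% of the predictor range
  qs <- stats::quantile(d$prop_track, c(0.05, 0.95))
  central <- crv$x >= qs[1] & crv$x <= qs[2]
  expect_true(all(diff(crv$smooth[central]) > -1e-6))
})

test_that("a null generating effect yields an essentially linear-null smooth", {
  m <- true_predator_model(intercept = log(2),
                           region_effects = c(A = 0, B = 0, C = 0),
                           nb_dispersion = 2)
  edfs <- devs <- numeric(5)
  for (s in 1:5) {
    d <- simulate_surveys(n_surveys = 300, regions = c("A", "B", "C"),
                          true_model = list(count = m), seed = 130 + s)
    fit <- fit_nb_gamm(d, "count", "prop_track")
    edfs[s] <- fit$edf_smooth
    devs[s] <- deviance_explained(fit)
    if (s == 1) {
      # the 95% band covers zero effect across the range
      crv <- smooth_curve(fit, n = 40)
      expect_gte(mean(crv$lower <= 0 & crv$upper >= 0), 0.95)
    }
  }
  # a single replicate may show spurious wiggliness; typically edf ~ 1
  expect_lt(stats::median(edfs), 1.5)
  expect_lt(stats::median(devs), 8)
})

test_that("distance acts as an exposure offset", {
  m <- true_predator_model(intercept = log(1.5),
                           region_effects = c(A = 0.3, B = -0.3),
                           nb_dispersion = 3)
  d <- simulate_surveys(n_surveys = 400, regions = c("A", "B"),
                        true_model = list(count = m), seed = 21)
  fit1 <- fit_nb_gamm(d, "count", "prop_track")
  # regenerate counts with doubled distances (same expected rate per km)
  d2 <- d
  d2$distance_km <- d$distance_km * 2
  set.seed(22)
  mu <- exp(m$intercept + unname(m$region_effects[d2$region]) +
              log(d2$distance_km))
  d2$count <- stats::rnbinom(nrow(d2), size = m$nb_dispersion, mu = mu)
  fit2 <- fit_nb_gamm(d2, "count", "prop_track")
  b1 <- stats::coef(fit1$fit)[["(Intercept)"]]
  b2 <- stats::coef(fit2$fit)[["(Intercept)"]]
  expect_lt(abs(b1 - b2), 0.15)  # Monte-Carlo error only
})

test_that("deviance explained is zero for the null model and consistent with mgcv", {
  d <- simulate_surveys(seed = 31)
  null_fit <- mgcv::gam(dolphin ~ 1 + offset(log(distance_km)),
                        family = mgcv::nb(), data = d)
  expect_equal(1 - null_fit$deviance / null_fit$null.deviance, 0,
               tolerance = 1e-8)
  fit <- fit_nb_gamm(d, "dolphin", "prop_track")
  expect_equal(deviance_explained(fit), fit$deviance_explained,
               tolerance = 1e-8)
  expect_true(fit$deviance_explained > 0 && fit$deviance_explained < 100)
  expect_gte(fit$edf, 1)
})

test_that("AIC ranking prefers the generating metric and ties on duplicates", {
  d <- simulate_surveys(seed = 3)
  ranked <- select_best_metric(d, "dolphin")
  expect_equal(attr(ranked, "ranking")[1], "prop_track")
  expect_gt(attr(ranked, "delta_aic"), 2)
  # penguin counts are sparser, so judge its metric over several replicates
  penguin_wins <- 0
  for (s in 1:15) {
    dp <- simulate_surveys(seed = 600 + s)
    rp <- select_best_metric(dp, "penguin")
    penguin_wins <- penguin_wins + (attr(rp, "ranking")[1] == "c_scha")
  }
  expect_gt(penguin_wins / 15, 0.6)

  # identical predictor columns -> essentially identical models
  dup <- d
  dup$prop_track <- dup$c_scha
  tied <- select_best_metric(dup, "dolphin")
  expect_lt(abs(attr(tied, "delta_aic")), 0.5)
})

test_that("dispersion and intercept are recovered at the study scale", {
  # intercept on a well-separated scale (relative error is meaningless for
  # an intercept near zero) and region deviations that average to zero
  # under the unbalanced study layout
  m <- true_predator_model(intercept = log(3),
                           region_effects = c(AK = 0.3, BF = -0.3, LB = 0.3,
                                              LL = -0.3, LY = 0.225, ME = -0.25),
                           nb_dispersion = 1.5)
  rel_err_b0 <- c(); rel_err_th <- c()
  for (s in 1:40) {
    d <- simulate_surveys(n_surveys = 136, true_model = list(count = m),
                          seed = 4000 + s)
    fit <- fit_nb_gamm(d, "count", "prop_track")
    b0 <- stats::coef(fit$fit)[["(Intercept)"]]
    rel_err_b0 <- c(rel_err_b0, abs(b0 - m$intercept) / abs(m$intercept))
    rel_err_th <- c(rel_err_th, abs(fit$nb_dispersion - 1.5) / 1.5)
  }
  expect_lt(mean(rel_err_b0), 0.25)
  expect_lt(mean(rel_err_th), 0.25)
})

test_that("smooth plots are written with labelled axes", {
  d <- simulate_surveys(seed = 17)
  fit <- fit_nb_gamm(d, "dolphin", "prop_track")
  path <- withr::local_tempfile(fileext = ".png")
  g <- plot_smooth(fit, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  expect_match(g$labels$x, "Prop.Track", fixed = TRUE)
  g2 <- plot_smooth(fit)
  expect_s3_class(g2, "ggplot")
})
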