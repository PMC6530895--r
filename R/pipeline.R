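#' Pipeline configuration
#'
#' Assembles and validates the configuration driving the two study
#' workflows. Paths are checked at run time by the workflow functions.
#'
#' @param out_dir output directory (created if needed).
#' @param preset SHAPES preset name (see [shapes_params()]).
#' @param threshold analysis threshold, dB.
#' @param tvg_candidates candidate TVG range coefficients.
#' @param min_bottom_depth,bottom_threshold seabed-pick settings.
#' @param backstep,nearfield_depth analysis-domain settings, m.
#' @param noise_cell,max_snr_loss background-noise-removal settings.
#' @param seed integer seed recorded in the manifest.
#' @param ... further named entries (file paths etc.) stored as-is.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, preset = "survey_results",
                            threshold = -35,
                            tvg_candidates = c(10, 15, 20, 40),
                            min_bottom_depth = 5, bottom_threshold = 18,
                            backstep = 0.3, nearfield_depth = 3,
                            noise_cell = c(20, 5), max_snr_loss = 3,
                            seed = 20150522, ...) {
  params <- shapes_params(threshold = threshold, preset = preset)
  structure(c(list(out_dir = out_dir, preset = preset,
                   shapes = params, threshold = threshold,
                   tvg_candidates = tvg_candidates,
                   min_bottom_depth = min_bottom_depth,
                   bottom_threshold = bottom_threshold,
                   backstep = backstep, nearfield_depth = nearfield_depth,
                   noise_cell = noise_cell, max_snr_loss = max_snr_loss,
                   seed = seed),
              list(...)),
            class = "pipeline_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

write_manifest <- function(config, inputs, stages) {
  cfg <- config
  cfg$shapes <- unclass(cfg$shapes)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  manifest <- list(
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tf)),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stage_counts = stages,
    written_utc = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  unlink(tf)
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

preprocess_echogram <- function(eg, fit, config) {
  eg_c <- apply_tvg(eg, fit)
  bottom <- detect_bottom(eg_c, config$min_bottom_depth,
                          config$bottom_threshold)
  domain <- build_analysis_domain(eg_c, bottom, config$backstep,
                                  config$nearfield_depth)
  eg_nr <- remove_background_noise(eg_c, fit, config$noise_cell,
                                   config$max_snr_loss)
  list(echogram = eg_nr, domain = domain, bottom = bottom)
}

#' Run the ground-truth characterisation workflow
#'
#' End-to-end: read ping and calibration-sphere exports, convert to
#' relative dB, select and apply the TVG form from the sphere regions,
#' preprocess (seabed, near-field, background noise), detect schools with
#' the ground-truth SHAPES preset and export the school table, dimension
#' and intensity histograms, the before/after sphere-correlation figure
#' and a TVG report. Every stage logs its input/output counts; a manifest
#' with config hash, seed and input checksums is written alongside.
#'
#' @param config a [pipeline_config()] with entries `ping_csv`,
#'   `sphere_csv`, `sphere_track_csv` (columns `ping`, `depth`) and `ctd`
#'   (list of arguments to [ctd_cast()]).
#' @return list with `schools`, `tvg_fit`, `regions`, and output paths.
#' @export
run_ground_truth <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c(config$ping_csv, config$sphere_csv, config$sphere_track_csv)) {
    if (!file.exists(f)) stop("[input] missing input file: ", f)
  }
  stages <- list()

  stage_msg("read", "reading ping export ", config$ping_csv)
  pings <- read_ping_csv(config$ping_csv)
  stages$pings <- nrow(pings)
  if (nrow(pings) == 0) stop("[read] ping export is empty")
  eg <- pings_to_echogram(pings)

  stage_msg("sphere", "reading sphere drop ", config$sphere_csv)
  sphere <- read_ping_csv(config$sphere_csv)
  track <- utils::read.csv(config$sphere_track_csv)
  sphere_eg <- pings_to_echogram(sphere)
  regions <- extract_sphere_regions(sphere_eg, track)
  stages$sphere_regions <- nrow(regions)
  stage_msg("sphere", nrow(regions), " sphere regions isolated")

  cast <- do.call(ctd_cast, config$ctd)
  alpha <- absorption_coefficient(cast)
  cs <- sound_speed(cast)
  fit <- fit_tvg_form(regions, alpha, config$tvg_candidates, sound_speed = cs)
  stage_msg("tvg", "selected ", fit$xi_selected, "log (alpha = ",
            signif(alpha, 3), " dB/m)")

  pre <- preprocess_echogram(eg, fit, config)
  stages$bottom_picked <- attr(pre$bottom, "n_picked")

  schools <- detect_schools(pre$echogram, pre$domain, config$shapes)
  stages$schools <- nrow(schools)
  stage_msg("shapes", nrow(schools), " schools detected (preset ",
            config$preset, ")")

  school_path <- file.path(config$out_dir, "school_table.csv")
  utils::write.csv(schools, school_path, row.names = FALSE)
  bottom_path <- file.path(config$out_dir, "bottom_line.csv")
  utils::write.csv(data.frame(ping = seq_along(pre$bottom),
                              depth_m = as.numeric(pre$bottom)),
                   bottom_path, row.names = FALSE)

  report <- list(xi_selected = fit$xi_selected, alpha_db_per_m = alpha,
                 sound_speed_m_s = cs,
                 correlation_by_xi = as.list(fit$correlation_by_xi),
                 n_regions = fit$n_regions)
  tvg_path <- file.path(config$out_dir, "tvg_report.json")
  jsonlite::write_json(report, tvg_path, auto_unbox = TRUE, digits = NA)

  figs <- ground_truth_figures(config$out_dir, schools, regions, fit)
  manifest <- write_manifest(config,
                             c(config$ping_csv, config$sphere_csv,
                               config$sphere_track_csv),
                             stages)
  list(schools = schools, tvg_fit = fit, regions = regions,
       paths = c(school_table = school_path, bottom_line = bottom_path,
                 tvg_report = tvg_path, manifest = manifest, figs))
}

ground_truth_figures <- function(out_dir, schools, regions, fit) {
  paths <- c()
  if (nrow(schools)) {
    long <- data.frame(
      value = c(schools$D, schools$A, schools$T, schools$L),
      dim = factor(rep(c("mean depth (m)", "area (m²)",
                         "thickness (m)", "length (m)"),
                       each = nrow(schools)),
                   levels = c("mean depth (m)", "area (m²)",
                              "thickness (m)", "length (m)"))
    )
    g <- ggplot2::ggplot(long, ggplot2::aes(x = value)) +
      ggplot2::geom_histogram(bins = 20, fill = "grey40") +
      ggplot2::facet_wrap(~dim, scales = "free") +
      ggplot2::labs(x = NULL, y = "schools") + ggplot2::theme_minimal()
    p <- file.path(out_dir, "school_dimensions.png")
    ggplot2::ggsave(p, g, width = 7, height = 5, dpi = 150)
    paths <- c(paths, dimensions = p)

    g2 <- ggplot2::ggplot(schools, ggplot2::aes(x = mean_intensity)) +
      ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
      ggplot2::labs(x = "mean relative intensity (dB)", y = "schools") +
      ggplot2::theme_minimal()
    p2 <- file.path(out_dir, "school_intensity.png")
    ggplot2::ggsave(p2, g2, width = 6, height = 4, dpi = 150)
    paths <- c(paths, intensity = p2)
  }
  if (nrow(regions)) {
    regions$after <- regions$mean_intensity +
      fit$xi_selected * log10(regions$depth) + 2 * fit$alpha * regions$depth
    both <- rbind(
      data.frame(depth = regions$depth, db = regions$mean_intensity,
                 panel = "(a) before TVG"),
      data.frame(depth = regions$depth, db = regions$after,
                 panel = "(b) after TVG")
    )
    g3 <- ggplot2::ggplot(both, ggplot2::aes(x = depth, y = db)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::facet_wrap(~panel, scales = "free_y") +
      ggplot2::labs(x = "depth (m)", y = "mean relative intensity (dB)") +
      ggplot2::theme_minimal()
    p3 <- file.path(out_dir, "sphere_correction.png")
    ggplot2::ggsave(p3, g3, width = 7, height = 4, dpi = 150)
    paths <- c(paths, sphere = p3)
  }
  paths
}

#' Run the predator-prey survey workflow
#'
#' For every survey listed in the survey table: read its ping export,
#' apply the (given or sphere-fitted) TVG correction, preprocess, detect
#' schools with the survey SHAPES preset, and summarise into the two RAPP
#' metrics. Then produce the region/season RAPP summary (with standard
#' errors), fit both negative-binomial GAMMs per predator, rank them by
#' AIC and plot the winning smooths.
#'
#' @param config a [pipeline_config()] with entries `ping_dir` (one
#'   `<survey_id>.csv` per survey), `survey_table_csv` (columns
#'   `survey_id`, `region`, `date`, `distance_km` and one column per
#'   predator), `tvg_xi`, `tvg_alpha` and optionally `count_cols`.
#' @return list with `rapp` (per-survey table), `season_summary`, `models`
#'   (per predator, AIC-ranked), and output paths.
#' @export
run_survey_analysis <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(config$survey_table_csv)) {
    stop("[input] missing survey table: ", config$survey_table_csv)
  }
  surveys <- utils::read.csv(config$survey_table_csv,
                             stringsAsFactors = FALSE)
  zero_dist <- !is.finite(surveys$distance_km) | surveys$distance_km <= 0
  if (any(zero_dist)) {
    warning(sum(zero_dist), " survey(s) with zero distance dropped")
    surveys <- surveys[!zero_dist, , drop = FALSE]
  }
  fit <- tvg_fit(config$tvg_xi, config$tvg_alpha)
  stages <- list(surveys = nrow(surveys))

  rapp <- vector("list", nrow(surveys))
  for (k in seq_len(nrow(surveys))) {
    sv <- surveys[k, ]
    f <- file.path(config$ping_dir, paste0(sv$survey_id, ".csv"))
    if (!file.exists(f)) stop("[read] missing ping export for survey ",
                              sv$survey_id)
    eg <- pings_to_echogram(read_ping_csv(f))
    pre <- preprocess_echogram(eg, fit, config)
    schools <- detect_schools(pre$echogram, pre$domain, config$shapes)
    rapp[[k]] <- summarize_survey(schools, sv)
  }
  rapp <- do.call(rbind, rapp)
  stage_msg("rapp", nrow(rapp), " surveys summarised; ",
            sum(rapp$n_schools), " schools total")
  stages$schools <- sum(rapp$n_schools)

  data <- merge(rapp, surveys[, setdiff(names(surveys),
                                        c("region", "distance_km", "date",
                                          "season"))],
                by = "survey_id")
  count_cols <- config$count_cols
  if (is.null(count_cols)) {
    count_cols <- setdiff(names(surveys),
                          c("survey_id", "region", "season", "date",
                            "distance_km"))
  }

  rapp_path <- file.path(config$out_dir, "rapp_table.csv")
  utils::write.csv(data, rapp_path, row.names = FALSE)

  season_summary <- stats::aggregate(
    cbind(prop_track, c_scha) ~ region + season, data = data,
    FUN = function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))))
  season_path <- file.path(config$out_dir, "rapp_by_region_season.csv")
  utils::write.csv(do.call(data.frame, season_summary), season_path,
                   row.names = FALSE)
  fig7 <- plot_rapp_by_region(data,
                              file.path(config$out_dir, "rapp_region_season.png"))

  models <- list()
  report <- list()
  for (resp in count_cols) {
    ranked <- select_best_metric(data, resp)
    models[[resp]] <- ranked
    best <- ranked[[1]]
    stage_msg("gamm", resp, ": best metric ", best$predictor,
              sprintf(" (deviance explained %.1f%%, dAIC %.1f)",
                      best$deviance_explained, attr(ranked, "delta_aic")))
    plot_smooth(best, file.path(config$out_dir,
                                paste0("smooth_", resp, ".png")))
    report[[resp]] <- lapply(ranked, function(f) {
      list(predictor = f$predictor, edf = f$edf, aic = f$aic,
           deviance_explained = f$deviance_explained,
           nb_dispersion = f$nb_dispersion)
    })
  }
  model_path <- file.path(config$out_dir, "model_report.json")
  jsonlite::write_json(report, model_path, auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(config, c(config$survey_table_csv), stages)

  list(rapp = data, season_summary = season_summary, models = models,
       paths = c(rapp_table = rapp_path, season_summary = season_path,
                 model_report = model_path, manifest = manifest,
                 fig_region_season = fig7))
}

plot_rapp_by_region <- function(data, file) {
  agg <- stats::aggregate(prop_track ~ region + season, data = data,
                          FUN = mean)
  agg$se <- stats::aggregate(prop_track ~ region + season, data = data,
                             FUN = function(v) stats::sd(v) / sqrt(length(v)))$prop_track
  g <- ggplot2::ggplot(agg, ggplot2::aes(x = region, y = prop_track,
                                         fill = season)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = prop_track - se,
                                        ymax = prop_track + se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::labs(x = "survey region", y = "mean Prop.Track") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, g, width = 6, height = 4, dpi = 150)
  file
}
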