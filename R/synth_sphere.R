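#' Simulate a calibration-sphere drop
#'
#' Emits ping records mimicking a 38.1 mm tungsten-carbide sphere lowered
#' directly below the transducer, one on-axis observation per requested
#' depth between 3 and 35 m. The raw (stored) peak intensity at depth `z`
#' is `sphere_level - xi_true * log10(z) - 2 * alpha_true * z` plus Gaussian
#' noise; the echo is spread over the 8 vertical bins of the standard
#' 8 x 1 measurement window with a fixed pulse envelope.
#'
#' Because 8-bit storage spans only ~48 dB while a 40log TVG spans ~65 dB
#' over 3-35 m, the default reference level anchors the raw echo mid-scale
#' at the mean TVG of the requested depths; pass `sphere_level` explicitly
#' to pin the absolute level (it must keep raw intensities below 0 dB).
#'
#' @param depths sphere depths, m; each must lie in (3, 35].
#' @param tvg_exponent_true true TVG range coefficient.
#' @param absorption_true true absorption coefficient, dB/m.
#' @param noise_sd_db Gaussian noise on the raw echo level, dB.
#' @param sphere_level raw reference level at 1 m, dB (default: auto
#'   mid-scale anchor).
#' @param max_range stored range window, m.
#' @param cell_vert vertical cell size, m.
#' @param seed integer RNG seed.
#' @param survey_id survey identifier.
#' @return list with `records` ([ping_records()]), `annotations` (data frame
#'   `ping`, `depth` -- the 8 x 1 region guide), and the generating
#'   parameters.
#' @export
make_sphere_drop <- function(depths, tvg_exponent_true = 10,
                             absorption_true = 0.05, noise_sd_db = 0.5,
                             sphere_level = NULL, max_range = 36,
                             cell_vert = 0.15, seed = 20150522,
                             survey_id = "sphere_drop") {
  if (any(depths <= 3)) stop("sphere depth <= 3 m lies inside the near-field")
  if (any(depths > 35)) stop("sphere depths must be <= 35 m")
  set.seed(seed)
  tvg <- tvg_exponent_true * log10(depths) + 2 * absorption_true * depths
  if (is.null(sphere_level)) sphere_level <- mean(tvg) - 24
  n_bins <- round(max_range / cell_vert) + 1L
  depth_axis <- (seq_len(n_bins) - 1) * max_range / (n_bins - 1)
  envelope <- -3 * abs(-3:4)  # dB below peak across the 8-bin window
  n <- length(depths)
  samples <- vector("list", n)
  for (k in seq_len(n)) {
    peak_db <- sphere_level - tvg[k] + stats::rnorm(1, 0, noise_sd_db)
    ctr <- which.min(abs(depth_axis - depths[k]))
    db <- rep(-Inf, n_bins)
    idx <- ctr + (-3:4)
    ok <- idx >= 1 & idx <= n_bins
    db[idx[ok]] <- peak_db + envelope[ok]
    samples[[k]] <- db_to_counts(db)
  }
  records <- ping_records(
    survey_id = survey_id, ping = seq_len(n),
    utc_ms = 1.4e12 + (seq_len(n) - 1) * 1000,
    lat = -43.8, lon = 173.1,
    min_range_m = 0, max_range_m = max_range,
    samples = samples
  )
  list(records = records,
       annotations = data.frame(ping = seq_len(n), depth = depths),
       tvg_exponent_true = tvg_exponent_true,
       absorption_true = absorption_true,
       sphere_level = sphere_level, seed = seed)
}
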