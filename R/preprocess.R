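#' Pick the seabed line on a TVG-corrected echogram
#'
#' Reconstruction of a "best candidate" bottom pick as the leading edge of
#' the strongest echo: per ping, the strongest sample below
#' `min_bottom_depth` qualifies as seabed if it lies within
#' `bottom_threshold` dB of the ping's overall maximum (the threshold is
#' relative to the per-ping maximum so the pick is invariant to any
#' constant offset on an uncalibrated system); the candidate depth is the
#' top of that echo -- the shallowest contiguous sample within 6 dB of it.
#' A cross-ping running median (window 9) enforces continuity and pings
#' with no candidate inherit the interpolated line.
#'
#' @param echogram TVG-corrected `echogram`.
#' @param min_bottom_depth shallowest admissible seabed depth, m.
#' @param bottom_threshold admission margin below the per-ping maximum, dB.
#' @return numeric bottom depth per ping, m (attribute `n_picked` gives the
#'   number of pings with a direct candidate).
#' @export
detect_bottom <- function(echogram, min_bottom_depth = 5,
                          bottom_threshold = 18) {
  stopifnot(inherits(echogram, "echogram"))
  n_pings <- nrow(echogram$intensity)
  depth <- echogram$depth
  eligible <- which(depth >= min_bottom_depth)
  if (!length(eligible)) stop("no bins below min_bottom_depth")
  edge_margin <- 6  # dB; echo top = shallowest contiguous sample this close to the peak
  cand <- rep(NA_real_, n_pings)
  for (p in seq_len(n_pings)) {
    v <- echogram$intensity[p, ]
    v[is.na(v) | v <= FLOOR_DB] <- -Inf
    pmax_db <- max(v)
    if (!is.finite(pmax_db)) next
    ve <- v[eligible]
    peak <- which.max(ve)
    if (ve[peak] < pmax_db - bottom_threshold) next
    # a seabed echo must stand out of the ping, not just be its maximum:
    # featureless (flat) pings yield no candidate (offset-invariant rule)
    background <- stats::median(v[is.finite(v)])
    if (ve[peak] < background + edge_margin) next
    top <- peak
    while (top > 1 && ve[top - 1] >= ve[peak] - edge_margin) top <- top - 1
    cand[p] <- depth[eligible[top]]
  }
  n_picked <- sum(!is.na(cand))
  if (n_picked < n_pings / 2) {
    stop("unusable transect: more than half the pings have no bottom candidate")
  }
  filled <- if (n_picked >= 2) {
    stats::approx(seq_len(n_pings)[!is.na(cand)], cand[!is.na(cand)],
                  xout = seq_len(n_pings), rule = 2)$y
  } else {
    rep(cand[!is.na(cand)], n_pings)
  }
  line <- stats::runmed(filled, k = min(9, n_pings - (1 - n_pings %% 2)))
  attr(line, "n_picked") <- n_picked
  line
}

#' Build the analysis domain mask
#'
#' Excludes the acoustic near-field (upper `nearfield_depth` metres) and
#' everything at or below the picked seabed minus a backstep that keeps the
#' seabed's side-lobe smear out of the school detector.
#'
#' @param echogram an `echogram`.
#' @param bottom_line per-ping seabed depth from [detect_bottom()], m.
#' @param backstep margin above the seabed to exclude, m.
#' @param nearfield_depth near-field exclusion depth, m.
#' @return an `analysis_domain` list: logical `mask` (pings x bins, `TRUE`
#'   where usable), plus the parameters.
#' @export
build_analysis_domain <- function(echogram, bottom_line, backstep = 0.3,
                                  nearfield_depth = 3) {
  stopifnot(inherits(echogram, "echogram"))
  if (backstep < 0) stop("backstep must be non-negative")
  bottom_line <- rep_len(bottom_line, nrow(echogram$intensity))
  ceiling_line <- bottom_line - backstep
  mask <- outer(ceiling_line, echogram$depth,
                function(bl, z) z < bl) &
    matrix(echogram$depth > nearfield_depth,
           nrow(echogram$intensity), ncol(echogram$intensity), byrow = TRUE)
  if (!any(mask)) warning("analysis domain is empty")
  structure(list(mask = mask, nearfield_depth = nearfield_depth,
                 bottom_line = bottom_line, backstep = backstep),
            class = "analysis_domain")
}

#' Remove range-dependent background noise
#'
#' De Robertis & Higginbottom style estimator. The echogram is averaged
#' over `cell` (pings x bins) windows in the linear domain; the noise level
#' at source is the minimum over cells of (cell mean - TVG at the cell's
#' depth). The per-sample noise estimate, noise-at-source plus TVG at the
#' sample's depth, is subtracted in the linear domain; samples whose
#' remaining signal-to-noise ratio falls below `max_snr_loss` are set to
#' the -999 dB floor sentinel (excluded from all later means).
#'
#' @param echogram TVG-corrected `echogram`.
#' @param fit the `tvg_fit` that corrected it.
#' @param cell averaging window as `c(pings, bins)`.
#' @param max_snr_loss minimum acceptable SNR after subtraction, dB.
#' @return the noise-removed `echogram` (attribute
#'   `noise_at_source_db` records the estimate).
#' @export
remove_background_noise <- function(echogram, fit, cell = c(20, 5),
                                    max_snr_loss = 3) {
  stopifnot(inherits(echogram, "echogram"), inherits(fit, "tvg_fit"))
  n_pings <- nrow(echogram$intensity)
  n_bins <- ncol(echogram$intensity)
  if (cell[1] > n_pings || cell[2] > n_bins) {
    stop("averaging window larger than the echogram")
  }
  tvg <- tvg_curve(fit, echogram$depth)
  p_grid <- split(seq_len(n_pings), ceiling(seq_len(n_pings) / cell[1]))
  b_grid <- split(seq_len(n_bins), ceiling(seq_len(n_bins) / cell[2]))
  # Cell means include floor-sentinel samples as zero power: a sentinel
  # records that noise there is already below measurable, so a previously
  # cleaned echogram yields a -Inf estimate and passes through unchanged.
  noise_src <- Inf
  for (pi in p_grid) {
    for (bi in b_grid) {
      vals <- as.vector(echogram$intensity[pi, bi])
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      m <- 10 * log10(mean(ifelse(vals <= FLOOR_DB, 0, 10^(vals / 10))))
      src <- m - mean(tvg[bi], na.rm = TRUE)
      if (!is.nan(src) && src < noise_src) noise_src <- src
    }
  }
  out <- echogram
  if (is.finite(noise_src)) {
    noise_db <- noise_src + tvg  # per-bin noise estimate
    lin <- 10^(echogram$intensity / 10)
    lin_noise <- matrix(10^(noise_db / 10), n_pings, n_bins, byrow = TRUE)
    cleaned <- lin - lin_noise
    cleaned_db <- matrix(FLOOR_DB, n_pings, n_bins)
    pos <- which(cleaned > 0)
    cleaned_db[pos] <- 10 * log10(cleaned[pos])
    snr <- cleaned_db - matrix(noise_db, n_pings, n_bins, byrow = TRUE)
    cleaned_db[is.na(snr) | snr < max_snr_loss] <- FLOOR_DB
    cleaned_db[is.na(echogram$intensity)] <- NA_real_
    cleaned_db[!is.na(echogram$intensity) &
                 echogram$intensity <= FLOOR_DB] <- FLOOR_DB
    out$intensity <- cleaned_db
  }
  attr(out, "noise_at_source_db") <- if (is.finite(noise_src)) noise_src else NA_real_
  out
}
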