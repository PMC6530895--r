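#' Assemble ping records into an echogram
#'
#' Builds the pings-by-depth-bins matrix of relative intensity (dB) with a
#' depth axis derived from the shared range window and an along-track axis
#' from haversine distances between successive GPS fixes. Depth is measured
#' below the transducer; bin `i` (1-based) sits at
#' `min_range + (i - 1) * (max_range - min_range) / (n_samples - 1)`.
#'
#' All pings must share the same range window and sample count: mid-survey
#' range or gain changes alter the (unknown) source level and destroy the
#' comparability of relative intensities, so they are rejected.
#'
#' @param records a `ping_records` data frame with at least 2 pings.
#' @param meta list of acoustic metadata; defaults cover the 200 kHz
#'   recreational-grade systems this pipeline targets: `frequency_khz`,
#'   `pulse_ms` (tau), `beam_deg` (3 dB beam angle phi), `sound_speed`
#'   (C, m/s), `gain_setting`, `ping_rate_hz`.
#' @return an `echogram` object: list with `intensity` (pings x bins dB
#'   matrix), `depth` (m per bin), `along_track` (cumulative m per ping),
#'   `lat`, `lon`, `utc_ms`, `survey_id`, `meta`.
#' @export
pings_to_echogram <- function(records, meta = list()) {
  validate_ping_records(records)
  if (nrow(records) < 2) stop("need at least 2 pings")
  if (length(unique(records$min_range_m)) != 1 ||
      length(unique(records$max_range_m)) != 1 ||
      length(unique(records$n_samples)) != 1) {
    stop("heterogeneous range windows: range/gain changes invalidate ",
         "relative-intensity comparability")
  }
  n_samples <- records$n_samples[1]
  r0 <- records$min_range_m[1]
  r1 <- records$max_range_m[1]
  depth <- r0 + (seq_len(n_samples) - 1) * (r1 - r0) / (n_samples - 1)
  counts <- do.call(rbind, records$samples)
  intensity <- matrix(counts_to_db(as.vector(counts)), nrow = nrow(counts))
  steps <- geosphere::distHaversine(
    cbind(records$lon[-nrow(records)], records$lat[-nrow(records)]),
    cbind(records$lon[-1], records$lat[-1]),
    r = 6371008.8
  )
  default_meta <- list(frequency_khz = 200, pulse_ms = 0.2, beam_deg = 12,
                       sound_speed = 1500, gain_setting = NA_character_,
                       ping_rate_hz = NA_real_)
  meta <- utils::modifyList(default_meta, meta)
  structure(list(
    intensity = intensity,
    depth = depth,
    along_track = c(0, cumsum(steps)),
    lat = records$lat,
    lon = records$lon,
    utc_ms = records$utc_ms,
    survey_id = records$survey_id[1],
    meta = meta
  ), class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat("<echogram>", nrow(x$intensity), "pings x", ncol(x$intensity),
      "bins;", sprintf("depth %.2f-%.2f m;", min(x$depth), max(x$depth)),
      sprintf("track %.1f m", max(x$along_track)), "\n")
  invisible(x)
}

#' @export
dim.echogram <- function(x) dim(x$intensity)

# Sentinel used for samples removed by background-noise subtraction;
# excluded from all linear-domain means downstream.
FLOOR_DB <- -999

#' Linear-domain mean of relative intensities
#'
#' Averages dB values as powers and re-expresses the mean in dB (the "mean
#' Sv" convention). Floor-sentinel (-999 dB) and `NA` samples are excluded.
#'
#' @param db numeric vector of dB values.
#' @return mean intensity in dB (`-Inf` if no usable samples).
#' @export
mean_db <- function(db) {
  db <- db[!is.na(db) & db > FLOOR_DB]
  if (!length(db)) return(-Inf)
  10 * log10(mean(10^(db / 10)))
}
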