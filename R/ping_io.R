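#' Construct a table of ping records
#'
#' A ping record is one acoustic transmission: navigation fix, range window
#' and the stored 8-bit sample vector. Records are held as a data frame with
#' one row per ping and a list column `samples` of integer vectors, class
#' `ping_records`.
#'
#' @param survey_id character survey identifier (recycled).
#' @param ping integer ping numbers.
#' @param utc_ms numeric UTC timestamps in milliseconds since the Unix epoch.
#' @param lat,lon decimal-degree navigation fixes.
#' @param min_range_m,max_range_m range window of the stored samples (m).
#' @param samples list of integer vectors, each value in `[0, 255]`.
#' @return a `ping_records` data frame.
#' @export
ping_records <- function(survey_id, ping, utc_ms, lat, lon,
                         min_range_m, max_range_m, samples) {
  n <- length(ping)
  df <- data.frame(
    survey_id = rep_len(as.character(survey_id), n),
    ping = as.integer(ping),
    utc_ms = as.numeric(utc_ms),
    lat = as.numeric(lat),
    lon = as.numeric(lon),
    min_range_m = rep_len(as.numeric(min_range_m), n),
    max_range_m = rep_len(as.numeric(max_range_m), n),
    n_samples = vapply(samples, length, integer(1)),
    stringsAsFactors = FALSE
  )
  df$samples <- lapply(samples, as.integer)
  class(df) <- c("ping_records", "data.frame")
  validate_ping_records(df)
  df
}

validate_ping_records <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$min_range_m < 0) || any(df$min_range_m >= df$max_range_m)) {
    stop("range window invalid: need 0 <= min_range < max_range")
  }
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)) {
    stop("latitude/longitude out of range")
  }
  if (any(df$n_samples != vapply(df$samples, length, integer(1)))) {
    stop("n_samples does not match sample vector length")
  }
  bad <- vapply(df$samples, function(s) {
    any(is.na(s)) || any(s < 0L) || any(s > 255L)
  }, logical(1))
  if (any(bad)) {
    stop("sample values outside [0, 255] in ping(s): ",
         paste(df$ping[bad], collapse = ", "))
  }
  invisible(df)
}

ping_csv_header <- c("survey_id", "ping", "utc_ms", "lat", "lon",
                     "min_range_m", "max_range_m", "n_samples")

#' Write ping records to the pipeline CSV schema
#'
#' One row per ping with header
#' `survey_id,ping,utc_ms,lat,lon,min_range_m,max_range_m,n_samples,s0,s1,...`.
#' The round trip through [read_ping_csv()] is bit-exact for every field,
#' including each 8-bit sample.
#'
#' @param records a `ping_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ping_csv <- function(records, path) {
  validate_ping_records(records)
  n_max <- if (nrow(records)) max(records$n_samples) else 0L
  header <- c(ping_csv_header,
              if (n_max > 0) paste0("s", seq_len(n_max) - 1L))
  lines <- character(nrow(records))
  for (k in seq_len(nrow(records))) {
    s <- records$samples[[k]]
    length(s) <- n_max  # pad with NA -> empty fields
    lines[k] <- paste(c(
      records$survey_id[k],
      records$ping[k],
      sprintf("%.17g", records$utc_ms[k]),
      sprintf("%.17g", records$lat[k]),
      sprintf("%.17g", records$lon[k]),
      sprintf("%.17g", records$min_range_m[k]),
      sprintf("%.17g", records$max_range_m[k]),
      records$n_samples[k],
      ifelse(is.na(s), "", s)
    ), collapse = ",")
  }
  writeLines(c(paste(header, collapse = ","), lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read ping records from the pipeline CSV schema
#'
#' Inverse of [write_ping_csv()]. The header must contain the mandatory
#' columns; malformed rows are reported with their file line numbers and
#' out-of-range sample values name the offending ping.
#'
#' @param path CSV file path.
#' @return a `ping_records` data frame, rows in file order.
#' @export
read_ping_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = NA)
  missing_cols <- setdiff(ping_csv_header, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  sample_cols <- grep("^s[0-9]+$", names(raw), value = TRUE)
  sample_cols <- sample_cols[order(as.integer(sub("^s", "", sample_cols)))]
  if (nrow(raw) == 0) {
    return(ping_records(character(0), integer(0), numeric(0), numeric(0),
                        numeric(0), numeric(0), numeric(0), list())[0, ])
  }
  smat <- as.matrix(raw[, sample_cols, drop = FALSE])
  bad_rows <- which(!is.finite(raw$ping) | !is.finite(raw$utc_ms) |
                      !is.finite(raw$n_samples))
  if (length(bad_rows)) {
    stop("malformed row(s) at file line(s): ",
         paste(bad_rows + 1L, collapse = ", "))  # +1 for header line
  }
  samples <- lapply(seq_len(nrow(raw)), function(k) {
    s <- smat[k, seq_len(raw$n_samples[k])]
    if (any(is.na(s))) {
      stop("malformed row at file line ", k + 1L,
           ": fewer samples than n_samples")
    }
    as.integer(s)
  })
  ping_records(raw$survey_id, raw$ping, raw$utc_ms, raw$lat, raw$lon,
               raw$min_range_m, raw$max_range_m, samples)
}

#' Convert UTC timestamps to New Zealand standard time
#'
#' Applies a fixed +12:00 offset (NZST) with no daylight-saving logic; field
#' seasons span DST boundaries ambiguously so the civil-time rule is
#' deliberately not used.
#'
#' @param utc_ms numeric UTC milliseconds since the Unix epoch.
#' @return `POSIXct` in the fixed-offset zone `Etc/GMT-12` (UTC+12).
#' @export
utc_to_local <- function(utc_ms) {
  if (any(!is.finite(utc_ms))) stop("invalid timestamp")
  as.POSIXct(utc_ms / 1000, origin = "1970-01-01", tz = "Etc/GMT-12")
}

#' Convert NZST local time back to UTC milliseconds
#'
#' @param local `POSIXct` times (any fixed-offset representation).
#' @return numeric UTC milliseconds since the Unix epoch.
#' @export
local_to_utc <- function(local) {
  as.numeric(local) * 1000
}
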