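#' Cumulative school area per kilometre of track (c.SchA)
#'
#' Sum of the (beam-corrected) areas of all valid schools detected in a
#' survey, standardised by survey distance -- m^2 per km.
#'
#' @param schools school data frame from [detect_schools()] (rows with
#'   `valid = FALSE` are excluded).
#' @param distance_km survey track length, km (> 0).
#' @param corrected use corrected areas `Ac` (default) or raw `A`.
#' @return c.SchA in m^2/km.
#' @export
cumulative_school_area <- function(schools, distance_km, corrected = TRUE) {
  if (!is.finite(distance_km) || distance_km <= 0) {
    stop("survey distance must be positive")
  }
  if (nrow(schools) == 0) return(0)
  use <- if ("valid" %in% names(schools)) schools$valid else rep(TRUE, nrow(schools))
  area <- if (corrected) schools$Ac else schools$A
  sum(area[use], na.rm = TRUE) / distance_km
}

#' Proportion of the survey track over which schools were detected
#'
#' Sums corrected school lengths `Lc` over the survey and divides by the
#' survey distance. By default the along-track intervals spanned by the
#' schools are merged before summation, so stacked or overlapping schools
#' are not double-counted and the result is a true proportion (<= 1 for
#' schools within the track).
#'
#' @param schools school data frame (needs `Lc`, `valid`, and -- for union
#'   semantics -- `x_min`, `x_max`).
#' @param distance_m survey track length, m (> 0).
#' @param union merge overlapping along-track intervals (default `TRUE`);
#'   `FALSE` gives the plain sum of `Lc`.
#' @return Prop.Track, dimensionless.
#' @export
prop_track <- function(schools, distance_m, union = TRUE) {
  if (!is.finite(distance_m) || distance_m <= 0) {
    stop("survey distance must be positive")
  }
  if (nrow(schools) == 0) return(0)
  use <- if ("valid" %in% names(schools)) schools$valid else rep(TRUE, nrow(schools))
  schools <- schools[use, , drop = FALSE]
  if (nrow(schools) == 0) return(0)
  if (!union) return(sum(schools$Lc) / distance_m)
  ctr <- (schools$x_min + schools$x_max) / 2
  lo <- ctr - schools$Lc / 2
  hi <- ctr + schools$Lc / 2
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[k])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    }
  }
  total <- total + (cur_hi - cur_lo)
  total / distance_m
}

#' Derive the survey season from its date
#'
#' January-March is summer, August-October winter; anything else is
#' `"other"` with a warning (the survey design has no effort in those
#' months).
#'
#' @param date a `Date` (or something `as.Date()` accepts).
#' @return `"summer"`, `"winter"` or `"other"`.
#' @export
survey_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  out <- ifelse(m %in% 1:3, "summer", ifelse(m %in% 8:10, "winter", "other"))
  if (any(out == "other")) {
    warning("survey date(s) outside both season windows; season set to \"other\"")
  }
  out
}

#' Summarise a survey's detected schools into RAPP metrics
#'
#' @param schools school data frame for the survey.
#' @param survey one-row data frame or list with `survey_id`, `region`,
#'   `date`, `distance_km`.
#' @param corrected use beam-corrected areas for c.SchA.
#' @param union union semantics for Prop.Track.
#' @return one-row data frame: `survey_id`, `region`, `season`,
#'   `distance_km`, `c_scha`, `prop_track`, `n_schools` (valid schools) and
#'   `n_invalid` (schools excluded for non-positive corrected dimensions).
#' @export
summarize_survey <- function(schools, survey, corrected = TRUE, union = TRUE) {
  valid <- if (nrow(schools)) schools$valid else logical(0)
  data.frame(
    survey_id = survey$survey_id,
    region = survey$region,
    season = survey_season(survey$date),
    distance_km = survey$distance_km,
    c_scha = cumulative_school_area(schools, survey$distance_km, corrected),
    prop_track = prop_track(schools, survey$distance_km * 1000, union),
    n_schools = sum(valid),
    n_invalid = sum(!valid),
    stringsAsFactors = FALSE
  )
}
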