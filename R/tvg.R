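#' Extract calibration-sphere measurement regions from an echogram
#'
#' For each annotated ping, finds the maximum-intensity bin within +/- 1 m
#' of the expected sphere depth and takes the standard 8 x 1 (vertical by
#' horizontal) window around it. The region's mean intensity is the
#' linear-domain mean of the window, re-expressed in dB. Regions whose
#' window holds no sample above the noise floor are skipped with a warning.
#'
#' @param echogram an [pings_to_echogram()] echogram of the sphere drop
#'   (raw, uncorrected intensities).
#' @param sphere_track data frame with columns `ping` and `depth` (expected
#'   sphere depth per annotated ping, m).
#' @param noise_floor_db samples at or below this raw level are treated as
#'   empty, dB.
#' @return data frame of sphere regions: `ping`, `depth` (window centre, m),
#'   `mean_intensity` (dB).
#' @export
extract_sphere_regions <- function(echogram, sphere_track,
                                   noise_floor_db = -47) {
  stopifnot(inherits(echogram, "echogram"),
            all(c("ping", "depth") %in% names(sphere_track)))
  n_bins <- ncol(echogram$intensity)
  out <- vector("list", nrow(sphere_track))
  skipped <- 0L
  for (k in seq_len(nrow(sphere_track))) {
    p <- sphere_track$ping[k]
    z <- sphere_track$depth[k]
    search <- which(abs(echogram$depth - z) <= 1)
    if (!length(search)) { skipped <- skipped + 1L; next }
    vals <- echogram$intensity[p, search]
    if (all(!is.finite(vals) | vals <= noise_floor_db)) {
      skipped <- skipped + 1L
      next
    }
    ctr <- search[which.max(vals)]
    win <- (ctr - 3):(ctr + 4)
    win <- win[win >= 1 & win <= n_bins]
    out[[k]] <- data.frame(
      ping = p,
      depth = echogram$depth[ctr],
      mean_intensity = mean_db(echogram$intensity[p, win])
    )
  }
  if (skipped > 0) {
    warning(skipped, " annotated ping(s) had no sample above the noise ",
            "floor in the search window and were skipped")
  }
  regions <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(regions)) {
    regions <- data.frame(ping = integer(0), depth = numeric(0),
                          mean_intensity = numeric(0))
  }
  regions
}

#' Select the TVG form that flattens sphere intensity against depth
#'
#' For each candidate range coefficient xi in `candidates`, corrects every
#' region's mean intensity by `xi * log10(depth) + 2 * alpha * depth` and
#' computes the Pearson correlation between corrected intensity and depth.
#' The selected form is the candidate minimising the absolute correlation
#' (positive or negative); ties break toward the smaller, less aggressive
#' coefficient. A residual-correlation warning is issued when even the best
#' candidate leaves |r| > 0.5 (the data's depth dependence is then outside
#' the candidate family).
#'
#' @param regions sphere-region data frame from [extract_sphere_regions()].
#' @param alpha absorption coefficient, dB/m (from
#'   [absorption_coefficient()]).
#' @param candidates candidate TVG range coefficients.
#' @param sound_speed sound speed recorded with the fit, m/s (metadata).
#' @return a `tvg_fit` list: `xi_selected`, `alpha`, `correlation_by_xi`,
#'   `sound_speed`, `n_regions`.
#' @export
fit_tvg_form <- function(regions, alpha, candidates = c(10, 15, 20, 40),
                         sound_speed = NA_real_) {
  if (nrow(regions) < 10) stop("need at least 10 sphere regions")
  if (diff(range(regions$depth)) < 10) {
    stop("sphere regions must span at least 10 m of depth")
  }
  if (stats::sd(regions$depth) == 0) stop("degenerate depth variance")
  cors <- vapply(candidates, function(xi) {
    corrected <- regions$mean_intensity + xi * log10(regions$depth) +
      2 * alpha * regions$depth
    stats::cor(corrected, regions$depth)
  }, numeric(1))
  names(cors) <- as.character(candidates)
  ord <- order(abs(cors), candidates)  # ties -> smaller xi
  xi_selected <- candidates[ord[1]]
  if (abs(cors[ord[1]]) > 0.5) {
    warning("residual correlation |r| = ", round(abs(cors[ord[1]]), 2),
            " after best TVG form; depth dependence not captured by the ",
            "candidate set")
  }
  structure(list(xi_selected = xi_selected, alpha = alpha,
                 correlation_by_xi = cors, sound_speed = sound_speed,
                 n_regions = nrow(regions)),
            class = "tvg_fit")
}

#' @export
print.tvg_fit <- function(x, ...) {
  cat("<tvg_fit> selected", paste0(x$xi_selected, "log"),
      sprintf("(alpha = %.4f dB/m, %d regions)\n", x$alpha, x$n_regions))
  print(round(x$correlation_by_xi, 4))
  invisible(x)
}

#' Manually construct a TVG correction
#'
#' @param xi TVG range coefficient.
#' @param alpha absorption coefficient, dB/m.
#' @param sound_speed sound speed, m/s (metadata).
#' @return a `tvg_fit` list.
#' @export
tvg_fit <- function(xi, alpha, sound_speed = NA_real_) {
  structure(list(xi_selected = xi, alpha = alpha,
                 correlation_by_xi = stats::setNames(NA_real_, xi),
                 sound_speed = sound_speed, n_regions = NA_integer_),
            class = "tvg_fit")
}

tvg_curve <- function(fit, depth) {
  ifelse(depth > 0,
         fit$xi_selected * log10(pmax(depth, 1e-12)) +
           2 * fit$alpha * depth,
         NA_real_)
}

#' Apply a TVG correction to an echogram
#'
#' Adds `xi * log10(z) + 2 * alpha * z` to every sample at depth `z`,
#' removing the depth dependence of the stored relative intensities. Bins
#' at depth <= 0 are masked (`NA`); shape and axes are unchanged.
#'
#' @param echogram an `echogram`.
#' @param fit a `tvg_fit` from [fit_tvg_form()] or [tvg_fit()].
#' @return the corrected `echogram`, with the fit recorded in
#'   `$meta$tvg_fit`.
#' @export
apply_tvg <- function(echogram, fit) {
  stopifnot(inherits(echogram, "echogram"), inherits(fit, "tvg_fit"))
  corr <- tvg_curve(fit, echogram$depth)
  out <- echogram
  out$intensity <- sweep(echogram$intensity, 2, corr, `+`)
  out$intensity[, echogram$depth <= 0] <- NA_real_
  out$meta$tvg_fit <- fit
  out
}
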