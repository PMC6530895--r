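#' Fit a negative-binomial GAMM of predator counts against a RAPP metric
#'
#' Model: `log mu = b0 + s(predictor) + b_region + log(distance)` with a
#' negative-binomial response. The smooth is a cubic regression spline with
#' basis dimension 4 (the "maximum of 4 knots" ceiling that prevents
#' over-smoothing); the region term is a penalized per-region random
#' intercept (`bs = "re"`); survey distance enters as a log offset so
#' counts are modelled per unit of search effort. Smoothness and the NB
#' dispersion are estimated together by (restricted) maximum likelihood
#' outer iteration in \pkg{mgcv}.
#'
#' @param data survey data frame with the response column, the predictor
#'   column, `region` and `distance_km`.
#' @param response name of the count column (non-negative integers).
#' @param predictor name of the RAPP metric column (`"c_scha"` or
#'   `"prop_track"`).
#' @param k basis dimension of the smooth.
#' @param method smoothing-parameter criterion passed to [mgcv::gam()].
#' @param offset_distance include `log(distance_km)` as an offset
#'   (default); `FALSE` drops it.
#' @return an `nb_gamm` object wrapping the [mgcv::gam] fit with `response`,
#'   `predictor`, `edf` (total effective degrees of freedom), `aic`,
#'   `deviance_explained` (%), `nb_dispersion` (size parameter theta) and
#'   `region_effects`.
#' @export
fit_nb_gamm <- function(data, response, predictor, k = 4, method = "REML",
                        offset_distance = TRUE) {
  if (nrow(data) < 30) stop("need at least 30 surveys to fit the GAMM")
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integer counts")
  }
  if (length(unique(data$region)) < 2) stop("need at least 2 regions")
  if (stats::var(data[[predictor]]) == 0) stop("predictor has zero variance")
  data$region <- factor(data$region)
  fml <- stats::as.formula(paste0(
    response, " ~ s(", predictor, ", bs = \"cr\", k = ", k, ")",
    " + s(region, bs = \"re\")",
    if (offset_distance) " + offset(log(distance_km))" else ""
  ))
  fit <- mgcv::gam(fml, family = mgcv::nb(), method = method, data = data)
  if (!fit$converged) stop("GAMM fit failed to converge")
  sm <- summary(fit)
  re_coef <- stats::coef(fit)
  re_coef <- re_coef[grep("^s\\(region\\)", names(re_coef))]
  names(re_coef) <- levels(data$region)
  structure(list(
    fit = fit,
    response = response,
    predictor = predictor,
    edf = sum(fit$edf),
    edf_smooth = unname(sm$s.table[1, "edf"]),
    aic = stats::AIC(fit),
    deviance_explained = 100 * sm$dev.expl,
    nb_dispersion = fit$family$getTheta(TRUE),
    region_effects = re_coef,
    n = nrow(data)
  ), class = "nb_gamm")
}

#' @export
print.nb_gamm <- function(x, ...) {
  cat(sprintf("<nb_gamm> %s ~ s(%s) + RE(region); edf %.1f, AIC %.1f, ",
              x$response, x$predictor, x$edf, x$aic),
      sprintf("deviance explained %.1f%%, theta %.2f\n",
              x$deviance_explained, x$nb_dispersion))
  invisible(x)
}

#' Percentage of null deviance explained by a fitted count model
#'
#' `100 * (1 - D_model / D_null)` with the null model being intercept plus
#' offset only, in the same family (mgcv computes the null deviance of the
#' fit at the estimated dispersion).
#'
#' @param result an `nb_gamm`.
#' @return deviance explained, %.
#' @export
deviance_explained <- function(result) {
  stopifnot(inherits(result, "nb_gamm"))
  100 * (1 - result$fit$deviance / result$fit$null.deviance)
}

#' Evaluate the fitted smooth with a pointwise 95% band
#'
#' @param result an `nb_gamm`.
#' @param n number of evaluation points across the predictor range.
#' @param at optional explicit predictor values (overrides `n`).
#' @param se_with_mean include the uncertainty of the model constant in
#'   the band (`type = "iterms"`); this is the band whose across-the-
#'   function coverage is close to nominal and the right choice for
#'   comparing the smooth against a reference curve.
#' @return data frame `x`, `smooth`, `lower`, `upper` (log-link scale,
#'   smooth term only, centred as fitted).
#' @export
smooth_curve <- function(result, n = 100, at = NULL, se_with_mean = FALSE) {
  stopifnot(inherits(result, "nb_gamm"))
  mf <- result$fit$model
  xvals <- if (is.null(at)) {
    seq(min(mf[[result$predictor]]), max(mf[[result$predictor]]),
        length.out = n)
  } else {
    at
  }
  nd <- data.frame(x = xvals,
                   region = mf$region[1],
                   distance_km = 1)
  names(nd)[1] <- result$predictor
  pr <- mgcv::predict.gam(result$fit, newdata = nd,
                          type = if (se_with_mean) "iterms" else "terms",
                          se.fit = TRUE)
  col <- grep(result$predictor, colnames(pr$fit), fixed = TRUE)
  data.frame(x = xvals,
             smooth = pr$fit[, col],
             lower = pr$fit[, col] - 1.96 * pr$se.fit[, col],
             upper = pr$fit[, col] + 1.96 * pr$se.fit[, col])
}

#' Fit both RAPP metrics and rank them by AIC
#'
#' Fits `response ~ s(c_scha)` and `response ~ s(prop_track)` (each with
#' the region random effect and distance offset) and ranks the two models
#' by AIC -- the study's criterion for the best prey metric per predator.
#'
#' @param data survey data frame.
#' @param response count column name.
#' @param ... passed to [fit_nb_gamm()].
#' @return list of the two `nb_gamm` fits ordered best-first, with
#'   attributes `ranking` (predictor names) and `delta_aic`.
#' @export
select_best_metric <- function(data, response, ...) {
  fits <- list(
    c_scha = fit_nb_gamm(data, response, "c_scha", ...),
    prop_track = fit_nb_gamm(data, response, "prop_track", ...)
  )
  ord <- order(vapply(fits, function(f) f$aic, numeric(1)))
  fits <- fits[ord]
  attr(fits, "ranking") <- names(fits)
  attr(fits, "delta_aic") <- fits[[2]]$aic - fits[[1]]$aic
  fits
}

#' Plot a fitted smooth with its 95% band
#'
#' Smoothed RAPP effect on the log-link scale with a pointwise 95%
#' confidence band and a rug showing the distribution of the predictor.
#'
#' @param result an `nb_gamm`.
#' @param file output figure path (`.png`, `.svg`, `.pdf`); `NULL` returns
#'   the ggplot object without writing.
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_smooth <- function(result, file = NULL) {
  crv <- smooth_curve(result)
  obs <- data.frame(x = result$fit$model[[result$predictor]])
  unit <- if (result$predictor == "c_scha") "c.SchA (m²/km)" else
    "Prop.Track (proportion of track)"
  g <- ggplot2::ggplot(crv, ggplot2::aes(x = x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = smooth)) +
    ggplot2::geom_rug(data = obs, ggplot2::aes(x = x),
                      inherit.aes = FALSE, sides = "b",
                      length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(x = unit,
                  y = sprintf("s(%s, %.1f)", result$predictor,
                              sum(result$fit$edf)),
                  title = sprintf("Smoothed RAPP effect on %s counts",
                                  result$response)) +
    ggplot2::theme_minimal()
  if (is.null(file)) return(g)
  ggplot2::ggsave(file, g, width = 6, height = 4, dpi = 150)
  invisible(g)
}
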