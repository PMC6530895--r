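#' SHAPES detection parameters
#'
#' Threshold, candidate minima, linking distances and school minima for the
#' threshold / candidate-detection / linking / minimum-dimension school
#' detector. Three named presets cover the study configurations:
#' `"ground_truth"` (3 m length, 1.5 m thickness minima used to
#' characterise known schools), `"survey_results"` (5 m / 2 m, the minima
#' justified by the observed dimension distribution and used for the
#' predator-prey surveys) and `"survey_methods"` (5 m / 3 m, the
#' alternative survey parameterisation).
#'
#' @param threshold analysis threshold, dB relative intensity.
#' @param min_candidate_length,min_candidate_thickness minimum metric
#'   extent of a 4-connected candidate region, m.
#' @param max_horizontal_link,max_vertical_link maximum bounding-box gaps
#'   across which candidates are linked into one school, m.
#' @param min_school_length,min_school_thickness minimum dimensions of a
#'   linked school, m.
#' @param preset optional preset name; explicit arguments override preset
#'   values.
#' @return a `shapes_params` list.
#' @export
shapes_params <- function(threshold = -35,
                          min_candidate_length = 1,
                          min_candidate_thickness = 0.5,
                          max_horizontal_link = 5,
                          max_vertical_link = 2,
                          min_school_length = 3,
                          min_school_thickness = 1.5,
                          preset = NULL) {
  p <- list(threshold = threshold,
            min_candidate_length = min_candidate_length,
            min_candidate_thickness = min_candidate_thickness,
            max_horizontal_link = max_horizontal_link,
            max_vertical_link = max_vertical_link,
            min_school_length = min_school_length,
            min_school_thickness = min_school_thickness)
  if (!is.null(preset)) {
    dims <- switch(preset,
      ground_truth = c(length = 3, thickness = 1.5),
      survey_results = c(length = 5, thickness = 2),
      survey_methods = c(length = 5, thickness = 3),
      stop("unknown preset: ", preset)
    )
    if (missing(min_school_length)) p$min_school_length <- dims[["length"]]
    if (missing(min_school_thickness)) p$min_school_thickness <- dims[["thickness"]]
  }
  lengths_pos <- c(p$min_candidate_length, p$min_candidate_thickness,
                   p$max_horizontal_link, p$max_vertical_link,
                   p$min_school_length, p$min_school_thickness)
  if (any(lengths_pos <= 0)) stop("all SHAPES lengths must be positive")
  if (p$min_school_length < p$min_candidate_length ||
      p$min_school_thickness < p$min_candidate_thickness) {
    stop("school minima must be >= candidate minima")
  }
  structure(p, class = "shapes_params")
}

# 4-connected component labelling of a logical matrix; returns a list of
# cell-index matrices (cbind(ping, bin)). Union-find with path halving over
# the right/down adjacencies (no diagonal bridges).
label_components <- function(mask) {
  cells <- which(mask)
  if (!length(cells)) return(list())
  np <- nrow(mask)
  nc <- length(mask)
  id <- seq_along(cells)
  pos <- integer(nc)
  pos[cells] <- id
  p <- ((cells - 1L) %% np) + 1L
  b <- ((cells - 1L) %/% np) + 1L
  right_nb <- ifelse(p < np, pos[pmin(cells + 1L, nc)], 0L)
  down_nb <- ifelse(cells + np <= nc, pos[pmin(cells + np, nc)], 0L)
  edges <- rbind(cbind(id, right_nb)[right_nb > 0L, , drop = FALSE],
                 cbind(id, down_nb)[down_nb > 0L, , drop = FALSE])
  parent <- id
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1L])
      rj <- find(edges[e, 2L])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(id, find, integer(1))
  lapply(split(id, roots),
         function(ix) cbind(ping = p[ix], bin = b[ix]))
}

#' Detect above-threshold candidate regions
#'
#' 4-connected components of in-domain samples at or above the analysis
#' threshold; components whose metric extent falls below the candidate
#' minima are discarded. 4-connectivity (not 8) prevents diagonal
#' single-cell bridges between distinct schools.
#'
#' @param echogram corrected, noise-removed `echogram`.
#' @param domain an [build_analysis_domain()] domain (or `NULL` for the
#'   whole echogram).
#' @param params a [shapes_params()].
#' @return list of candidate regions (cell-index matrices with attributes
#'   `bbox_x`, `bbox_z` in metres).
#' @export
detect_candidates <- function(echogram, domain, params) {
  stopifnot(inherits(echogram, "echogram"), inherits(params, "shapes_params"))
  mask <- !is.na(echogram$intensity) &
    echogram$intensity > FLOOR_DB &
    echogram$intensity >= params$threshold
  if (!is.null(domain)) mask <- mask & domain$mask
  comps <- label_components(mask)
  dx <- cell_width(echogram)
  dz <- cell_height(echogram)
  keep <- list()
  for (comp in comps) {
    ext <- region_extent(comp, echogram, dx, dz)
    if (ext$L >= params$min_candidate_length &&
        ext$T >= params$min_candidate_thickness) {
      attr(comp, "bbox_x") <- ext$bbox_x
      attr(comp, "bbox_z") <- ext$bbox_z
      keep[[length(keep) + 1]] <- comp
    }
  }
  keep
}

cell_width <- function(echogram) {
  if (length(echogram$along_track) < 2) return(NA_real_)
  stats::median(diff(echogram$along_track))
}

cell_height <- function(echogram) {
  stats::median(diff(echogram$depth))
}

region_extent <- function(cells, echogram, dx, dz) {
  xr <- range(echogram$along_track[cells[, "ping"]])
  zr <- range(echogram$depth[cells[, "bin"]])
  list(L = diff(xr) + dx, T = diff(zr) + dz,
       bbox_x = xr + c(-dx / 2, dx / 2), bbox_z = zr + c(-dz / 2, dz / 2))
}

#' Link nearby candidates into schools
#'
#' Candidates whose bounding boxes are separated by at most
#' `max_horizontal_link` metres along-track *and* `max_vertical_link`
#' metres vertically are merged, transitively, into single schools. The
#' result is invariant to the input order of the candidates.
#'
#' @param candidates output of [detect_candidates()].
#' @param params a [shapes_params()].
#' @return list of school regions (merged cell-index matrices).
#' @export
link_candidates <- function(candidates, params) {
  n <- length(candidates)
  if (n <= 1) return(candidates)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    bi_x <- attr(candidates[[i]], "bbox_x")
    bi_z <- attr(candidates[[i]], "bbox_z")
    for (j in (i + 1):n) {
      bj_x <- attr(candidates[[j]], "bbox_x")
      bj_z <- attr(candidates[[j]], "bbox_z")
      hgap <- max(0, max(bi_x[1], bj_x[1]) - min(bi_x[2], bj_x[2]))
      vgap <- max(0, max(bi_z[1], bj_z[1]) - min(bi_z[2], bj_z[2]))
      if (hgap <= params$max_horizontal_link &&
          vgap <= params$max_vertical_link) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(ix) {
    merged <- do.call(rbind, lapply(candidates[ix], function(m) {
      attributes(m)[c("bbox_x", "bbox_z")] <- NULL
      m[, c("ping", "bin"), drop = FALSE]
    }))
    merged[!duplicated(merged), , drop = FALSE]
  })
}

#' Measure a school region
#'
#' Uncorrected morphology in the "exported school table" convention:
#' length `L` is the along-track extent of the occupied pings (plus one
#' cell width), thickness `T` the vertical extent of occupied bins, area
#' `A` the summed area of member cells, depth `D` the (area-weighted, i.e.
#' plain for uniform cells) mean depth of member cells, and
#' `mean_intensity` the linear-domain mean re-expressed in dB.
#'
#' @param region a cell-index matrix (`ping`, `bin`).
#' @param echogram the measured `echogram`.
#' @return one-row data frame with `ping_min`, `ping_max`, `x_min`,
#'   `x_max`, `depth_min`, `depth_max`, `L`, `T`, `A`, `D`,
#'   `mean_intensity`, `n_cells`.
#' @export
school_metrics <- function(region, echogram) {
  stopifnot(nrow(region) > 0)
  dx <- cell_width(echogram)
  dz <- cell_height(echogram)
  ext <- region_extent(region, echogram, dx, dz)
  vals <- echogram$intensity[region]
  data.frame(
    ping_min = min(region[, "ping"]), ping_max = max(region[, "ping"]),
    x_min = ext$bbox_x[1], x_max = ext$bbox_x[2],
    depth_min = ext$bbox_z[1], depth_max = ext$bbox_z[2],
    L = ext$L, T = ext$T,
    A = nrow(region) * dx * dz,
    D = mean(echogram$depth[region[, "bin"]]),
    mean_intensity = mean_db(vals),
    n_cells = nrow(region)
  )
}

#' Filter linked schools by minimum dimensions
#'
#' @param schools data frame of measured schools (rows from
#'   [school_metrics()]).
#' @param params a [shapes_params()].
#' @return the retained rows; attributes `n_retained` / `n_discarded`
#'   report the counts.
#' @export
filter_schools <- function(schools, params) {
  keep <- schools$L >= params$min_school_length &
    schools$T >= params$min_school_thickness
  out <- schools[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Correct school morphology for beam geometry
#'
#' The acoustic beam widens with depth and the transmitted pulse has finite
#' length, so raw school dimensions are biased upward. The corrections are
#' \deqn{L_c = L - 2 D \tan(\phi/2)}
#' \deqn{T_c = T - (C/2)(\tau/1000)}
#' \deqn{A_c = A (L_c T_c)/(L T), \quad L T \neq 0}
#' with `D` mean school depth (m), `phi` the 3 dB beam angle (degrees),
#' `C` the sound speed (m/s) and `tau` the pulse length (ms). Schools whose
#' corrected dimensions are non-positive (or with `L * T = 0`) are retained
#' but flagged `valid = FALSE` and excluded from downstream prey metrics.
#'
#' @param schools data frame with columns `L`, `T`, `A`, `D`.
#' @param meta list with `beam_deg`, `sound_speed`, `pulse_ms` (an
#'   echogram's `$meta` works).
#' @return `schools` with columns `Lc`, `Tc`, `Ac`, `valid` appended.
#' @export
beam_correct <- function(schools, meta) {
  phi <- meta$beam_deg * pi / 180
  schools$Lc <- schools$L - 2 * schools$D * tan(phi / 2)
  schools$Tc <- schools$T - (meta$sound_speed / 2) * (meta$pulse_ms / 1000)
  lt <- schools$L * schools$T
  schools$Ac <- ifelse(lt != 0, schools$A * (schools$Lc * schools$Tc) / lt,
                       NA_real_)
  schools$valid <- lt != 0 & schools$Lc > 0 & schools$Tc > 0
  schools$Ac[!schools$valid] <- NA_real_
  schools
}

#' Detect, link, measure, filter and correct schools on an echogram
#'
#' Convenience wrapper running the full school-detection chain. Schools
#' whose upper edge touches the near-field line and whose aspect ratio
#' `L/T` exceeds `aspect_flag` are flagged `review = TRUE` (surface noise,
#' bubbles and wake produce such shapes) but are not dropped.
#'
#' @param echogram corrected, noise-removed `echogram`.
#' @param domain analysis domain (or `NULL`).
#' @param params a [shapes_params()].
#' @param aspect_flag review-flag ceiling on `L/T` for surface-touching
#'   schools.
#' @return data frame of schools (possibly 0 rows) with morphology,
#'   corrections, `valid` and `review` columns.
#' @export
detect_schools <- function(echogram, domain, params, aspect_flag = 50) {
  cands <- detect_candidates(echogram, domain, params)
  linked <- link_candidates(cands, params)
  if (!length(linked)) {
    out <- school_metrics(cbind(ping = 1L, bin = 1L), echogram)[0, ]
    out <- beam_correct(out, echogram$meta)
    out$review <- logical(0)
    return(out)
  }
  measured <- do.call(rbind, lapply(linked, school_metrics,
                                    echogram = echogram))
  measured <- filter_schools(measured, params)
  measured <- beam_correct(measured, echogram$meta)
  nearfield <- if (!is.null(domain)) domain$nearfield_depth else 3
  measured$review <- measured$depth_min <= nearfield + cell_height(echogram) &
    measured$L / measured$T > aspect_flag
  rownames(measured) <- NULL
  measured
}
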