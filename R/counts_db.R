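#' Convert 8-bit sample counts to relative intensity (dB)
#'
#' Recreational-grade echosounders export water-column samples as linear
#' 8-bit integers. The manufacturer's exact linear-to-dB mapping is
#' proprietary, so the package uses a declared affine-in-log mapping,
#' \deqn{dB = 20 \log_{10}(\max(c, 1) / 255),}
#' i.e. full scale (count 255) is 0 dB and the quantisation floor (count 1,
#' with zero counts clamped to 1) is about -48.13 dB. Any affine-in-log
#' mapping preserves the *relative*-intensity analysis the pipeline performs;
#' all dB values downstream are "relative dB (full scale = 0)".
#'
#' @param counts integer vector of sample counts, each in `[0, 255]`.
#' @return numeric vector of relative intensities in dB, in `[-48.13, 0]`.
#' @seealso [db_to_counts()] for the (quantising) inverse.
#' @export
#' @examples
#' counts_to_db(c(255, 1)) # 0 dB and the floor
counts_to_db <- function(counts) {
  if (!is.numeric(counts)) stop("`counts` must be numeric")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts > 255)) {
    stop("sample counts must lie in [0, 255]")
  }
  20 * log10(pmax(counts, 1) / 255)
}

#' Quantise relative dB to 8-bit sample counts
#'
#' Inverse of [counts_to_db()] up to 8-bit quantisation: counts are rounded
#' to the nearest integer and clamped to `[0, 255]`. Used by the synthetic
#' generators so simulated data pass through exactly the storage format the
#' instrument uses.
#'
#' @param db numeric vector of relative intensities (dB, full scale = 0).
#' @return integer vector of counts in `[0, 255]`.
#' @export
db_to_counts <- function(db) {
  counts <- round(255 * 10^(db / 20))
  as.integer(pmin(pmax(counts, 0), 255))
}
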