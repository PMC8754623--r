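#' Classify weight-for-age Z-scores
#'
#' Classifies children by weight-for-age Z-score (WAZ) against the WHO
#' reference-population median: below -2 SD is underweight, below -3 SD is
#' severely underweight. The boundaries are strict, so a child at exactly
#' -2 SD is classified as normal.
#'
#' @param waz Numeric vector of weight-for-age Z-scores. Must be finite.
#' @return An ordered factor with levels `normal < underweight < severe`.
#' @examples
#' classify_waz(c(0, -2.5, -3.2))
#' @seealso [is_underweight()] for the binary indicator used as the
#'   modelling outcome (`waz < -2`, so `severe` implies underweight).
#' @export
classify_waz <- function(waz) {
  if (!is.numeric(waz)) {
    abort("`waz` must be numeric.", class = "nd_invalid_input")
  }
  if (any(!is.finite(waz))) {
    abort("`waz` must be finite (no NA/NaN/Inf).", class = "nd_invalid_input")
  }
  out <- ifelse(waz < -3, "severe", ifelse(waz < -2, "underweight", "normal"))
  factor(out, levels = c("normal", "underweight", "severe"), ordered = TRUE)
}

#' Binary underweight indicator from WAZ
#'
#' @param waz Numeric vector of finite weight-for-age Z-scores.
#' @return Integer vector, 1 if `waz < -2` (strict), else 0.
#' @export
is_underweight <- function(waz) {
  if (!is.numeric(waz) || any(!is.finite(waz))) {
    abort("`waz` must be finite numeric.", class = "nd_invalid_input")
  }
  as.integer(waz < -2)
}
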