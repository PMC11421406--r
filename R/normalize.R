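#' Rankit rank-based inverse-normal transform
#'
#' Maps a value with (mean) rank r among n to the standard-normal
#' quantile of the plotting position (r - 0.5) / n.  Ties — frequent for
#' 7-category effort ratings — receive mean ranks before the transform,
#' so tied inputs stay tied.  With `scope`, the transform is applied
#' separately within each scope unit (e.g. per participant), which
#' removes between-participant differences in how the rating scale is
#' used while preserving each participant's ordering across conditions.
#'
#' @param values numeric or ordinal (integer) values.
#' @param scope optional vector of scope keys, same length as `values`;
#'   `NULL` means one global scope.
#' @return numeric vector of rank-normalized values.
#' @examples
#' rankit(c(3, 1, 2))                 # 0.674  -0.674  0
#' rankit(1:4, scope = c(1, 1, 2, 2)) # per-scope +-0.674
#' @export
rankit <- function(values, scope = NULL) {
  if (!length(values)) stop_vrt("rankit needs at least one value")
  if (is.null(scope)) scope <- rep(1L, length(values))
  if (length(scope) != length(values))
    stop_vrt("scope must have the same length as values")
  out <- rep(NA_real_, length(values))
  for (idx in split(seq_along(values), scope)) {
    v <- values[idx]
    if (!length(v) || all(is.na(v)))
      stop_vrt("empty scope unit in rankit")
    r <- rank(v, ties.method = "average", na.last = "keep")
    out[idx] <- qnorm((r - 0.5) / sum(!is.na(v)))
  }
  out
}

#' Within-participant z-transformation
#'
#' Standardizes values to mean 0 and (sample) SD 1 within each
#' participant, eliminating between-participant offsets and scale
#' differences in response behaviour while keeping each participant's
#' condition effects (SNR, masker type) intact.
#'
#' @param values numeric vector.
#' @param participant_keys participant id per value.
#' @return numeric vector of z-scores.
#' @export
zscore_within <- function(values, participant_keys) {
  if (length(values) != length(participant_keys))
    stop_vrt("participant_keys must have the same length as values")
  out <- rep(NA_real_, length(values))
  for (p in unique(participant_keys)) {
    idx <- which(participant_keys == p)
    v <- values[idx]
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      stop_vrt("participant '%s' has fewer than two values; cannot z-transform", p)
    s <- sd(v[ok])
    if (!is.finite(s) || s == 0)
      stop_vrt("participant '%s' has zero variance; cannot z-transform", p)
    out[idx] <- (v - mean(v[ok])) / s
  }
  out
}
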