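#' Verbal response time (VRT)
#'
#' VRT is the interval between the end of the presented sentence and the
#' onset of the first response token (matrix word or `<OOV>`).  Because
#' listeners sometimes start before the sentence ends, VRT can be
#' negative; a physiological floor of -150 ms is assumed (roughly the
#' minimal reaction time minus the mean word duration), and values at or
#' below the floor are clamped to -149 ms so the log transform stays
#' finite.  The manual-examiner convention instead clamps all negative
#' VRTs to zero.
#'
#' @param alignment a [response_alignment()]; its `sentence_end_s` must
#'   be set (join the trial table first if it came from a CTM file).
#' @param sentence_end_s optional override of the alignment's sentence
#'   end time.
#' @param convention `"asr"` (negative VRTs kept, floored at -149 ms) or
#'   `"manual"` (negative VRTs set to 0).
#' @return VRT in seconds, or `NA` for an empty (no-response) alignment.
#' @export
compute_vrt <- function(alignment, sentence_end_s = NULL,
                        convention = c("asr", "manual")) {
  convention <- match.arg(convention)
  end_s <- sentence_end_s %||% alignment$sentence_end_s
  if (is.na(end_s))
    stop_vrt("sentence_end_s is unknown; supply it or join the trial table")
  if (!nrow(alignment$tokens)) return(NA_real_)
  vrt_from_onset(alignment$tokens$onset_s[1L], end_s, convention)
}

vrt_from_onset <- function(first_onset_s, sentence_end_s,
                           convention = "asr") {
  v <- first_onset_s - sentence_end_s
  if (convention == "manual") return(pmax(v, 0))
  low <- !is.na(v) & v < -0.149
  if (any(low)) {
    warning(sprintf("%d VRT value(s) below the -150 ms floor clamped to -149 ms",
                    sum(low)), call. = FALSE)
    v[low] <- -0.149
  }
  v
}

#' Logarithmic VRT transform
#'
#' `log_vrt()` maps VRT (seconds) to `10 * ln((VRT + 0.15) / 0.15)`,
#' compensating the right-skew of response-time distributions; the
#' factor 10 scales typical values into roughly 0-100.  It is a strictly
#' increasing bijection from (-0.15 s, Inf) onto the real line;
#' `inv_log_vrt()` is its exact inverse, `0.15 * (exp(L / 10) - 1)`.
#'
#' @param vrt_s VRT in seconds, each > -0.15.
#' @param l transformed value(s).
#' @return transformed values (dimensionless) / seconds.
#' @examples
#' log_vrt(0)      # 0
#' log_vrt(0.15)   # 10 * log(2)
#' inv_log_vrt(log_vrt(0.42))
#' @export
log_vrt <- function(vrt_s) {
  if (any(!is.na(vrt_s) & vrt_s <= -0.15))
    stop_vrt("log_vrt is undefined at or below the -0.15 s floor")
  10 * log((vrt_s + 0.15) / 0.15)
}

#' @rdname log_vrt
#' @export
inv_log_vrt <- function(l) 0.15 * (exp(l / 10) - 1)

#' Response speech rate (RSR)
#'
#' Number of response tokens divided by the span from the onset of the
#' first token to the end of the last token (matrix words and `<OOV>`
#' both count), in words per second.  Inter-word pauses lie inside the
#' span, so pausing lowers RSR.
#'
#' @param alignment a [response_alignment()] with at least one token.
#' @return rate in words/second, or `NA` for an empty alignment.
#' @export
compute_rsr <- function(alignment) {
  tok <- alignment$tokens
  if (!nrow(tok)) return(NA_real_)
  span <- tok$onset_s[nrow(tok)] + tok$duration_s[nrow(tok)] - tok$onset_s[1L]
  if (span <= 0) stop_vrt("zero response span; cannot compute RSR")
  nrow(tok) / span
}

#' Per-trial timing table
#'
#' Computes VRT (recognizer and manual conventions), log-VRT, RSR, and
#' the response word count for every trial in the trial table, using the
#' token-level alignment data.  Trials without any aligned token get
#' `NA` timing (no-response or unrecorded trials).
#'
#' @param alignments list of [response_alignment()] objects or a token
#'   data.frame as produced internally.
#' @param trials trial table (see [read_trials()]).
#' @return data.frame keyed by (listener_id, block_id, sentence_index)
#'   with columns `vrt_s`, `vrt_manual_s`, `log_vrt`, `rsr_wps`,
#'   `n_response_words`.
#' @export
timing_table <- function(alignments, trials) {
  tok <- if (is.data.frame(alignments)) alignments else
    alignments_to_tokens(alignments)
  key_tok <- paste(tok$listener_id, tok$block_id, tok$sentence_index, sep = "__")
  key_tr <- paste(trials$listener_id, trials$block_id, trials$sentence_index,
                  sep = "__")
  out <- data.frame(listener_id = trials$listener_id,
                    block_id = trials$block_id,
                    sentence_index = trials$sentence_index,
                    vrt_s = NA_real_, vrt_manual_s = NA_real_,
                    log_vrt = NA_real_, rsr_wps = NA_real_,
                    n_response_words = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(tok)) {
    f <- factor(key_tok, levels = key_tr)
    if (anyNA(f))
      stop_vrt("alignment token refers to unknown trial '%s'",
               key_tok[is.na(f)][1L])
    first_onset <- tapply(tok$onset_s, f, min)
    last_end <- tapply(tok$onset_s + tok$duration_s, f, max)
    n_tok <- tapply(tok$onset_s, f, length)
    has <- !is.na(n_tok)
    v <- vrt_from_onset(first_onset[has], trials$sentence_end_s[has], "asr")
    out$vrt_s[has] <- v
    out$vrt_manual_s[has] <- pmax(first_onset[has] - trials$sentence_end_s[has], 0)
    out$log_vrt[has] <- log_vrt(v)
    span <- last_end[has] - first_onset[has]
    rsr <- ifelse(span > 0, n_tok[has] / span, NA_real_)
    # single very short token can give span ~ one grid step; keep finite
    out$rsr_wps[has] <- rsr
    out$n_response_words[has] <- as.integer(n_tok[has])
  }
  out
}
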