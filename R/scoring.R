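#' Word scoring against the matrix vocabulary
#'
#' A response word counts as correct only for the slot of the presented
#' sentence it belongs to (slot-wise matrix-test scoring).  Since each
#' of the 50 words belongs to exactly one slot, this amounts to counting
#' the presented words that occur among the response's in-vocabulary
#' tokens; `<OOV>` tokens never match.
#'
#' @param presented character vector of 5 words, one per slot.
#' @param response a [response_alignment()].
#' @param vocabulary an [matrix_vocabulary()] object.
#' @return integer count of correct words, 0..5.
#' @export
score_sentence <- function(presented, response, vocabulary) {
  check_presented(presented, vocabulary)
  tok <- response$tokens$token
  tok <- tok[!is_oov(tok)]
  sum(presented %in% tok)
}

check_presented <- function(presented, vocabulary) {
  if (length(presented) != 5L)
    stop_vrt("a matrix sentence has exactly 5 words")
  slots <- slot_of(presented, vocabulary)
  if (anyNA(slots))
    stop_vrt("presented word '%s' is not in the vocabulary",
             presented[is.na(slots)][1L])
  if (!identical(as.integer(slots), 1:5))
    stop_vrt("presented words must occupy slots 1..5 in order")
  invisible(TRUE)
}

#' Score every trial of a cohort from its alignments
#'
#' Vectorized driver over [score_sentence()]: computes the
#' recognizer-channel word count for each row of the trial table.
#' Trials without tokens score 0 (no response); use the trial status to
#' distinguish unrecorded trials, whose score is `NA` pending
#' [impute_unrecorded()].
#'
#' @param trials trial table with `word1`..`word5` columns.
#' @param alignments list of alignments or token data.frame.
#' @param vocabulary an [matrix_vocabulary()] object.
#' @param status optional character vector per trial; rows with status
#'   `"unrecorded"` get `NA` instead of 0.
#' @return integer vector of per-trial correct-word counts.
#' @export
score_trials <- function(trials, alignments, vocabulary, status = NULL) {
  tok <- if (is.data.frame(alignments)) alignments else
    alignments_to_tokens(alignments)
  key_tr <- paste(trials$listener_id, trials$block_id, trials$sentence_index,
                  sep = "__")
  n <- rep(0L, nrow(trials))
  if (nrow(tok)) {
    tok <- tok[!is_oov(tok$token), , drop = FALSE]
    key_tok <- paste(tok$listener_id, tok$block_id, tok$sentence_index,
                     sep = "__")
    f <- factor(key_tok, levels = key_tr)
    words <- as.matrix(trials[, paste0("word", 1:5)])
    by_trial <- split(tok$token, f)
    idx <- which(lengths(by_trial) > 0L)
    for (i in idx) n[i] <- sum(words[i, ] %in% by_trial[[i]])
  }
  n <- as.numeric(n)
  if (!is.null(status)) n[status == "unrecorded"] <- NA_real_
  n
}

#' Block-level speech-recognition score
#'
#' Percentage of the block's presented words (5 sentences x 5 words)
#' repeated correctly.
#'
#' @param n_correct numeric vector of per-sentence correct-word counts.
#' @param words_per_sentence words per sentence (default 5).
#' @return percentage in 0..100.
#' @examples
#' block_score(c(5, 4, 3, 2, 1))  # 60
#' @export
block_score <- function(n_correct, words_per_sentence = 5L) {
  if (anyNA(n_correct))
    stop_vrt("block contains unscored sentences; run impute_unrecorded first")
  100 * sum(n_correct) / (words_per_sentence * length(n_correct))
}

#' Impute recognizer scores for unrecorded sentences
#'
#' When a recording stopped before the last sentence of a block, the
#' recognizer channel has no score for that sentence while the examiner
#' scored the rest of the block live.  The missing recognizer score is
#' filled with the mean manual correct-word count of the block's
#' recorded sentences, which is arithmetically the same as increasing
#' the block total by that average.
#'
#' @param asr_n_correct recognizer counts per sentence (`NA` where
#'   unrecorded).
#' @param manual_n_correct manual counts (`NA` where unrecorded).
#' @param block_id block key per sentence.
#' @return list with `scores` (recognizer counts, imputed where needed)
#'   and `n_imputed`.
#' @export
impute_unrecorded <- function(asr_n_correct, manual_n_correct, block_id) {
  out <- asr_n_correct
  n_imp <- 0L
  for (b in unique(block_id[is.na(asr_n_correct)])) {
    idx <- which(block_id == b)
    miss <- idx[is.na(asr_n_correct[idx])]
    have <- idx[!is.na(manual_n_correct[idx])]
    if (!length(have))
      stop_vrt("block '%s' is entirely unrecorded; cannot impute", b)
    out[miss] <- mean(manual_n_correct[have])
    n_imp <- n_imp + length(miss)
  }
  list(scores = out, n_imputed = n_imp)
}

#' Rationalized arcsine transform (RAU)
#'
#' Variance-stabilizing transform of a proportion-correct score:
#' `theta = asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))`,
#' `RAU = (146 / pi) * theta - 23` (Studebaker's linearized arcsine
#' units).  Defined on counts x correct out of n presented; x need not
#' be an integer (imputed scores are fractional).
#'
#' @param x correct count(s), `0 <= x <= n`.
#' @param n presented count(s), `>= 1`.
#' @return RAU score(s); roughly -23 at 0% and 123 at 100%, close to the
#'   percentage scale in midrange.
#' @export
rau_transform <- function(x, n) {
  if (any(n < 1)) stop_vrt("rau_transform needs n >= 1")
  if (any(x < 0 | x > n)) stop_vrt("rau_transform needs 0 <= x <= n")
  theta <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  (146 / pi) * theta - 23
}

#' Aggregate sentence-level measures to analysis cells
#'
#' Collapses the cohort to one row per participant x masker type x SNR
#' (270 rows for the full 27-participant design): speech-recognition
#' scores and rank-normalized effort ratings are averaged over the
#' cell's blocks, while raw effort, VRT, and RSR use the median;
#' within-participant z-transformed log-VRT and RSR are averaged.  Rank
#' normalization (global and per participant) operates on the
#' block-level ratings; z-transformation operates on the sentence-level
#' timing values.
#'
#' @param trials trial table.
#' @param scores data.frame with per-sentence `asr_n_correct` (imputed,
#'   no `NA`) aligned with `trials` rows.
#' @param ratings data.frame with one row per block: `listener_id`,
#'   `block_id`, `srle` (category 1..7).
#' @param timing per-sentence timing table from [timing_table()]
#'   (row-aligned with `trials`).
#' @param rau_on `"counts"` pools the cell's correct/presented counts
#'   before the RAU transform; `"percent"` averages per-block RAU scores.
#' @return data.frame of class `aggregate_cells`, one row per cell.
#' @export
aggregate_cells <- function(trials, scores, ratings, timing,
                            rau_on = c("counts", "percent")) {
  rau_on <- match.arg(rau_on)
  if (nrow(scores) != nrow(trials) || nrow(timing) != nrow(trials))
    stop_vrt("scores and timing must be row-aligned with trials")
  if (anyNA(scores$asr_n_correct))
    stop_vrt("scores contain NA; run impute_unrecorded first")

  ratings$srle_rank_global <- rankit(ratings$srle)
  ratings$srle_rank_individual <- rankit(ratings$srle, scope = ratings$listener_id)
  z_logvrt <- zscore_within(timing$log_vrt, trials$listener_id)
  z_rsr <- zscore_within(timing$rsr_wps, trials$listener_id)

  block_key <- paste(trials$listener_id, trials$block_id, sep = "__")
  rkey <- paste(ratings$listener_id, ratings$block_id, sep = "__")
  ridx <- match(block_key, rkey)
  if (anyNA(ridx))
    stop_vrt("block '%s' has no effort rating", block_key[is.na(ridx)][1L])

  cell <- interaction(trials$listener_id, trials$masker_type,
                      trials$snr_re_srt, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), cell), function(idx) {
    tr <- trials[idx, ]
    nblock <- length(unique(tr$block_id))
    per_block <- tapply(scores$asr_n_correct[idx], tr$block_id, sum)
    n_words <- tapply(scores$asr_n_correct[idx], tr$block_id, length) * 5
    rau <- if (rau_on == "counts")
      rau_transform(sum(per_block), sum(n_words))
    else mean(rau_transform(per_block, n_words))
    rat <- ratings[unique(ridx[idx]), ]
    vrt <- timing$vrt_s[idx]
    rsr <- timing$rsr_wps[idx]
    if (all(is.na(vrt)))
      stop_vrt("cell %s has no usable VRT", as.character(cell[idx[1L]]))
    data.frame(
      listener_id = tr$listener_id[1L],
      group = tr$group[1L],
      masker_type = tr$masker_type[1L],
      snr_re_srt = tr$snr_re_srt[1L],
      n_blocks = nblock,
      mean_score_pct = 100 * sum(per_block) / sum(n_words),
      rau_score = rau,
      srle_median_raw = median(rat$srle),
      srle_mean_rank_individual = mean(rat$srle_rank_individual),
      srle_mean_rank_global = mean(rat$srle_rank_global),
      vrt_median_s = median(vrt, na.rm = TRUE),
      z_logvrt_mean = mean(z_logvrt[idx], na.rm = TRUE),
      rsr_median_wps = median(rsr, na.rm = TRUE),
      z_rsr_mean = mean(z_rsr[idx], na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$listener_id, out$masker_type, out$snr_re_srt), ]
  rownames(out) <- NULL
  out
}
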