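#' Word-level response alignment records
#'
#' A `response_alignment` holds one trial's timed response: an ordered
#' set of word tokens (from the matrix vocabulary, or the literal
#' `<OOV>` marker for out-of-vocabulary words) with onset and duration
#' in seconds on the recording timeline, plus the end time of the
#' presented sentence that the verbal response time is measured against.
#'
#' @param listener_id,block_id,sentence_index trial key components.
#' @param tokens data.frame with columns `token`, `onset_s`,
#'   `duration_s`; may have zero rows (no-response trial).
#' @param sentence_end_s end of the presented sentence (seconds); `NA`
#'   when only the alignment file is available.
#' @return object of class `response_alignment`.
#' @export
response_alignment <- function(listener_id, block_id, sentence_index,
                               tokens, sentence_end_s = NA_real_) {
  if (is.null(tokens) || nrow(tokens) == 0L) {
    tokens <- data.frame(token = character(), onset_s = numeric(),
                         duration_s = numeric(), stringsAsFactors = FALSE)
  } else {
    tokens <- as.data.frame(tokens)[, c("token", "onset_s", "duration_s")]
    if (any(tokens$duration_s <= 0))
      stop_vrt("token durations must be positive")
    if (any(tokens$onset_s < 0))
      stop_vrt("token onsets must be non-negative")
    o <- order(tokens$onset_s)
    tokens <- tokens[o, , drop = FALSE]
    if (nrow(tokens) > 1L) {
      ends <- tokens$onset_s[-nrow(tokens)] + tokens$duration_s[-nrow(tokens)]
      if (any(tokens$onset_s[-1L] < ends - 1e-9))
        stop_vrt("token intervals overlap")
    }
    rownames(tokens) <- NULL
  }
  structure(list(listener_id = as.character(listener_id),
                 block_id = as.character(block_id),
                 sentence_index = as.integer(sentence_index),
                 sentence_end_s = as.numeric(sentence_end_s),
                 tokens = tokens),
            class = "response_alignment")
}

#' @export
print.response_alignment <- function(x, ...) {
  cat(sprintf("response_alignment %s: %d token(s)\n",
              utterance_id(x), nrow(x$tokens)))
  if (nrow(x$tokens)) print(x$tokens)
  invisible(x)
}

utterance_id <- function(x) {
  paste(x$listener_id, x$block_id, x$sentence_index, sep = "__")
}

parse_utterance_id <- function(id) {
  parts <- strsplit(id, "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop_vrt("utterance id '%s' is not of the form listener__block__sentence",
             id[bad][1L])
  data.frame(listener_id = vapply(parts, `[[`, "", 1L),
             block_id = vapply(parts, `[[`, "", 2L),
             sentence_index = as.integer(vapply(parts, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Read alignments from a CTM file
#'
#' CTM ("time-marked conversation") is the conventional one-token-per-line
#' recognizer output: `utterance_id channel onset duration token
#' [confidence]`, whitespace separated.  The utterance id encodes the
#' trial key as `listener__block__sentence`.  Tokens not found in the
#' vocabulary are mapped to `<OOV>` with a warning; the optional
#' confidence field is ignored.
#'
#' @param path CTM file.
#' @param vocabulary an [matrix_vocabulary()] object, or `NULL` to skip
#'   vocabulary mapping.
#' @return list of [response_alignment()] objects (sentence_end_s is
#'   `NA`; join against the trial table for timing analysis).
#' @export
read_ctm <- function(path, vocabulary = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 5L | nf > 6L))
    stop_vrt("malformed CTM line %d: expected 5 or 6 fields, got %d",
             which(nf < 5L | nf > 6L)[1L], nf[nf < 5L | nf > 6L][1L])
  utt <- vapply(fields, `[[`, "", 1L)
  onset <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  dur <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  token <- vapply(fields, `[[`, "", 5L)
  if (anyNA(onset) || anyNA(dur))
    stop_vrt("malformed CTM line %d: non-numeric onset/duration",
             which(is.na(onset) | is.na(dur))[1L])
  if (any(onset < 0))
    stop_vrt("CTM line %d: negative onset", which(onset < 0)[1L])
  if (!is.null(vocabulary)) {
    unknown <- !(token %in% vocabulary$word) & !is_oov(token)
    if (any(unknown)) {
      warning(sprintf("%d token(s) outside the vocabulary mapped to %s (e.g. '%s')",
                      sum(unknown), OOV_TOKEN, token[unknown][1L]),
              call. = FALSE)
      token[unknown] <- OOV_TOKEN
    }
  }
  key <- parse_utterance_id(unique(utt))
  idx <- split(seq_along(utt), factor(utt, levels = unique(utt)))
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    j <- idx[[i]]
    out[[i]] <- response_alignment(
      key$listener_id[i], key$block_id[i], key$sentence_index[i],
      data.frame(token = token[j], onset_s = onset[j], duration_s = dur[j],
                 stringsAsFactors = FALSE))
  }
  out
}

#' Write alignments to a CTM file
#'
#' Times are written with two decimals, which is lossless for the 30-ms
#' alignment grid.  No-response alignments (zero tokens) produce no
#' lines, matching recognizer behaviour.
#'
#' @param alignments list of [response_alignment()] objects.
#' @param path output file.
#' @export
write_ctm <- function(alignments, path) {
  if (inherits(alignments, "response_alignment")) alignments <- list(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    if (!nrow(a$tokens)) next
    writeLines(sprintf("%s 1 %.2f %.2f %s", utterance_id(a),
                       a$tokens$onset_s, a$tokens$duration_s, a$tokens$token),
               con)
  }
  invisible(path)
}

trial_columns <- c("listener_id", "group", "masker_id", "masker_type",
                   "snr_re_srt", "block_id", "sentence_index",
                   paste0("word", 1:5), "sentence_end_s")

#' Read / write the pipeline's CSV tables
#'
#' Plain RFC-4180 CSV with a header row.  `read_trials()` additionally
#' checks the trial-table schema and rejects duplicated trial keys.
#'
#' @param path CSV file.
#' @param rows data.frame to write.
#' @param required character vector of required column names.
#' @return `read_trials()`/`read_table_checked()` return a data.frame.
#' @export
read_trials <- function(path) {
  df <- read_table_checked(path, trial_columns)
  key <- paste(df$listener_id, df$block_id, df$sentence_index, sep = "__")
  if (anyDuplicated(key))
    stop_vrt("duplicate trial key '%s'", key[duplicated(key)][1L])
  df$sentence_index <- as.integer(df$sentence_index)
  df$masker_type <- as.integer(df$masker_type)
  df$group <- as.integer(df$group)
  df$snr_re_srt <- as.numeric(df$snr_re_srt)
  df$sentence_end_s <- as.numeric(df$sentence_end_s)
  df
}

#' @rdname read_trials
#' @export
read_table_checked <- function(path, required = character()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_vrt("table %s is missing required column(s): %s", path,
             paste(missing, collapse = ", "))
  df
}

#' @rdname read_trials
#' @export
write_table <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Flatten a list of alignments to one token-per-row data.frame (the fast
# internal representation used by scoring and timing).
alignments_to_tokens <- function(alignments) {
  keep <- vapply(alignments, function(a) nrow(a$tokens) > 0L, TRUE)
  alignments <- alignments[keep]
  if (!length(alignments)) {
    return(data.frame(listener_id = character(), block_id = character(),
                      sentence_index = integer(), token = character(),
                      onset_s = numeric(), duration_s = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- vapply(alignments, function(a) nrow(a$tokens), 1L)
  data.frame(
    listener_id = rep(vapply(alignments, `[[`, "", "listener_id"), n),
    block_id = rep(vapply(alignments, `[[`, "", "block_id"), n),
    sentence_index = rep(vapply(alignments, function(a) a$sentence_index, 1L), n),
    token = unlist(lapply(alignments, function(a) a$tokens$token)),
    onset_s = unlist(lapply(alignments, function(a) a$tokens$onset_s)),
    duration_s = unlist(lapply(alignments, function(a) a$tokens$duration_s)),
    stringsAsFactors = FALSE, row.names = NULL)
}
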