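#' Default masker set
#'
#' Nine maskers mirroring a typical matrix-test masker comparison: two
#' stationary speech-shaped noises (superposition noises) and seven
#' fluctuating, speech-like maskers.  Masker type is coded 1 =
#' fluctuating, 2 = stationary throughout the package.
#'
#' @return data.frame with columns `masker_id`, `masker_type`.
#' @export
default_maskers <- function() {
  data.frame(
    masker_id = c("ICRA5-250", "ISTS", "IFFM", "NFIMG", "NFIMM",
                  "NFFMG", "NFFMM", "OLnoise", "IFnoise"),
    masker_type = c(rep(1L, 7L), 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Missingness plan
#'
#' Counts of the four incomplete-data categories the generator injects:
#' sentences whose recording stopped early (`n_unrecorded`; recognizer
#' channel missing, block imputable), sentences with no response at all
#' (`n_no_response`), sentences the examiner scored as "no response"
#' while the recognizer detected words (`n_asr_only`), and sentences
#' with a manual response time but no recognizer output
#' (`n_manual_only`).  Defaults match the study design the generator
#' emulates.
#'
#' @param n_unrecorded,n_no_response,n_asr_only,n_manual_only counts.
#' @param seed optional seed for assigning affected trials; defaults to
#'   a child seed of the cohort master seed.
#' @return list of class `missingness_plan`.
#' @export
missingness_plan <- function(n_unrecorded = 3L, n_no_response = 22L,
                             n_asr_only = 52L, n_manual_only = 6L,
                             seed = NULL) {
  counts <- c(n_unrecorded, n_no_response, n_asr_only, n_manual_only)
  if (any(counts < 0)) stop_vrt("missingness counts must be >= 0")
  structure(list(n_unrecorded = as.integer(n_unrecorded),
                 n_no_response = as.integer(n_no_response),
                 n_asr_only = as.integer(n_asr_only),
                 n_manual_only = as.integer(n_manual_only),
                 seed = seed),
            class = "missingness_plan")
}

#' Cohort configuration
#'
#' All generative parameters of the virtual cohort in one document.
#' Defaults emulate a two-group design (15 normal-hearing, 12
#' hearing-impaired listeners), nine maskers, five SNRs at 0/3/6/9/12 dB
#' above the individual speech-recognition threshold (SRT), five-sentence
#' blocks, and the stationary/fluctuating contrasts reported for such
#' designs: stationary-masker SRT means around -7.5/-8.5 dB SNR (NH) and
#' -5.1/-5.5 dB SNR (HI), release from masking of about 12 dB (NH) and
#' 6 dB (HI) for fluctuating maskers, and steeper psychometric slopes
#' for stationary (15 %/dB) than for fluctuating maskers (7 %/dB).
#' Can be serialized to and read from YAML or JSON via
#' [read_cohort_config()].
#'
#' @param n_nh,n_hi group sizes.
#' @param maskers data.frame as [default_maskers()].
#' @param snr_offsets SNRs re SRT in dB.
#' @param sentences_per_block sentences per block.
#' @param srt SRT distribution parameters (group means per stationary
#'   masker, release from masking, between-listener SD, per-masker SD).
#' @param slopes psychometric slope (proportion correct per dB at the
#'   50% point) per masker type.
#' @param srle latent effort model: category cut of
#'   `intercept + snr_coef * SNR + stationary_offset * [stationary]`
#'   plus Gaussian noise, with per-listener cutpoint jitter.
#' @param vrt log-VRT model (intercepts per group, per-dB SNR slope,
#'   stationary offset, residual SD, per-listener pace SD).
#' @param rsr response-speech-rate model (words/second).
#' @param hl500 hearing-level (500 Hz) distribution per group, used only
#'   for the presentation-level rule.
#' @param asr recognizer behaviour: `oov_rate` (probability that a
#'   missed word slot produces an `<OOV>` token) and `discrepancy_rate`
#'   (probability per sentence that recognizer and examiner word counts
#'   differ by one).
#' @param missingness a [missingness_plan()].
#' @param mode `"psychometric"` (word-level Bernoulli correctness from
#'   the psychometric function) or `"latent_linear"` (block outcomes
#'   drawn from linear models; see [simulate_block()]).
#' @param latent optional linear-model coefficients for the
#'   latent_linear block mode (`list(score = list(intercept, snr_coef,
#'   type_coef, group_coef, sd))`); `NULL` uses built-in defaults.
#' @param seed master seed; every stage derives child seeds from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_nh = 15L, n_hi = 12L,
    maskers = default_maskers(),
    snr_offsets = c(0, 3, 6, 9, 12),
    sentences_per_block = 5L,
    srt = list(stationary_means = list(
                 nh = c(OLnoise = -7.5, IFnoise = -8.5),
                 hi = c(OLnoise = -5.1, IFnoise = -5.5)),
               release = c(nh = 12, hi = 6),
               between_sd = c(nh = 1.5, hi = 2.5),
               masker_sd = 0.5),
    slopes = c(stationary = 0.15, fluctuating = 0.07),
    srle = list(intercept = 6.2, snr_coef = -0.28,
                stationary_offset = -0.9, sd = 0.8,
                threshold_jitter_sd = 0.5),
    vrt = list(intercept = c(nh = 15, hi = 17), snr_coef = -0.55,
               stationary_offset = -2.0, sd = 2.0, pace_sd = 2.5),
    rsr = list(base = c(nh = 2.3, hi = 1.8), snr_coef = 0.035,
               stationary_offset = 0.12, sd = 0.25, pace_sd = 0.2,
               min = 0.3),
    hl500 = list(nh = c(mean = 5, sd = 4, min = 0, max = 15),
                 hi = c(mean = 35, sd = 12, min = 10, max = 70)),
    asr = list(oov_rate = 0.3, discrepancy_rate = 0.01),
    missingness = missingness_plan(),
    mode = c("psychometric", "latent_linear"),
    latent = NULL,
    seed = 1L) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "cohort_config")
}

#' @rdname cohort_config
#' @param path YAML (`.yml`/`.yaml`) or JSON file holding overrides for
#'   any [cohort_config()] argument.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_vrt("unknown cohort configuration field(s): %s",
             paste(unknown, collapse = ", "))
  if (!is.null(raw$maskers)) raw$maskers <- as.data.frame(raw$maskers)
  if (!is.null(raw$missingness))
    raw$missingness <- do.call(missingness_plan, raw$missingness)
  defaults <- cohort_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.data.frame(upd[[nm]]) && !inherits(upd[[nm]], "missingness_plan")) {
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      } else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- merge_into(defaults, raw)
  class(cfg) <- "cohort_config"
  cfg
}

#' Presentation level for a hearing-impaired listener
#'
#' Maskers are presented at 65 dB SPL plus a gain of half the listener's
#' hearing level at 500 Hz, capped at 80 dB SPL.
#'
#' @param hl500 hearing level at 500 Hz in dB HL, `>= 0`.
#' @return presentation level in dB SPL.
#' @examples
#' presentation_level(0)   # 65
#' presentation_level(20)  # 75
#' presentation_level(40)  # 80 (cap)
#' @export
presentation_level <- function(hl500) {
  if (any(hl500 < 0)) stop_vrt("hl500 must be non-negative")
  pmin(65 + hl500 / 2, 80)
}

#' Build the full experimental design
#'
#' Every listener completes one five-sentence block for each masker x
#' SNR combination (45 blocks with the default nine maskers and five
#' SNRs), with block order randomized per listener.  Sentences are drawn
#' uniformly from the 10 x 5 word matrix.  Sentence end times lie on the
#' 30-ms alignment grid along each listener's recording timeline.
#'
#' @param n_nh,n_hi group sizes (NH coded 1, HI coded 2).
#' @param maskers data.frame with `masker_id`, `masker_type`.
#' @param snr_offsets dB values of SNR re SRT.
#' @param sentences_per_block sentences per block.
#' @param seed RNG seed.
#' @param vocabulary an [matrix_vocabulary()].
#' @return trial table (one row per presented sentence).
#' @export
build_design <- function(n_nh = 15L, n_hi = 12L, maskers = default_maskers(),
                         snr_offsets = c(0, 3, 6, 9, 12),
                         sentences_per_block = 5L, seed = 1L,
                         vocabulary = matrix_vocabulary()) {
  if (n_nh + n_hi < 1L) stop_vrt("need at least one participant")
  if (is.null(maskers) || nrow(maskers) < 1L) stop_vrt("need at least one masker")
  if (!length(snr_offsets)) stop_vrt("need at least one SNR offset")
  listeners <- data.frame(
    listener_id = c(sprintf("NH%02d", seq_len(n_nh)),
                    sprintf("HI%02d", seq_len(n_hi))),
    group = rep(c(1L, 2L), c(n_nh, n_hi)),
    stringsAsFactors = FALSE)
  words <- matrix(vocabulary$word, nrow = 10L)  # column = slot
  conditions <- expand.grid(masker_row = seq_len(nrow(maskers)),
                            snr_re_srt = snr_offsets)
  n_blocks <- nrow(conditions)
  per_listener <- vector("list", nrow(listeners))
  for (i in seq_len(nrow(listeners))) {
    tab <- with_seed(derive_seed(seed, 1L, i), {
      ord <- sample.int(n_blocks)
      cond <- conditions[ord, , drop = FALSE]
      n_tr <- n_blocks * sentences_per_block
      sent <- matrix(words[cbind(sample.int(10L, 5L * n_tr, replace = TRUE),
                                 rep(1:5, n_tr))],
                     ncol = 5L, byrow = TRUE)
      data.frame(
        listener_id = listeners$listener_id[i],
        group = listeners$group[i],
        masker_id = rep(maskers$masker_id[cond$masker_row],
                        each = sentences_per_block),
        masker_type = rep(as.integer(maskers$masker_type[cond$masker_row]),
                          each = sentences_per_block),
        snr_re_srt = rep(cond$snr_re_srt, each = sentences_per_block),
        block_id = rep(sprintf("b%02d", seq_len(n_blocks)),
                       each = sentences_per_block),
        sentence_index = rep(seq_len(sentences_per_block), n_blocks),
        word1 = sent[, 1L], word2 = sent[, 2L], word3 = sent[, 3L],
        word4 = sent[, 4L], word5 = sent[, 5L],
        sentence_end_s = quantize_grid(2 + (seq_len(n_tr) - 1L) * 6.51),
        stringsAsFactors = FALSE)
    })
    per_listener[[i]] <- tab
  }
  out <- do.call(rbind, per_listener)
  rownames(out) <- NULL
  out
}

quantize_grid <- function(t, step = 0.03) round(t / step) * step

#' Draw a virtual listener
#'
#' Samples the generative parameters of one simulated participant:
#' per-masker SRTs (stationary maskers around the group means,
#' fluctuating maskers lower by the group's release from masking),
#' psychometric slopes per masker type, latent effort cutpoints,
#' log-VRT and RSR parameters, and a per-listener pace offset.  Every
#' listener satisfies the release-from-masking invariant (each
#' fluctuating-masker SRT below each stationary-masker SRT) and has
#' strictly increasing effort cutpoints.
#'
#' @param group `"NH"` or `"HI"`.
#' @param seed RNG seed.
#' @param config a [cohort_config()].
#' @param listener_id id string stored in the object.
#' @return list of class `virtual_listener`.
#' @export
draw_listener <- function(group = c("NH", "HI"), seed = 1L,
                          config = cohort_config(), listener_id = NULL) {
  group <- match.arg(group)
  g <- tolower(group)
  maskers <- config$maskers
  with_seed(seed, {
    hl <- config$hl500[[g]]
    hl500 <- min(max(rnorm(1L, hl[["mean"]], hl[["sd"]]), hl[["min"]]),
                 hl[["max"]])
    stat_means <- config$srt$stationary_means[[g]]
    delta <- rnorm(1L, 0, config$srt$between_sd[[g]])
    jit <- rnorm(nrow(maskers), 0, config$srt$masker_sd)
    is_stat <- maskers$masker_type == 2L
    srt <- numeric(nrow(maskers))
    base_stat <- mean(stat_means)
    stat_mean_for <- function(id) {
      if (id %in% names(stat_means)) stat_means[[id]] else base_stat
    }
    srt[is_stat] <- vapply(maskers$masker_id[is_stat], stat_mean_for, 0) +
      delta + jit[is_stat]
    srt[!is_stat] <- base_stat - config$srt$release[[g]] + delta + jit[!is_stat]
    if (any(is_stat) && any(!is_stat))  # release-from-masking invariant
      srt[!is_stat] <- pmin(srt[!is_stat], min(srt[is_stat]) - 0.5)
    names(srt) <- maskers$masker_id
    cut_shift <- rnorm(1L, 0, config$srle$threshold_jitter_sd)
    structure(list(
      listener_id = listener_id %||% paste0(group, "01"),
      group = group,
      group_code = if (group == "NH") 1L else 2L,
      hl500 = hl500,
      srt_per_masker = srt,
      slope_per_type = config$slopes,
      srle_thresholds = seq(1.5, 6.5, by = 1) + cut_shift,
      vrt_params = list(intercept = config$vrt$intercept[[g]],
                        snr_coef = config$vrt$snr_coef,
                        stationary_offset = config$vrt$stationary_offset,
                        residual_sd = config$vrt$sd),
      rsr_params = list(base = config$rsr$base[[g]],
                        snr_coef = config$rsr$snr_coef,
                        stationary_offset = config$rsr$stationary_offset,
                        residual_sd = config$rsr$sd,
                        min = config$rsr$min),
      pace_offset = rnorm(1L, 0, config$vrt$pace_sd),
      pace_offset_rsr = rnorm(1L, 0, config$rsr$pace_sd)),
      class = "virtual_listener")
  })
}

#' Psychometric word-correct probability
#'
#' Logistic psychometric function in SNR re SRT, anchored at 50% correct
#' at 0 dB with the given slope (proportion correct per dB at the 50%
#' point).
#'
#' @param snr_re_srt dB relative to the individual SRT.
#' @param slope proportion correct per dB.
#' @return probability of repeating one word correctly.
#' @export
psychometric_p <- function(snr_re_srt, slope) {
  1 / (1 + exp(-4 * slope * snr_re_srt))
}

#' Simulate one five-sentence block
#'
#' In `psychometric` mode each presented word is repeated correctly with
#' probability given by the listener's psychometric function for the
#' block's masker type; the effort rating comes from cutting a latent
#' effort value (decreasing in SNR, lower for stationary maskers) at the
#' listener's cutpoints; raw VRT is generated on the log-VRT scale and
#' inverse-transformed; raw RSR is linear in SNR and masker type with a
#' positive floor.  In `latent_linear` mode the block score (percent) is
#' drawn directly from a configurable linear model, which makes
#' generating coefficients exactly recoverable in the noiseless limit.
#'
#' @param listener a [draw_listener()] object.
#' @param trials the block's rows of the trial table (same block id).
#' @param mode `"psychometric"` or `"latent_linear"`.
#' @param seed RNG seed.
#' @param config a [cohort_config()].
#' @return list with `sentences` (data.frame: `n_correct`, `vrt_s`,
#'   `rsr_wps`), `srle` (category 1..7), and `score_pct` (block percent;
#'   in latent_linear mode the exact linear-model draw).
#' @export
simulate_block <- function(listener, trials,
                           mode = c("psychometric", "latent_linear"),
                           seed = 1L, config = cohort_config()) {
  mode <- match.arg(mode)
  if (length(unique(trials$block_id)) != 1L)
    stop_vrt("simulate_block expects the trials of exactly one block")
  n_sent <- nrow(trials)
  snr <- trials$snr_re_srt[1L]
  stationary <- trials$masker_type[1L] == 2L
  with_seed(seed, {
    if (mode == "psychometric") {
      slope <- listener$slope_per_type[[if (stationary) "stationary" else
        "fluctuating"]]
      p <- psychometric_p(snr, slope)
      n_correct <- rbinom(n_sent, 5L, p)
      score_pct <- 100 * sum(n_correct) / (5 * n_sent)
    } else {
      lm_cfg <- config$latent %||% list(
        score = list(intercept = 40, snr_coef = 4, type_coef = 10,
                     group_coef = 0, sd = 8))
      sc <- lm_cfg$score
      score_pct <- sc$intercept + sc$snr_coef * snr +
        sc$type_coef * trials$masker_type[1L] +
        sc$group_coef * (if (listener$group == "NH") 1 else 2) +
        rnorm(1L, 0, sc$sd)
      score_pct <- min(max(score_pct, 0), 100)
      total <- score_pct / 100 * 5 * n_sent
      base <- floor(total / n_sent)
      n_correct <- rep(base, n_sent)
      extra <- round(total - base * n_sent)
      if (extra > 0) n_correct[seq_len(min(extra, n_sent))] <-
        n_correct[seq_len(min(extra, n_sent))] + 1L
      n_correct <- pmin(pmax(n_correct, 0L), 5L)
    }
    eff <- config$srle
    latent <- eff$intercept + eff$snr_coef * snr +
      eff$stationary_offset * stationary + rnorm(1L, 0, eff$sd)
    srle <- 1L + sum(latent > listener$srle_thresholds)
    vp <- listener$vrt_params
    l_vrt <- vp$intercept + vp$snr_coef * snr +
      vp$stationary_offset * stationary + listener$pace_offset +
      rnorm(n_sent, 0, vp$residual_sd)
    vrt_s <- inv_log_vrt(l_vrt)
    rp <- listener$rsr_params
    rsr <- rp$base + rp$snr_coef * snr + rp$stationary_offset * stationary +
      listener$pace_offset_rsr + rnorm(n_sent, 0, rp$residual_sd)
    rsr <- pmax(rsr, rp$min)
    list(sentences = data.frame(n_correct = as.integer(n_correct),
                                vrt_s = vrt_s, rsr_wps = rsr),
         srle = srle, score_pct = score_pct)
  })
}

#' Simulate a recognizer alignment for one response
#'
#' Emits the correct words (in slot order) plus optional `<OOV>`
#' insertions as timed tokens: the first onset is the sentence end plus
#' the verbal response time, the span from first onset to last token end
#' is `n_tokens / rsr`, and all times are quantized to the 30-ms
#' recognizer grid.
#'
#' @param sentence the 5 presented words.
#' @param n_correct how many presented words the response contains.
#' @param vrt_s verbal response time in seconds (may be negative).
#' @param rsr_wps response speech rate in words/second (> 0 whenever at
#'   least one token is emitted).
#' @param sentence_end_s sentence end on the recording timeline.
#' @param seed RNG seed (slot choice, `<OOV>` placement).
#' @param n_oov number of `<OOV>` insertions; if `NULL`, drawn
#'   Binomial(5 - n_correct, `oov_rate`).
#' @param oov_rate see `n_oov`.
#' @param listener_id,block_id,sentence_index trial key.
#' @return a [response_alignment()]; empty when `n_correct = 0` and no
#'   `<OOV>` tokens are drawn (no-response trial).
#' @export
simulate_alignment <- function(sentence, n_correct, vrt_s, rsr_wps,
                               sentence_end_s = 0, seed = 1L,
                               n_oov = NULL, oov_rate = 0,
                               listener_id = "L01", block_id = "b01",
                               sentence_index = 1L) {
  if (n_correct < 0L || n_correct > 5L)
    stop_vrt("n_correct must be in 0..5")
  with_seed(seed, {
    if (is.null(n_oov))
      n_oov <- rbinom(1L, 5L - n_correct, oov_rate)
    n_tok <- n_correct + n_oov
    if (n_tok == 0L) {
      return(response_alignment(listener_id, block_id, sentence_index,
                                NULL, sentence_end_s))
    }
    if (is.na(rsr_wps) || rsr_wps <= 0)
      stop_vrt("rsr must be positive when the response has tokens")
    slots <- sort(sample.int(5L, n_correct))
    tokens <- rep(OOV_TOKEN, n_tok)
    pos_correct <- sort(sample.int(n_tok, n_correct))
    tokens[pos_correct] <- sentence[slots]
    gap <- 1 / rsr_wps
    onsets <- quantize_grid(sentence_end_s + vrt_s + (seq_len(n_tok) - 1L) * gap)
    dur <- quantize_grid(c(rep(0.8 * gap, n_tok - 1L), gap))
    dur <- pmax(dur, 0.03)
    if (n_tok > 1L) {  # keep intervals non-overlapping on the grid
      avail <- diff(onsets)
      dur[-n_tok] <- pmin(dur[-n_tok], avail)
    }
    response_alignment(listener_id, block_id, sentence_index,
                       data.frame(token = tokens, onset_s = onsets,
                                  duration_s = dur,
                                  stringsAsFactors = FALSE),
                       sentence_end_s)
  })
}

#' Inject the missingness structure into simulated outcomes
#'
#' Assigns the plan's four incomplete-data categories to trials drawn
#' uniformly at random (unrecorded trials always hit the last sentence
#' of distinct blocks, emulating a recording that stopped after the
#' previous response), and blanks the affected channels: `unrecorded`
#' loses both channels for that sentence, `no_response` is empty on both
#' channels with a word count of zero, `asr_only` keeps recognizer
#' output while the examiner noted "no response", `manual_only` keeps
#' the manual channel while the recognizer produced nothing.
#'
#' @param outcomes per-sentence outcome table (row-aligned with the
#'   trial table; columns `asr_n_correct`, `manual_n_correct`,
#'   `vrt_s`, `vrt_manual_s`, `rsr_wps` and trial keys).
#' @param plan a [missingness_plan()].
#' @param seed RNG seed (used when the plan carries none).
#' @return `outcomes` with a `status` column and blanked channels.
#' @export
inject_missingness <- function(outcomes, plan = missingness_plan(),
                               seed = 1L) {
  n <- nrow(outcomes)
  total <- plan$n_unrecorded + plan$n_no_response + plan$n_asr_only +
    plan$n_manual_only
  if (total > n)
    stop_vrt("missingness plan assigns %d trials but only %d exist", total, n)
  outcomes$status <- "complete"
  if (total == 0L) return(outcomes)
  with_seed(plan$seed %||% seed, {
    last_sent <- max(outcomes$sentence_index)
    block_key <- paste(outcomes$listener_id, outcomes$block_id, sep = "__")
    eligible <- which(outcomes$sentence_index == last_sent)
    if (plan$n_unrecorded > length(eligible))
      stop_vrt("not enough blocks for %d unrecorded sentences",
               plan$n_unrecorded)
    unrec <- sample(eligible, plan$n_unrecorded)
    pool <- setdiff(seq_len(n), unrec)
    pick <- sample(pool, plan$n_no_response + plan$n_asr_only +
                     plan$n_manual_only)
    no_resp <- pick[seq_len(plan$n_no_response)]
    asr_only <- pick[plan$n_no_response + seq_len(plan$n_asr_only)]
    man_only <- pick[plan$n_no_response + plan$n_asr_only +
                       seq_len(plan$n_manual_only)]
    outcomes$status[unrec] <- "unrecorded"
    outcomes$status[no_resp] <- "no_response"
    outcomes$status[asr_only] <- "asr_only"
    outcomes$status[man_only] <- "manual_only"
    # unrecorded: nothing available for that sentence on either channel
    outcomes$asr_n_correct[unrec] <- NA_real_
    outcomes$manual_n_correct[unrec] <- NA_real_
    outcomes$vrt_s[unrec] <- NA_real_
    outcomes$vrt_manual_s[unrec] <- NA_real_
    outcomes$rsr_wps[unrec] <- NA_real_
    # no response: zero score, no timing on either channel
    outcomes$asr_n_correct[no_resp] <- 0
    outcomes$manual_n_correct[no_resp] <- 0
    outcomes$vrt_s[no_resp] <- NA_real_
    outcomes$vrt_manual_s[no_resp] <- NA_real_
    outcomes$rsr_wps[no_resp] <- NA_real_
    # recognizer-only: examiner heard no response
    outcomes$manual_n_correct[asr_only] <- 0
    outcomes$vrt_manual_s[asr_only] <- NA_real_
    outcomes$asr_n_correct[asr_only] <-
      pmax(outcomes$asr_n_correct[asr_only], 0)
    # manual-only: recognizer produced no output
    outcomes$asr_n_correct[man_only] <- 0
    outcomes$vrt_s[man_only] <- NA_real_
    outcomes$rsr_wps[man_only] <- NA_real_
  })
  outcomes
}

#' Simulate a full virtual cohort
#'
#' Runs the generator end to end: design, virtual listeners,
#' per-sentence outcomes (correctness, effort rating, VRT, RSR),
#' missingness injection, and symbolic recognizer alignments.  One
#' master seed determines everything; child seeds are derived
#' deterministically per stage, listener, and block.
#'
#' @param config a [cohort_config()].
#' @return list of class `virtual_cohort`: `trials` (trial table),
#'   `listeners`, `outcomes` (per-sentence generated values, channels,
#'   and status), `ratings` (per-block effort categories), `tokens`
#'   (token-level alignment table), `alignments` accessor via
#'   [tokens_to_alignments()], and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  seed <- config$seed
  vocab <- matrix_vocabulary()
  trials <- build_design(config$n_nh, config$n_hi, config$maskers,
                         config$snr_offsets, config$sentences_per_block,
                         seed = seed, vocabulary = vocab)
  ids <- unique(trials$listener_id)
  listeners <- vector("list", length(ids))
  names(listeners) <- ids
  outcome_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- trials[trials$listener_id == ids[i], ]
    grp <- if (rows$group[1L] == 1L) "NH" else "HI"
    li <- draw_listener(grp, derive_seed(seed, 2L, i), config,
                        listener_id = ids[i])
    listeners[[i]] <- li
    blocks <- unique(rows$block_id)
    per_block <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      br <- rows[rows$block_id == blocks[b], ]
      sim <- simulate_block(li, br, config$mode,
                            derive_seed(seed, 3L, i, b), config)
      per_block[[b]] <- data.frame(
        listener_id = br$listener_id, block_id = br$block_id,
        sentence_index = br$sentence_index,
        manual_n_correct = as.numeric(sim$sentences$n_correct),
        asr_n_correct = as.numeric(sim$sentences$n_correct),
        vrt_s = sim$sentences$vrt_s,
        vrt_manual_s = pmax(sim$sentences$vrt_s, 0),
        rsr_wps = sim$sentences$rsr_wps,
        srle = sim$srle,
        stringsAsFactors = FALSE)
    }
    outcome_rows[[i]] <- do.call(rbind, per_block)
  }
  outcomes <- do.call(rbind, outcome_rows)
  rownames(outcomes) <- NULL
  # occasional recognizer/examiner word-count disagreement
  with_seed(derive_seed(seed, 6L), {
    flip <- runif(nrow(outcomes)) < config$asr$discrepancy_rate
    shift <- sample(c(-1, 1), sum(flip), replace = TRUE)
    outcomes$asr_n_correct[flip] <-
      pmin(pmax(outcomes$asr_n_correct[flip] + shift, 0), 5)
  })
  outcomes <- inject_missingness(outcomes, config$missingness,
                                 seed = derive_seed(seed, 4L))
  tokens <- build_cohort_tokens(trials, outcomes, config, derive_seed(seed, 5L))
  ratings <- outcomes[outcomes$sentence_index == 1L,
                      c("listener_id", "block_id", "srle")]
  rownames(ratings) <- NULL
  structure(list(trials = trials, listeners = listeners,
                 outcomes = outcomes, ratings = ratings,
                 tokens = tokens, config = config),
            class = "virtual_cohort")
}

# Token table for all trials with recognizer output.
build_cohort_tokens <- function(trials, outcomes, config, seed) {
  has_asr <- outcomes$status %in% c("complete", "asr_only")
  words <- as.matrix(trials[, paste0("word", 1:5)])
  parts <- vector("list", nrow(trials))
  for (j in which(has_asr)) {
    n_corr <- as.integer(round(outcomes$asr_n_correct[j]))
    force_tok <- outcomes$status[j] == "asr_only"
    a <- simulate_alignment(words[j, ], n_corr,
                            outcomes$vrt_s[j], outcomes$rsr_wps[j],
                            sentence_end_s = trials$sentence_end_s[j],
                            seed = derive_seed(seed, j),
                            n_oov = NULL, oov_rate = config$asr$oov_rate,
                            listener_id = trials$listener_id[j],
                            block_id = trials$block_id[j],
                            sentence_index = trials$sentence_index[j])
    if (force_tok && !nrow(a$tokens)) {
      a <- simulate_alignment(words[j, ], 0L, outcomes$vrt_s[j],
                              max(outcomes$rsr_wps[j], config$rsr$min, 0.5),
                              sentence_end_s = trials$sentence_end_s[j],
                              seed = derive_seed(seed, j, 1L),
                              n_oov = 1L,
                              listener_id = trials$listener_id[j],
                              block_id = trials$block_id[j],
                              sentence_index = trials$sentence_index[j])
    }
    if (nrow(a$tokens)) {
      parts[[j]] <- data.frame(listener_id = a$listener_id,
                               block_id = a$block_id,
                               sentence_index = a$sentence_index,
                               token = a$tokens$token,
                               onset_s = a$tokens$onset_s,
                               duration_s = a$tokens$duration_s,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Rebuild alignment objects from a token table
#'
#' @param tokens token-level table (as in `simulate_cohort()$tokens`).
#' @param trials trial table supplying sentence end times.
#' @return list of [response_alignment()] objects (trials with no
#'   recognizer output are omitted, as in real recognizer logs).
#' @export
tokens_to_alignments <- function(tokens, trials = NULL) {
  key <- paste(tokens$listener_id, tokens$block_id, tokens$sentence_index,
               sep = "__")
  ends <- NULL
  if (!is.null(trials)) {
    tkey <- paste(trials$listener_id, trials$block_id, trials$sentence_index,
                  sep = "__")
    ends <- setNames(trials$sentence_end_s, tkey)
  }
  lapply(split(seq_len(nrow(tokens)), factor(key, levels = unique(key))),
         function(idx) {
           j <- idx[1L]
           k <- key[j]
           response_alignment(
             tokens$listener_id[j], tokens$block_id[j],
             tokens$sentence_index[j],
             tokens[idx, c("token", "onset_s", "duration_s")],
             if (!is.null(ends) && k %in% names(ends)) ends[[k]] else NA_real_)
         })
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf(
    "virtual cohort: %d trials, %d listeners, %d complete records\n",
    nrow(x$trials), length(x$listeners),
    sum(x$outcomes$status == "complete")))
  invisible(x)
}
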