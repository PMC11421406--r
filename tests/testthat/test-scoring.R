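voc <- matrix_vocabulary()
sent <- voc$word[c(1, 11, 21, 31, 41)]  # one word per slot

align_with <- function(tokens) {
  response_alignment("L01", "b01", 1,
    data.frame(token = tokens,
               onset_s = seq(1, by = 0.5, length.out = length(tokens)),
               duration_s = rep(0.3, length(tokens))), 0.5)
}

test_that("slot-wise word scoring counts presented words only", {
  expect_equal(score_sentence(sent, align_with(sent), voc), 5)
  expect_equal(score_sentence(sent, align_with(character()), voc), 0)
  expect_equal(score_sentence(sent, align_with(c(sent[1:3], "<OOV>", "<OOV>")),
                              voc), 3)
  # a word from the right slot but the wrong alternative does not count
  other <- voc$word[voc$slot == 1 & voc$word != sent[1]][1]
  expect_equal(score_sentence(sent, align_with(c(other, sent[2])), voc), 1)
  # order within the response does not matter
  expect_equal(score_sentence(sent, align_with(rev(sent)), voc), 5)
  expect_error(score_sentence(c("zzz", sent[2:5]), align_with(sent), voc),
               "not in the vocabulary")
})

test_that("block scores are percent of 25 presented words", {
  expect_equal(block_score(rep(5, 5)), 100)
  expect_equal(block_score(c(5, 4, 3, 2, 1)), 60)
  expect_equal(block_score(rep(0, 5)), 0)
  expect_error(block_score(c(5, NA, 3, 2, 1)), "impute")
})

test_that("unrecorded sentences are filled with the block's mean manual score", {
  asr <- c(5, 5, 4, 4, NA)
  man <- c(5, 5, 4, 4, NA)
  out <- impute_unrecorded(asr, man, rep("b01", 5))
  expect_equal(out$scores[5], 4.5)
  expect_equal(out$n_imputed, 1)
  # identity when nothing is missing
  out2 <- impute_unrecorded(1:5, 1:5, rep("b01", 5))
  expect_equal(out2$scores, 1:5)
  expect_equal(out2$n_imputed, 0)
  expect_error(impute_unrecorded(rep(NA_real_, 5), rep(NA_real_, 5),
                                 rep("b01", 5)), "entirely unrecorded")
  # the default cohort requires exactly three imputations
  cohort <- simulate_cohort(cohort_config(seed = 3))
  raw <- score_trials(cohort$trials, cohort$tokens, voc,
                      status = cohort$outcomes$status)
  imp <- impute_unrecorded(raw, cohort$outcomes$manual_n_correct,
                           paste(cohort$trials$listener_id,
                                 cohort$trials$block_id, sep = "__"))
  expect_equal(imp$n_imputed, 3)
  expect_false(anyNA(imp$scores))
})

test_that("RAU transform matches direct evaluation and is strictly monotone", {
  # frozen from the closed-form oracle (146/pi)(asin sqrt(x/(n+1)) +
  # asin sqrt((x+1)/(n+1))) - 23
  expect_equal(rau_transform(25, 25), 113.826388, tolerance = 1e-6)
  expect_equal(rau_transform(0, 25), -13.826388, tolerance = 1e-6)
  expect_equal(rau_transform(15, 25), 59.000189, tolerance = 1e-6)
  for (n in c(5, 25, 175)) {
    r <- rau_transform(0:n, n)
    expect_true(all(diff(r) > 0))
  }
  expect_error(rau_transform(26, 25), "<= n")
  expect_error(rau_transform(-1, 25), "<= n")
})

test_that("aggregation yields one row per participant, masker type, and SNR", {
  cohort <- simulate_cohort(small_config(seed = 13))
  raw <- score_trials(cohort$trials, cohort$tokens, voc,
                      status = cohort$outcomes$status)
  scores <- data.frame(asr_n_correct = raw,
                       manual_n_correct = cohort$outcomes$manual_n_correct)
  timing <- timing_table(cohort$tokens, cohort$trials)
  cells <- aggregate_cells(cohort$trials, scores, cohort$ratings, timing)
  expect_equal(nrow(cells), 5 * 2 * 5)
  expect_true(all(cells$mean_score_pct >= 0 & cells$mean_score_pct <= 100))
  expect_true(all(table(cells$listener_id) == 10))
  # constant VRT within a cell -> the median is that constant
  one_cell <- cohort$trials$listener_id == "NH01" &
    cohort$trials$masker_type == 2 & cohort$trials$snr_re_srt == 0
  timing2 <- timing
  timing2$vrt_s[one_cell] <- 0.333
  cells2 <- aggregate_cells(cohort$trials, scores, cohort$ratings, timing2)
  expect_equal(cells2$vrt_median_s[cells2$listener_id == "NH01" &
                                     cells2$masker_type == 2 &
                                     cells2$snr_re_srt == 0], 0.333)
})

test_that("recognizer and manual channels agree perfectly without injected discrepancy", {
  cfg <- small_config(seed = 19, asr = list(oov_rate = 0.3,
                                            discrepancy_rate = 0))
  cohort <- simulate_cohort(cfg)
  raw <- score_trials(cohort$trials, cohort$tokens, voc,
                      status = cohort$outcomes$status)
  expect_equal(raw, cohort$outcomes$manual_n_correct)
  cell_f <- interaction(cohort$trials$listener_id,
                        cohort$trials$masker_type,
                        cohort$trials$snr_re_srt, drop = TRUE)
  icc <- icc_absolute_agreement(
    as.numeric(tapply(raw, cell_f, mean)),
    as.numeric(tapply(cohort$outcomes$manual_n_correct, cell_f, mean)))
  expect_equal(icc$icc, 1)
})
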