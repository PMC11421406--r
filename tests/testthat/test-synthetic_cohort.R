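test_that("design cardinality is participants x maskers x SNRs x sentences", {
  d <- build_design(15, 12, default_maskers(), c(0, 3, 6, 9, 12), 5, seed = 1)
  expect_equal(nrow(d), 6075)
  expect_equal(nrow(build_design(1, 0, default_maskers()[1, ], 0, 5, seed = 1)), 5)
  expect_equal(nrow(build_design(2, 2, default_maskers()[c(1, 8), ],
                                 c(0, 3, 6, 9, 12), 5, seed = 7)), 200)
  # each listener: one block per masker x SNR, five sentences each
  one <- d[d$listener_id == "NH01", ]
  expect_equal(nrow(one), 225)
  expect_equal(length(unique(one$block_id)), 45)
  expect_true(all(table(one$masker_id, one$snr_re_srt) == 5))
  expect_error(build_design(0, 0), "participant")
  expect_error(build_design(1, 1, default_maskers()[0, ]), "masker")
})

test_that("virtual listeners honour the SRT and slope structure", {
  cfg <- cohort_config()
  # group means recovered in expectation for the stationary maskers
  srts <- sapply(1:300, function(i)
    draw_listener("NH", seed = i, cfg)$srt_per_masker[["OLnoise"]])
  expect_equal(mean(srts), -7.5, tolerance = 0.05)
  srts_hi <- sapply(1:300, function(i)
    draw_listener("HI", seed = i, cfg)$srt_per_masker[["IFnoise"]])
  expect_equal(mean(srts_hi), -5.5, tolerance = 0.1)
  # release from masking and slope ordering hold for every listener
  for (i in 1:25) {
    li <- draw_listener(if (i %% 2) "NH" else "HI", seed = i, cfg)
    stat <- li$srt_per_masker[cfg$maskers$masker_type == 2]
    fluct <- li$srt_per_masker[cfg$maskers$masker_type == 1]
    expect_true(all(outer(stat, fluct, `-`) > 0))
    expect_gt(li$slope_per_type[["stationary"]],
              li$slope_per_type[["fluctuating"]])
    expect_true(all(diff(li$srle_thresholds) > 0))
  }
  # degenerate draw: no between-listener variation -> identical SRTs
  cfg0 <- cohort_config(srt = list(
    stationary_means = cfg$srt$stationary_means,
    release = cfg$srt$release, between_sd = c(nh = 0, hi = 0),
    masker_sd = 0))
  a <- draw_listener("NH", seed = 1, cfg0)
  b <- draw_listener("NH", seed = 99, cfg0)
  expect_equal(a$srt_per_masker, b$srt_per_masker)
})

test_that("presentation level is 65 dB SPL plus half the 500-Hz loss, capped at 80", {
  expect_equal(presentation_level(0), 65)
  expect_equal(presentation_level(20), 75)
  expect_equal(presentation_level(40), 80)
  expect_equal(presentation_level(60), 80)
  expect_error(presentation_level(-5), "non-negative")
})

test_that("psychometric mode yields 50% words correct at SRT and near 100% at +12 dB", {
  cfg <- small_config()
  li <- draw_listener("NH", seed = 2, cfg)
  d <- build_design(1, 0, cfg$maskers, c(0, 12), 5, seed = 2)
  at0 <- d[d$snr_re_srt == 0 & d$masker_type == 2, ]
  props <- sapply(1:400, function(s) {
    blk <- simulate_block(li, at0[at0$block_id == at0$block_id[1], ],
                          "psychometric", seed = s, cfg)
    mean(blk$sentences$n_correct) / 5
  })
  expect_equal(mean(props), 0.5, tolerance = 0.03)
  expect_equal(psychometric_p(0, 0.15), 0.5)
  expect_gt(psychometric_p(12, 0.15), 0.999)
  # monotone non-decreasing in SNR
  expect_true(all(diff(psychometric_p(seq(-10, 15, 0.5), 0.07)) >= 0))
})

test_that("latent_linear block outcomes equal the linear predictor when noiseless", {
  cfg <- small_config(mode = "latent_linear",
                      latent = list(score = list(intercept = 30, snr_coef = 4,
                                                 type_coef = 8, group_coef = 0,
                                                 sd = 0)),
                      srle = list(intercept = 6.2, snr_coef = -0.28,
                                  stationary_offset = -0.9, sd = 0,
                                  threshold_jitter_sd = 0),
                      vrt = list(intercept = c(nh = 15, hi = 17),
                                 snr_coef = -0.55, stationary_offset = -2,
                                 sd = 0, pace_sd = 0),
                      rsr = list(base = c(nh = 2.3, hi = 1.8),
                                 snr_coef = 0.035, stationary_offset = 0.12,
                                 sd = 0, pace_sd = 0, min = 0.3))
  li <- draw_listener("NH", seed = 5, cfg)
  d <- build_design(1, 0, cfg$maskers, c(6), 5, seed = 5)
  blk <- simulate_block(li, d[d$masker_type == 2, ], "latent_linear",
                        seed = 3, cfg)
  expect_equal(blk$score_pct, 30 + 4 * 6 + 8 * 2)      # exact linear predictor
  expect_equal(blk$sentences$vrt_s,
               rep(inv_log_vrt(15 - 0.55 * 6 - 2), 5))
  expect_equal(blk$sentences$rsr_wps, rep(2.3 + 0.035 * 6 + 0.12, 5))
  expect_error(simulate_block(li, d[d$masker_type == 2, ], "nonsense"),
               "arg")
})

test_that("simulated alignments respect VRT, span, and the 30-ms grid", {
  sent <- c("Peter", "sieht", "zwei", "alte", "Ringe")
  a <- simulate_alignment(sent, 5, vrt_s = 0.45, rsr_wps = 2,
                          sentence_end_s = 10, seed = 1, n_oov = 0)
  expect_equal(nrow(a$tokens), 5)
  expect_lt(abs(a$tokens$onset_s[1] - 10 - 0.45), 0.0151)
  span <- a$tokens$onset_s[5] + a$tokens$duration_s[5] - a$tokens$onset_s[1]
  expect_equal(span, 2.5, tolerance = 0.031)
  times <- c(a$tokens$onset_s, a$tokens$duration_s)
  expect_equal(times, round(times / 0.03) * 0.03, tolerance = 1e-9)
  expect_setequal(a$tokens$token, sent)

  # no-response trial
  empty <- simulate_alignment(sent, 0, 0.4, 2, seed = 1, n_oov = 0)
  expect_equal(nrow(empty$tokens), 0)
  # early responses start before the sentence ends
  neg <- simulate_alignment(sent, 3, vrt_s = -0.12, rsr_wps = 2,
                            sentence_end_s = 10, seed = 2, n_oov = 0)
  expect_lt(neg$tokens$onset_s[1], 10)
  expect_lt(abs(neg$tokens$onset_s[1] - 10 + 0.12), 0.0151)
  expect_error(simulate_alignment(sent, 2, 0.4, 0, seed = 1, n_oov = 0),
               "rsr")
})

test_that("missingness injection marks disjoint trial sets with the stated counts", {
  cfg <- cohort_config(seed = 5)
  cohort <- simulate_cohort(cfg)
  st <- table(cohort$outcomes$status)
  expect_equal(unname(st[["unrecorded"]]), 3)
  expect_equal(unname(st[["no_response"]]), 22)
  expect_equal(unname(st[["asr_only"]]), 52)
  expect_equal(unname(st[["manual_only"]]), 6)
  expect_equal(unname(st[["complete"]]), 5992)
  # channels blanked as specified
  o <- cohort$outcomes
  expect_true(all(is.na(o$asr_n_correct[o$status == "unrecorded"])))
  expect_true(all(o$manual_n_correct[o$status == "asr_only"] == 0))
  expect_true(all(is.na(o$vrt_s[o$status == "manual_only"])))
  # recognizer-only trials really have recognizer output
  keys <- function(df) paste(df$listener_id, df$block_id, df$sentence_index)
  tok_keys <- unique(keys(cohort$tokens))
  expect_true(all(keys(o[o$status == "asr_only", ]) %in% tok_keys))
  expect_false(any(keys(o[o$status %in% c("unrecorded", "no_response",
                                          "manual_only"), ]) %in% tok_keys))

  # zero plan is the identity
  out0 <- inject_missingness(o[, setdiff(names(o), "status")],
                             missingness_plan(0, 0, 0, 0))
  expect_true(all(out0$status == "complete"))
  # single unrecorded trial on a tiny record set
  small <- o[o$listener_id == "NH01" & o$block_id == "b01",
             setdiff(names(o), "status")]
  out1 <- inject_missingness(small, missingness_plan(1, 0, 0, 0, seed = 2))
  expect_equal(sum(is.na(out1$asr_n_correct)), 1)
  expect_error(inject_missingness(small, missingness_plan(3, 3, 0, 0)),
               "assigns")
})

test_that("the same master seed reproduces the cohort exactly", {
  a <- simulate_cohort(small_config(seed = 77))
  b <- simulate_cohort(small_config(seed = 77))
  expect_identical(a$trials, b$trials)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$tokens, b$tokens)
  c2 <- simulate_cohort(small_config(seed = 78))
  expect_false(identical(a$outcomes, c2$outcomes))
})

test_that("cohort configuration round-trips through YAML and JSON", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_nh = 4, n_hi = 3, seed = 9,
                        asr = list(oov_rate = 0.1)), path)
  cfg <- read_cohort_config(path)
  expect_equal(cfg$n_nh, 4)
  expect_equal(cfg$asr$oov_rate, 0.1)
  expect_equal(cfg$asr$discrepancy_rate, 0.01)  # default retained
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_hi = 2, bogus_field = 1), jpath,
                       auto_unbox = TRUE)
  expect_error(read_cohort_config(jpath), "bogus_field")
})
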