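test_that("WAV files round-trip mono audio at 16-bit precision", {
  a <- white_noise(0.5, rate = 8000, seed = 2)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, path)
  b <- read_wav(path)
  expect_equal(b$rate, 8000)
  expect_equal(b$samples, a$samples, tolerance = 1e-4)  # 16-bit quantization
  expect_error(audio_segment(c(0, NaN), 8000), "finite")
  expect_error(audio_segment(0, -1), "positive")
})

test_that("pause detection finds gaps and respects the length filter", {
  a <- burst_gap_burst(gap_s = 0.6)
  p <- detect_pauses(a)
  expect_equal(nrow(p), 1)
  expect_equal(p$end_s - p$start_s, 0.6, tolerance = 0.05)
  expect_equal(p$start_s, 0.5, tolerance = 0.05)
  # continuous noise has no pauses
  expect_equal(nrow(detect_pauses(white_noise())), 0)
  # gaps shorter than min_pause_ms are ignored
  short <- burst_gap_burst(gap_s = 0.3)
  expect_equal(nrow(detect_pauses(short, min_pause_ms = 400)), 0)
  # silence is one whole-file pause
  silent <- audio_segment(rep(0, 8000), 8000)
  ps <- detect_pauses(silent)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$end_s, 1)
})

test_that("pause shortening caps pauses at 250 ms and removes the exact excess", {
  a <- burst_gap_burst(gap_s = 0.6)
  p <- detect_pauses(a)
  out <- shorten_pauses(a, p)
  gap <- p$end_s - p$start_s
  removed <- length(a$samples) - length(out$samples)
  expect_equal(removed / a$rate, gap - 0.25, tolerance = 1e-6)
  # idempotence: re-detection finds no pause over 250 ms (+1 frame)
  p2 <- detect_pauses(out)
  if (nrow(p2)) expect_true(all(p2$end_s - p2$start_s <= 0.25 + 0.01 + 1e-9))
  # samples outside the excised region and crossfade ramps are untouched
  n_keep_head <- round(a$rate * (p$start_s + 0.25 / 2)) - round(a$rate * 0.005)
  expect_equal(out$samples[seq_len(n_keep_head)],
               a$samples[seq_len(n_keep_head)])
  # pauses at or under the cap leave the signal untouched
  short <- burst_gap_burst(gap_s = 0.2)
  ps <- detect_pauses(short, min_pause_ms = 150)
  expect_identical(shorten_pauses(short, ps)$samples, short$samples)
  expect_error(shorten_pauses(a, data.frame(start_s = c(0.5, 0.6),
                                            end_s = c(0.9, 1.0))),
               "overlap")
})

test_that("spectral shaping imposes the target spectrum shape within 1 dB", {
  a <- white_noise(4, rate = 8000, seed = 12)
  # -6 dB/octave target over the analysis range
  centres <- third_octave_spectrum(a)$freq_hz
  target <- data.frame(freq_hz = centres,
                       level_db = -6 * log2(centres / 1000))
  shaped <- shape_spectrum(a, target)
  meas <- third_octave_spectrum(shaped)
  resid <- (meas$level_db - target$level_db)
  resid <- resid - mean(resid)  # shape, not absolute level
  expect_lt(max(abs(resid)), 1)
  # measured slope is about -6 dB per octave
  slope <- coef(lm(meas$level_db ~ log2(meas$freq_hz)))[2]
  expect_equal(unname(slope), -6, tolerance = 0.3)
  # shaping to the signal's own spectrum is (nearly) the identity
  own <- shape_spectrum(a, third_octave_spectrum(a))
  expect_equal(rms(own$samples - a$samples) / rms(a$samples), 0,
               tolerance = 0.02)
  # level preserved by construction
  expect_equal(rms(shaped$samples), rms(a$samples))
  # idempotence within the stated band tolerance
  twice <- shape_spectrum(shaped, target)
  m2 <- third_octave_spectrum(twice)
  expect_lt(max(abs(m2$level_db - meas$level_db)), 1)
})

test_that("superposition synthesis flattens the envelope but keeps the spectrum", {
  src <- speechy_noise()
  out <- synthesize_stationary(src, 32, seed = 5)
  expect_equal(length(out$samples), length(src$samples))
  expect_equal(rms(out$samples), rms(src$samples))
  # long-term third-octave spectrum preserved within 1 dB
  s_src <- third_octave_spectrum(src)
  s_out <- third_octave_spectrum(out)
  expect_lt(max(abs(s_out$level_db - s_src$level_db)), 1)
  # modulation depth decreases, and (on average over seeds) keeps
  # decreasing as more copies are superposed
  expect_lt(envelope_modulation_db(out), envelope_modulation_db(src))
  mean_depth <- function(n) mean(sapply(1:5, function(s)
    envelope_modulation_db(synthesize_stationary(src, n, seed = s))))
  expect_lt(mean_depth(32), mean_depth(4))
  # determinism, bit for bit
  expect_identical(synthesize_stationary(src, 8, seed = 9)$samples,
                   synthesize_stationary(src, 8, seed = 9)$samples)
  expect_error(synthesize_stationary(src, 1), "at least 2")
})

test_that("section rearrangement is sample-exact and involutive", {
  a <- white_noise(3, rate = 8000, seed = 14)
  lens <- c(1, 0.5, 1.5)
  ident <- rearrange_sections(a, lens, permutation = 1:3)
  expect_identical(ident$samples, a$samples)
  swapped <- rearrange_sections(a, c(1.5, 1.5), permutation = c(2, 1))
  back <- rearrange_sections(swapped, c(1.5, 1.5), permutation = c(2, 1))
  expect_identical(back$samples, a$samples)
  perm <- rearrange_sections(a, lens, seed = 3)
  expect_identical(sort(perm$samples), sort(a$samples))  # multiset preserved
  expect_error(rearrange_sections(a, c(1, 1)), "tile")
})

test_that("RMS normalization applies an exact scalar gain", {
  a <- white_noise(0.5, seed = 6)
  out <- rms_normalize(a, 0.1)
  expect_equal(rms(out$samples), 0.1)
  half <- audio_segment(a$samples / 2, a$rate)
  expect_equal(rms_normalize(half, rms(a$samples))$samples, a$samples)
  same <- rms_normalize(a, rms(a$samples))
  expect_equal(same$samples, a$samples)
  expect_error(rms_normalize(audio_segment(rep(0, 100), 8000), 1), "silent")
})
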