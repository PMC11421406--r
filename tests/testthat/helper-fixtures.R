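# Shared fixtures, generated in code.

# A small cohort: 3 NH + 2 HI listeners, one stationary and one
# fluctuating masker, five SNRs, five-sentence blocks -> 250 trials.
small_config <- function(seed = 11L, ...) {
  cohort_config(
    n_nh = 3L, n_hi = 2L,
    maskers = data.frame(masker_id = c("FLUCT1", "OLnoise"),
                         masker_type = c(1L, 2L),
                         stringsAsFactors = FALSE),
    missingness = missingness_plan(0L, 0L, 0L, 0L),
    seed = seed, ...)
}

# Burst - silence - burst audio fixture (deterministic noise).
burst_gap_burst <- function(rate = 8000, burst_s = 0.5, gap_s = 0.6,
                            seed = 4L) {
  n_b <- round(rate * burst_s)
  n_g <- round(rate * gap_s)
  noise <- with_fixture_seed(seed, stats::rnorm(2 * n_b, sd = 0.3))
  audio_segment(c(noise[seq_len(n_b)], rep(0, n_g),
                  noise[n_b + seq_len(n_b)]), rate)
}

white_noise <- function(dur_s = 2, rate = 8000, seed = 9L) {
  audio_segment(with_fixture_seed(seed,
    stats::rnorm(round(dur_s * rate), sd = 0.25)), rate)
}

# Speech-like fixture: noise with a slow on/off envelope, so it has
# strong envelope modulation for the superposition test.
speechy_noise <- function(dur_s = 4, rate = 8000, seed = 21L) {
  n <- round(dur_s * rate)
  t <- seq_len(n) / rate
  env <- 0.55 + 0.45 * sin(2 * pi * 3 * t)
  audio_segment(with_fixture_seed(seed, stats::rnorm(n, sd = 0.2)) * env,
                rate)
}

rms <- function(x) sqrt(mean(x^2))

# Full default cohort, simulated once per test run.
.fixture_cache <- new.env(parent = emptyenv())
default_cohort_cached <- function() {
  if (is.null(.fixture_cache$cohort))
    .fixture_cache$cohort <- simulate_cohort(cohort_config(seed = 1L))
  .fixture_cache$cohort
}

with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Independent ICC oracle: mean squares from a two-way fixed-effects
# ANOVA fitted with lm/anova (a different computational route than the
# closed-form implementation).
icc_oracle_aov <- function(x, y) {
  d <- data.frame(v = c(x, y), subj = factor(rep(seq_along(x), 2L)),
                  rater = factor(rep(1:2, each = length(x))))
  ms <- stats::anova(stats::lm(v ~ subj + rater, d))[["Mean Sq"]]
  n <- length(x)
  (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / n) * (ms[2] - ms[3]))
}
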