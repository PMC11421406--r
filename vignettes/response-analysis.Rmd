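---
title: "Automated analysis of verbal responses in matrix speech tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated analysis of verbal responses in matrix speech tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Matrix sentence tests present five-word sentences drawn from a fixed
10 x 5 word matrix (name - verb - number - adjective - object, 50 words
in total) in background maskers, and score how many words the listener
repeats correctly.  At signal-to-noise ratios (SNRs) above the
speech-recognition threshold (SRT, the SNR for 50% words correct),
scores saturate near 100% while the *effort* of listening keeps
changing.  Two additional measures can be extracted automatically from
a recognizer's word-level alignment of the listener's spoken response:

* **Verbal response time (VRT)** — the interval from the end of the
  presented sentence to the onset of the first response word.  It can
  be negative when listeners start before the sentence ends.
* **Response speech rate (RSR)** — the number of response words divided
  by the span from the first word's onset to the last word's end
  (pauses included), in words per second.

Together with a 7-category self-reported listening-effort rating
(SR-LE, "no effort" ... "extreme effort") collected after each
five-sentence block, these measures let VRT be evaluated as a
behavioral proxy for self-reported effort.  `vrteffort` implements the
full analysis pipeline and a synthetic-cohort generator that emulates
the study design, so every stage is testable without human recordings.

## Data model and formats

Recognizer output is consumed as CTM records (one token per line:
utterance id, channel, onset, duration, token), with onsets and
durations on a 30-ms grid — the temporal resolution of the recognizer's
analysis windows.  Tokens are either one of the 50 matrix words or the
literal `<OOV>` (out-of-vocabulary) marker; `<OOV>` tokens count for
the timing measures but never for scoring.  The utterance id encodes
the trial key as `listener__block__sentence`; sentence end times travel
in the trial table, and all other tables are plain CSV.

## Transforms

* **Word scoring** is slot-wise: a response word counts only for the
  matrix slot it belongs to.  Because each word belongs to exactly one
  slot, this is equivalent to counting presented words that appear in
  the response.
* **RAU**: proportion-correct scores are linearized with the
  rationalized arcsine transform,
  `RAU = (146/pi) * (asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))) - 23`,
  applied to pooled counts per analysis cell (a configuration flag
  switches to averaging per-block RAU values instead).
* **log-VRT**: `10 * ln((VRT + 0.15)/0.15)`.  The 150-ms floor reflects
  the shortest plausible response: minimal reaction times to known
  words are about 300 ms from word onset and the mean word duration is
  about 450 ms, so responses cannot legitimately begin more than about
  150 ms before the sentence ends.  Values at or below the floor are
  clamped to -149 ms (one grid step inside the floor) so the transform
  stays finite; the manual-examiner convention clamps negative VRTs to
  zero instead.
* **Rankit**: effort ratings are rank-normalized by mapping the mean
  rank r of n values to `qnorm((r - 0.5)/n)`, once over all block
  ratings ("global") and once within each participant ("individual").
  The individual variant removes differences in how participants use
  the category scale while preserving each participant's condition
  effects.  Ranks are assigned at the block level (ratings are given
  per block, 1215 in the full design), and ties — frequent with seven
  categories — receive mean ranks, the standard convention.
* **Within-participant z-scores** (sample SD) standardize log-VRT and
  RSR per participant before the group-level regressions, for the same
  reason.

## Statistical machinery

Agreement between the examiner and recognizer channels uses the
single-measures intraclass correlation from a two-way layout of the
"absolute agreement" type, `(MSR - MSE) / (MSR + MSE + (2/n)(MSC -
MSE))`, which penalizes systematic offsets; single measures is the
conservative choice where the averaging variant is not explicitly
called for.  The regression stage is forward-stepwise OLS with entry at
p <= .05 and removal at p >= .10 — the long-standing defaults of
commercial statistics packages, exposed as arguments — and reports
*every* candidate: non-entered predictors are shown with the
coefficient each would have if added to the final model, flagged as not
entered.  Diagnostics cover the Durbin-Watson statistic of the final
residuals in row order and a pairwise collinearity screen (|r| > .7);
because the effort rating is strongly collinear with SNR, the two never
enter the same model — the rating *replaces* SNR in its own model.  No
interaction terms are fitted: the masker-type-dependent slopes visible
in the data are described by the main-effects models plus the
qualitative contrast, and a slope interaction can be explored by
fitting the models per masker type.  Mixed-effects alternatives are out
of scope by design; with this balanced within-participant design,
participant random effects change the fixed-effect estimates very
little, and the z- and rank-transformations already absorb
between-participant offsets.

## The synthetic cohort

The generator reproduces the study design exactly: 15 normal-hearing
(NH) and 12 hearing-impaired (HI) virtual listeners, nine maskers (two
stationary, seven fluctuating), five SNRs at 0/3/6/9/12 dB above the
per-masker SRT, five-sentence blocks — 225 sentences per listener, 6075
in total, aggregated to 270 participant x masker-type x SNR cells.

Defaults that the design left open were fixed once, at values a
practitioner would call typical for matrix-test cohorts:

* SRT means for the stationary maskers: -7.5/-8.5 dB SNR (NH) and
  -5.1/-5.5 dB SNR (HI); fluctuating maskers lower by a 12 dB (NH) or
  6 dB (HI) release from masking.  Between-listener SD 1.5 dB (NH) and
  2.5 dB (HI) with 0.5 dB per-masker jitter; within-group SDs are not
  published numerically, so these are typical adaptive-procedure
  spreads.  A clamp guarantees the release-from-masking invariant for
  every listener.
* Psychometric slopes 15 %/dB (stationary) and 7 %/dB (fluctuating),
  matching the steeper-slope finding for stationary maskers and the
  matrix-test literature; word correctness is independent Bernoulli
  within a sentence, the simplest model consistent with word scoring.
* Latent effort `6.2 - 0.28*SNR - 0.9*[stationary]` (SD 0.8) cut at
  equally spaced cutpoints 1.5..6.5 with a per-listener shift (SD 0.5)
  emulating different interpretations of the category scale.
* log-VRT intercepts 15 (NH) and 17 (HI) (about 0.52 s and 0.67 s),
  -0.55/dB SNR, -2.0 for stationary maskers, residual SD 2.0, and a
  per-listener pace offset (SD 2.5) that the z-transformation must
  remove.  RSR: 2.3 (NH) / 1.8 (HI) words/s, +0.035/dB, +0.12
  stationary, SD 0.25, floored at 0.3 words/s.
* Recognizer behaviour: missed word slots produce `<OOV>` insertions
  with probability 0.3, and recognizer and examiner word counts
  disagree by one on 1% of sentences, which places the score ICC near
  the high-0.99s observed for such systems.

Missingness is injected uniformly at random (which conditions were
affected is not documented): 3 unrecorded sentences (always the last
sentence of distinct blocks, emulating a recording that stopped after
the fourth response), 22 with no response, 52 recognizer-only, 6
manual-only — leaving 5992 of 6075 sentences complete.  The recognizer
score of an unrecorded sentence is filled with the block's mean manual
score; "filling the sentence" and "increasing the block total by the
average" are arithmetically the same operation, so the ambiguity
between those two readings is moot.

One master seed drives everything.  Child seeds are derived as
`s <- (s*69069 + index*1013904223 + position) mod (2^31 - 1)` over the
stage/listener/block indices, so stages are independently reproducible
and a rerun with the same seed is bit-identical.

### The latent-linear mode and coefficient recovery

For validating the regression stage, the generator has a second mode
that draws the 270 analysis cells *directly* from linear models in SNR,
masker type (1 = fluctuating, 2 = stationary), and group (1 = NH, 2 =
HI).  The five default effect sets (`latent_effects()`) cover RAU
scores, rank-normalized effort, and z-transformed log-VRT and RSR, with
effect sizes and explained variance representative of matrix-test
listening-effort studies.  The residual SD is calibrated from the
target adjusted R-squared on the realized design,
`sd^2 = Var(Xb) * (1 - R2) / R2`, which a brute-force refit verifies
(the achieved adjusted R-squared matches the target within Monte-Carlo
error).  In the noiseless limit the stepwise fit recovers the
generating coefficients exactly; with calibrated noise, the recovery
distribution's SD reproduces the analytic coefficient standard errors,
and `recover_coefficients()` runs the whole experiment over replicate
seeds.  For the model using the effort rating as a predictor, the
rating is itself generated from the effort-on-SNR model first, so its
correlation with SNR (about -0.9, the reason the two never co-enter a
model) is realistic.

### What the synthetic data do and do not show

Passing tests demonstrate that the pipeline's arithmetic, transforms,
and model fits are correct and that known effects are recovered at the
design's sample size.  They do not validate recognizer accuracy on real
audio, listener behaviour beyond the generating models (e.g.,
sentence-level word dependence, effort heteroscedasticity across SNR,
which is not documented), or the floor/ceiling behaviour of real rating
scales.  Conclusions about real cohorts still require real recordings.

## Masker construction DSP

The DSP module covers the operations used to build masker families from
speech-like sources: frame-RMS pause detection (10-ms frames, -25 dB
relative threshold, 250-ms minimum — detection parameters are not
standardized, so all are configurable), pause shortening to a 250-ms
cap by symmetric excision around the pause centre with a 5-ms crossfade
(output length shrinks by exactly the excised excess), third-octave
spectral shaping to a target long-term spectrum (zero-phase FFT filter,
band match within +-1 dB), stationary-noise synthesis by summing random
circular time-shifts of a source (spectrum preserved, envelope
modulation shrinking roughly with sqrt(n)), section rearrangement, and
exact RMS normalization.  WAV input/output is a minimal mono PCM
reader/writer.  Fixtures in the tests are synthetic noises; the
standardized masker recordings themselves are licensed material and are
not reproduced.

## Numerical choices and problem sizes

Alignment times are quantized to the 30-ms grid (round half to even via
`round()`), and token durations are capped so quantization can never
create overlapping intervals.  Stepwise selection treats the NaN
p-values of zero-residual fits as significant (the noiseless limit) and
reports the Durbin-Watson statistic as `NA` there.  The test-suite runs
use one full 6075-sentence cohort (simulated once and cached), small
five-listener cohorts elsewhere, 100 replicate seeds for each
coefficient-recovery experiment, and a few seconds of 8-kHz audio for
the DSP properties; the complete suite and the acceptance script each
finish in about a minute on one core.

The package's interface is its functions — `simulate_cohort()`,
`run_pipeline()`, `recover_coefficients()`, and the DSP verbs — plus
`scripts/acceptance.R` as a worked command-line entry point; a separate
CLI wrapper would add nothing over `Rscript` one-liners on these
functions.

## Known limitations

* The generator's between-listener SDs and timing coefficients are
  plausible defaults, not estimates from data; only the effect
  directions and the latent-linear effect sizes are anchored.
* The manual channel is simulated as the recognizer channel with a
  small symmetric disagreement rate; real examiner errors are not
  symmetric.
* `shape_spectrum()` imposes band *shape* and preserves overall RMS; it
  does not calibrate absolute presentation levels.
* The stepwise "coefficient if added to the final model" convention for
  non-entered predictors is one of several reporting conventions;
  it is flagged in the output so downstream consumers can ignore those
  rows.
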