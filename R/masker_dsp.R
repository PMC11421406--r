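#' Mono audio container
#'
#' @param samples numeric vector of finite samples (nominal range
#'   -1..1).
#' @param rate sampling rate in Hz.
#' @return object of class `audio_segment`.
#' @export
audio_segment <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_vrt("rate must be a positive scalar")
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop_vrt("samples must be finite")
  structure(list(samples = samples, rate = rate), class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("audio_segment: %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              rms(x$samples)))
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))

#' Minimal mono WAV input/output
#'
#' Reads and writes RIFF/WAVE files: 16- or 32-bit integer PCM and
#' 32-bit float are read; writing is 16-bit PCM.  Only mono signals are
#' supported; unknown chunks are skipped on read.
#'
#' @param path WAV file.
#' @param audio an [audio_segment()] (samples clipped to -1..1 on
#'   write).
#' @return `read_wav()` returns an [audio_segment()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (riff != "RIFF") stop_vrt("%s is not a RIFF file", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (readChar(con, 4L, useBytes = TRUE) != "WAVE")
    stop_vrt("%s is not a WAVE file", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(fmt_raw[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1L, 2L, endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_vrt("%s: missing fmt or data chunk", path)
  if (fmt$channels != 1L) stop_vrt("only mono WAV is supported")
  samples <- switch(as.character(fmt$format),
    "1" = switch(as.character(fmt$bits),
      "16" = readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                     signed = TRUE, endian = "little") / 32768,
      "32" = readBin(data_raw, "integer", length(data_raw) / 4L, 4L,
                     endian = "little") / 2147483648,
      stop_vrt("unsupported PCM bit depth %d", fmt$bits)),
    "3" = readBin(data_raw, "double", length(data_raw) / 4L, 4L,
                  endian = "little"),
    stop_vrt("unsupported WAV format code %d", fmt$format))
  audio_segment(samples, fmt$rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(audio, path) {
  x <- pmin(pmax(audio$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")        # PCM, mono
  writeBin(as.integer(audio$rate), con, 4L, endian = "little")
  writeBin(as.integer(audio$rate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Detect speech pauses by frame energy
#'
#' Splits the signal into fixed frames, computes each frame's RMS level
#' relative to the long-term RMS, and reports maximal runs of frames at
#' least `threshold_db_rel` below the long-term level that last at
#' least `min_pause_ms`.  A fully silent signal is reported as one
#' pause spanning the whole file.
#'
#' @param audio an [audio_segment()].
#' @param frame_ms analysis frame (default 10 ms).
#' @param threshold_db_rel pause threshold relative to long-term RMS in
#'   dB (negative, default -25).
#' @param min_pause_ms minimal pause duration (default 250 ms).
#' @return data.frame with `start_s`, `end_s`, one row per pause.
#' @export
detect_pauses <- function(audio, frame_ms = 10, threshold_db_rel = -25,
                          min_pause_ms = 250) {
  if (frame_ms <= 0) stop_vrt("frame_ms must be positive")
  x <- audio$samples
  if (all(x == 0)) {
    return(data.frame(start_s = 0,
                      end_s = length(x) / audio$rate))
  }
  flen <- max(1L, round(audio$rate * frame_ms / 1000))
  n_frames <- floor(length(x) / flen)
  fr <- matrix(x[seq_len(n_frames * flen)], nrow = flen)
  frame_rms <- sqrt(colMeans(fr^2))
  thresh <- rms(x) * 10^(threshold_db_rel / 20)
  silent <- frame_rms < thresh
  r <- rle(silent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * flen / audio$rate >= min_pause_ms / 1000)
  data.frame(start_s = (starts[keep] - 1L) * flen / audio$rate,
             end_s = ends[keep] * flen / audio$rate)
}

#' Shorten speech pauses to a maximum duration
#'
#' For every pause longer than `max_pause_ms`, material is excised
#' symmetrically around the pause centre until the remaining pause
#' equals `max_pause_ms`, with a short linear crossfade (default 5 ms)
#' across each splice.  Samples outside the excised regions and
#' crossfade ramps are untouched, and the output is shorter than the
#' input by exactly the sum of the excised durations.
#'
#' @param audio an [audio_segment()].
#' @param pauses data.frame from [detect_pauses()] (non-overlapping).
#' @param max_pause_ms pause cap (default 250 ms).
#' @param crossfade_ms splice crossfade (default 5 ms).
#' @return shortened [audio_segment()].
#' @export
shorten_pauses <- function(audio, pauses, max_pause_ms = 250,
                           crossfade_ms = 5) {
  if (!nrow(pauses)) return(audio)
  pauses <- pauses[order(pauses$start_s), , drop = FALSE]
  if (any(pauses$end_s <= pauses$start_s))
    stop_vrt("pause with non-positive duration")
  if (nrow(pauses) > 1L &&
      any(pauses$start_s[-1L] < pauses$end_s[-nrow(pauses)]))
    stop_vrt("overlapping pauses")
  x <- audio$samples
  rate <- audio$rate
  keep_len <- round(rate * max_pause_ms / 1000)
  cf <- round(rate * crossfade_ms / 1000)
  for (i in rev(seq_len(nrow(pauses)))) {
    p0 <- max(1L, round(pauses$start_s[i] * rate) + 1L)
    p1 <- min(length(x), round(pauses$end_s[i] * rate))
    plen <- p1 - p0 + 1L
    excess <- plen - keep_len
    if (excess <= 0L) next
    centre <- p0 + plen %/% 2L
    if (excess > cf) {
      hard <- excess - cf
      c0 <- centre - hard %/% 2L
      c1 <- c0 + hard - 1L
      head_part <- x[seq_len(c0 - 1L)]
      tail_part <- x[seq.int(c1 + 1L, length(x))]
      # crossfade removes cf further samples by overlap-add
      la <- length(head_part)
      fade <- seq(1, 0, length.out = cf)
      mixed <- head_part[seq.int(la - cf + 1L, la)] * fade +
        tail_part[seq_len(cf)] * (1 - fade)
      x <- c(head_part[seq_len(la - cf)], mixed,
             tail_part[seq.int(cf + 1L, length(tail_part))])
    } else {
      c0 <- centre - excess %/% 2L
      x <- x[-seq.int(c0, c0 + excess - 1L)]
    }
  }
  audio_segment(x, rate)
}

#' Third-octave band spectrum
#'
#' Long-term band levels on the standard third-octave grid
#' (`1000 * 2^(k/3)` Hz centres, band edges a sixth octave either
#' side), from the signal's periodogram.  Levels are relative dB
#' (10 log10 of band power); only bands fully below the Nyquist
#' frequency are reported.
#'
#' @param audio an [audio_segment()].
#' @param f_min,f_max analysis range in Hz.
#' @return data.frame with `freq_hz` (centre) and `level_db`.
#' @export
third_octave_spectrum <- function(audio, f_min = 100, f_max = NULL) {
  x <- audio$samples
  n <- length(x)
  f_max <- f_max %||% (0.45 * audio$rate)
  p <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1L) * audio$rate / n
  half <- freqs <= audio$rate / 2
  p <- p[half]; freqs <- freqs[half]
  k <- seq(-30L, 30L)
  centres <- 1000 * 2^(k / 3)
  centres <- centres[centres >= f_min & centres * 2^(1 / 6) <= f_max]
  lev <- vapply(centres, function(fc) {
    inb <- freqs >= fc * 2^(-1 / 6) & freqs < fc * 2^(1 / 6)
    10 * log10(sum(p[inb]) + .Machine$double.xmin)
  }, 0)
  data.frame(freq_hz = centres, level_db = lev)
}

#' Shape a signal to a target long-term spectrum
#'
#' Measures the signal's third-octave spectrum, computes the per-band
#' gain `target - measured` (dB), interpolates the gains over frequency
#' (linear in log-frequency), and applies them as a zero-phase filter
#' in the frequency domain.  The output's long-term third-octave
#' spectrum matches the target shape within about +-1 dB for bands with
#' sufficient energy.
#'
#' @param audio an [audio_segment()].
#' @param target_spectrum data.frame with `freq_hz`, `level_db` (e.g. a
#'   long-term average speech spectrum); absolute level is not
#'   interpreted — only the band-to-band shape is imposed, the overall
#'   RMS is preserved.
#' @return shaped [audio_segment()].
#' @export
shape_spectrum <- function(audio, target_spectrum) {
  meas <- third_octave_spectrum(audio)
  tg <- approx(log(target_spectrum$freq_hz), target_spectrum$level_db,
               xout = log(meas$freq_hz), rule = 2L)$y
  if (any(!is.finite(meas$level_db) | meas$level_db < -200))
    stop_vrt("band with no energy in the input; target unattainable")
  gain_db <- tg - meas$level_db
  gain_db <- gain_db - mean(gain_db)
  x <- audio$samples
  n <- length(x)
  freqs <- (seq_len(n) - 1L) * audio$rate / n
  fold <- pmin(freqs, audio$rate - freqs)  # mirror for negative freqs
  g <- approx(log(meas$freq_hz), gain_db, xout = log(pmax(fold, 1e-3)),
              rule = 2L)$y
  y <- Re(fft(fft(x) * 10^(g / 20), inverse = TRUE)) / n
  out <- audio_segment(y, audio$rate)
  rms_normalize(out, rms(x))
}

#' Stationary noise by superposition
#'
#' Sums `n_superpositions` random circular time-shifts of a speech-like
#' source and normalizes back to the source RMS.  The long-term
#' spectrum of the result matches the source (within band tolerance)
#' while the envelope modulation depth shrinks roughly with the square
#' root of the number of superpositions — the classical recipe for a
#' speech-shaped stationary masker.
#'
#' @param audio source [audio_segment()].
#' @param n_superpositions number of shifted copies, `>= 2`.
#' @param seed RNG seed (same seed, same output, bit for bit).
#' @return stationary [audio_segment()] of the same length.
#' @export
synthesize_stationary <- function(audio, n_superpositions, seed = 1L) {
  if (n_superpositions < 2L)
    stop_vrt("need at least 2 superpositions")
  x <- audio$samples
  n <- length(x)
  y <- with_seed(seed, {
    shifts <- sample.int(n, n_superpositions, replace = TRUE)
    acc <- numeric(n)
    for (s in shifts) acc <- acc + c(x[seq.int(s, n)], x[seq_len(s - 1L)])
    acc
  })
  rms_normalize(audio_segment(y, audio$rate), rms(x))
}

#' Envelope modulation depth
#'
#' Standard deviation of the frame-RMS envelope in dB — a simple
#' modulation-depth summary used to verify that superposition flattens
#' a fluctuating source.
#'
#' @param audio an [audio_segment()].
#' @param frame_ms envelope frame (default 20 ms).
#' @return modulation depth in dB.
#' @export
envelope_modulation_db <- function(audio, frame_ms = 20) {
  flen <- max(1L, round(audio$rate * frame_ms / 1000))
  n_frames <- floor(length(audio$samples) / flen)
  fr <- matrix(audio$samples[seq_len(n_frames * flen)], nrow = flen)
  env <- sqrt(colMeans(fr^2))
  env <- env[env > 0]
  sd(20 * log10(env))
}

#' Rearrange fixed-length sections of a signal
#'
#' Splits the signal into consecutive sections of the given lengths and
#' permutes them (sample-exact within sections).  The section lengths
#' must tile the signal exactly.
#'
#' @param audio an [audio_segment()].
#' @param section_lengths_s section durations in seconds.
#' @param permutation permutation of `seq_along(section_lengths_s)`;
#'   when `NULL`, a seeded shuffle is used.
#' @param seed RNG seed for the shuffle.
#' @return rearranged [audio_segment()].
#' @export
rearrange_sections <- function(audio, section_lengths_s,
                               permutation = NULL, seed = 1L) {
  lens <- round(section_lengths_s * audio$rate)
  if (sum(lens) != length(audio$samples))
    stop_vrt("section lengths (%d samples) do not tile the signal (%d samples)",
             sum(lens), length(audio$samples))
  if (is.null(permutation))
    permutation <- with_seed(seed, sample.int(length(lens)))
  if (!identical(sort(as.integer(permutation)), seq_along(lens)))
    stop_vrt("invalid permutation")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  sections <- lapply(seq_along(lens),
                     function(i) audio$samples[starts[i]:ends[i]])
  audio_segment(unlist(sections[permutation]), audio$rate)
}

#' Normalize overall RMS level
#'
#' @param audio an [audio_segment()] (non-silent).
#' @param target_rms desired RMS.
#' @return scaled [audio_segment()] whose RMS equals `target_rms`.
#' @export
rms_normalize <- function(audio, target_rms) {
  r <- rms(audio$samples)
  if (r == 0) stop_vrt("cannot normalize a silent signal")
  audio_segment(audio$samples * (target_rms / r), audio$rate)
}
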