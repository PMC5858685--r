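#' Single-channel audio buffer
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate_hz sampling rate in Hz (default 44100).
#' @export
audio_buffer <- function(samples, sample_rate_hz = 44100) {
  s <- as.numeric(samples)
  if (any(!is.finite(s))) stop("samples must be finite")
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be > 0")
  structure(list(samples = s, sample_rate_hz = sample_rate_hz),
            class = "qbif_audio")
}

#' @export
print.qbif_audio <- function(x, ...) {
  cat(sprintf("Audio: %d samples @ %g Hz (%.3f s)\n", length(x$samples),
              x$sample_rate_hz, length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))

#' Mix target and masker at a target-to-masker ratio
#'
#' Scales the masker so that the broadband RMS level difference
#' `20 log10(rms(target) / rms(masker))` equals `tmr_db`, then returns the
#' sum.  The TMR is defined on full-bandwidth RMS before any filtering.  A
#' masker shorter than the target is looped with wrap-around (optionally
#' from a circular offset); a longer masker is trimmed.
#'
#' @param target,masker [audio_buffer()]s at the same rate.
#' @param tmr_db requested TMR in dB.
#' @param offset circular start offset (samples) applied to the masker
#'   before loop/trim; a session may draw it from its RNG stream.
#' @return mixed [audio_buffer()]; the scaled masker is attached as
#'   attribute `"masker"` for level verification.
#' @export
mix_at_tmr <- function(target, masker, tmr_db, offset = 0L) {
  if (target$sample_rate_hz != masker$sample_rate_hz)
    stop("target and masker sample rates differ")
  if (!is.finite(tmr_db)) stop("tmr_db must be finite")
  m <- masker$samples
  if (rms(m) == 0) stop("masker is silent; TMR is undefined")
  n <- length(target$samples)
  if (offset != 0L) m <- m[c((offset + 1L):length(m), seq_len(offset))]
  m <- rep_len(m, n)
  scale <- rms(target$samples) / (rms(m) * 10^(tmr_db / 20))
  m <- m * scale
  out <- audio_buffer(target$samples + m, target$sample_rate_hz)
  attr(out, "masker") <- m
  out
}

# Band filter: 6th-order Butterworth highpass at center/sqrt(2) cascaded
# with a 6th-order lowpass at center*sqrt(2).  The octave-wide edges are far
# apart, so each edge's 36 dB/oct roll-off is governed by one filter and the
# cascade realizes the 12th-order band filter in a numerically stable
# factorization (a direct transfer-function bandpass of that order is
# unstable in double precision at the lowest centers).
.band_filter <- function(x, center, fs, zero_phase = TRUE) {
  hp <- signal::butter(6, (center / sqrt(2)) / (fs / 2), type = "high")
  lp <- signal::butter(6, (center * sqrt(2)) / (fs / 2), type = "low")
  apply1 <- function(flt, s) {
    if (zero_phase) signal::filtfilt(flt, s) else
      as.numeric(signal::filter(flt, s))
  }
  apply1(lp, apply1(hp, x))
}

#' Split a signal through the octave filterbank
#'
#' One 12th-order Butterworth band filter per grid band, with cutoffs at
#' `center/sqrt(2)` and `center*sqrt(2)` and 36 dB/oct roll-off at each
#' cutoff.  Filters are applied zero-phase (forward-backward) by default so
#' that reconstruction is free of band-dependent group delay; set
#' `zero_phase = FALSE` for causal single-pass filtering.
#'
#' @param x an [audio_buffer()].
#' @param grid a [band_grid()]; the top band edge must be below Nyquist.
#' @param zero_phase logical.
#' @return list of band-limited [audio_buffer()]s, one per band.
#' @export
octave_filterbank <- function(x, grid = band_grid(), zero_phase = TRUE) {
  fs <- x$sample_rate_hz
  if (max(grid$centers) * sqrt(2) >= fs / 2)
    stop("band grid exceeds the Nyquist frequency")
  lapply(grid$centers, function(fc)
    audio_buffer(.band_filter(x$samples, fc, fs, zero_phase), fs))
}

#' Reconstruct a signal from a subset of filterbank bands
#'
#' @param bands list of equal-length [audio_buffer()]s (filterbank outputs).
#' @param mask logical vector; bands with `TRUE` are summed, the rest are
#'   omitted.
#' @return reconstructed [audio_buffer()].
#' @export
reconstruct_subset <- function(bands, mask) {
  if (length(bands) != length(mask)) stop("mask length does not match bands")
  ns <- vapply(bands, function(b) length(b$samples), integer(1))
  if (length(unique(ns)) != 1L) stop("band buffers have different lengths")
  fs <- bands[[1]]$sample_rate_hz
  out <- numeric(ns[1])
  for (i in which(as.logical(mask))) out <- out + bands[[i]]$samples
  audio_buffer(out, fs)
}

#' Synthesize one trial's stimulus
#'
#' The full signal chain: mix target and masker at the stimulus TMR, split
#' the mixture through the octave filterbank, and reconstruct with the
#' stimulus band mask.  For quiet stimuli the masker stage is skipped.
#'
#' @param target,masker [audio_buffer()]s.
#' @param stimulus a [stimulus_spec()].
#' @param grid a [band_grid()] matching the stimulus mask.
#' @param zero_phase passed to [octave_filterbank()].
#' @param offset masker circular offset passed to [mix_at_tmr()].
#' @return the processed [audio_buffer()].
#' @export
make_trial_stimulus <- function(target, masker, stimulus, grid = band_grid(),
                                zero_phase = TRUE, offset = 0L) {
  if (length(stimulus$band_mask) != grid$n_band)
    stop("stimulus mask does not match the band grid")
  mixed <- if (stimulus$in_quiet) target else
    mix_at_tmr(target, masker, stimulus$tmr_db, offset = offset)
  bands <- octave_filterbank(audio_buffer(mixed$samples, target$sample_rate_hz),
                             grid, zero_phase = zero_phase)
  reconstruct_subset(bands, stimulus$band_mask)
}

#' Synthetic audio fixtures
#'
#' Seeded generators for test and demo material: white Gaussian noise,
#' speech-shaped noise (white noise shaped by a one-pole lowpass at 500 Hz,
#' approximating a -6 dB/oct spectral slope above 500 Hz), and a multi-tone
#' complex at the band center frequencies.
#'
#' @param duration_s duration in seconds.
#' @param sample_rate_hz sampling rate.
#' @param seed RNG seed for the noise generators.
#' @param grid band grid whose centers the tone complex uses.
#' @return an [audio_buffer()].
#' @name audio_fixtures
NULL

#' @rdname audio_fixtures
#' @export
gen_white_noise <- function(duration_s = 0.5, sample_rate_hz = 44100, seed = 1L) {
  n <- round(duration_s * sample_rate_hz)
  x <- with_stream(new_rng_stream(seed), rnorm(n))
  audio_buffer(x / rms(x), sample_rate_hz)
}

#' @rdname audio_fixtures
#' @export
gen_speech_shaped_noise <- function(duration_s = 0.5, sample_rate_hz = 44100,
                                    seed = 1L) {
  w <- gen_white_noise(duration_s, sample_rate_hz, seed)
  # one-pole lowpass, -3 dB at 500 Hz
  a <- exp(-2 * pi * 500 / sample_rate_hz)
  y <- as.numeric(signal::filter(signal::Arma(b = 1 - a, a = c(1, -a)),
                                 w$samples))
  audio_buffer(y / rms(y), sample_rate_hz)
}

#' @rdname audio_fixtures
#' @export
gen_tone_complex <- function(duration_s = 0.5, sample_rate_hz = 44100,
                             grid = band_grid()) {
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  x <- rowSums(sapply(grid$centers, function(f) sin(2 * pi * f * t)))
  audio_buffer(x / rms(x), sample_rate_hz)
}
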