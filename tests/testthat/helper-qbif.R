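# Shared test utilities: ideal logistic-link listeners, uniform stimulus
# sampling from the pool, and an FFT reference band splitter used as an
# independent oracle for the filterbank.

# Response callback for a listener that obeys the logistic link exactly.
logistic_listener <- function(weights, srt_db, beta, seed = 1L) {
  params <- link_params(srt_db, beta)
  stream <- qbif:::new_rng_stream(seed)
  function(stimulus) {
    p <- logistic_link(compute_sii(weights, stimulus), params)
    qbif:::with_stream(stream, runif(1) < p)
  }
}

# n stimuli drawn uniformly (with replacement) from a pool.
sample_pool_stimuli <- function(pool, n, seed = 1L) {
  idx <- qbif:::with_stream(qbif:::new_rng_stream(seed),
                            sample.int(length(pool$stimuli), n, replace = TRUE))
  pool$stimuli[idx]
}

# Trial records from presenting `stimuli` to a callback.
collect_records <- function(stimuli, callback) {
  lapply(stimuli, function(s) list(stimulus = s, correct = callback(s)))
}

# Reference band-energy measurement: total |FFT|^2 between two frequencies.
fft_band_energy <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  spec <- abs(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= f_lo & freqs <= f_hi & freqs <= fs / 2
  sum(spec[keep])
}

# Analytic magnitude response of one cascaded octave band filter (6th-order
# Butterworth highpass at fc/sqrt2 times 6th-order lowpass at fc*sqrt2),
# evaluated directly from the filter polynomials -- an oracle independent of
# the time-domain filtering path.  zero_phase doubles the dB attenuation.
band_mag <- function(fc, f, fs, zero_phase = TRUE) {
  hp <- signal::butter(6, (fc / sqrt(2)) / (fs / 2), "high")
  lp <- signal::butter(6, (fc * sqrt(2)) / (fs / 2), "low")
  z <- exp(1i * 2 * pi * f / fs)
  mag <- function(flt) abs(signal::polyval(rev(flt$b), z) /
                             signal::polyval(rev(flt$a), z))
  m <- mag(hp) * mag(lp)
  if (zero_phase) m^2 else m
}

# Hann-windowed tone: confines the tone's spectrum so band-energy
# measurements are not dominated by onset/offset splatter.
windowed_tone <- function(freq, duration_s, fs) {
  t <- seq(0, duration_s, by = 1 / fs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(t) / length(t))
  audio_buffer(sin(2 * pi * freq * t) * w, fs)
}

# Cached heavyweight simulation shared by the acceptance blocks.
acceptance_cache <- local({
  env <- new.env()
  function(name, expr) {
    if (is.null(env[[name]])) env[[name]] <- force(expr)
    env[[name]]
  }
})
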