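#' Octave band grid
#'
#' The frequency axis of the SII model: a set of octave-spaced band center
#' frequencies.  The default six-band grid (250--8000 Hz) covers the speech
#' spectrum at octave resolution.
#'
#' @param center_frequencies_hz ascending numeric vector of band centers in
#'   Hz; successive centers are expected to be octave-spaced.
#' @return object of class `qbif_grid` with elements `centers` and `n_band`.
#' @examples
#' g <- band_grid()
#' g$n_band
#' @export
band_grid <- function(center_frequencies_hz = c(250, 500, 1000, 2000, 4000, 8000)) {
  f <- as.numeric(center_frequencies_hz)
  if (length(f) < 2L) stop("a band grid needs at least 2 bands")
  if (any(!is.finite(f)) || any(f <= 0)) stop("band centers must be positive and finite")
  if (any(diff(f) <= 0)) stop("band centers must be strictly increasing")
  structure(list(centers = f, n_band = length(f)), class = "qbif_grid")
}

#' Octave-spaced grid of a given size starting at 250 Hz
#'
#' Convenience constructor used by the band-count simulation sweep; bands are
#' nominal (the simulations never touch audio).
#'
#' @param n_band number of bands.
#' @export
octave_grid <- function(n_band) band_grid(250 * 2^(seq_len(n_band) - 1L))

#' @export
print.qbif_grid <- function(x, ...) {
  cat("Octave band grid:", x$n_band, "bands at",
      paste(x$centers, collapse = ", "), "Hz\n")
  invisible(x)
}

#' Spectral weights (band importance function)
#'
#' Validates a per-band weight vector: non-negative, matching the grid, and
#' summing to 1 (the reported, normalized form of the band importance
#' function).
#'
#' @param weights numeric vector of per-band weights.
#' @param grid optional `qbif_grid` to check the length against.
#' @return the weight vector, invisibly validated.
#' @export
spectral_weights <- function(weights, grid = NULL) {
  w <- as.numeric(weights)
  if (!is.null(grid) && length(w) != grid$n_band)
    stop("weights length does not match the band grid")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  w
}

#' Logistic link parameters
#'
#' @param srt_db speech recognition threshold: the TMR (dB) at 50% correct.
#' @param beta slope of the logistic link (> 0); units 1/dB on the rescaled
#'   SII axis.
#' @export
link_params <- function(srt_db, beta) {
  if (!is.finite(srt_db)) stop("srt_db must be finite")
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  structure(list(srt_db = srt_db, beta = beta), class = "qbif_link")
}

#' Stimulus specification
#'
#' One trial's stimulus: a broadband target-to-masker ratio and a switch
#' vector saying which octave bands are retained at reconstruction.  Stimuli
#' presented in quiet (no masker) carry `in_quiet = TRUE`, which forces the
#' audibility of every presented band to 1 regardless of `tmr_db`.
#'
#' @param tmr_db target-to-masker ratio in dB.
#' @param band_mask logical vector, `TRUE` where the band is presented.
#' @param in_quiet logical; quiet presentation (audibility 1 in presented
#'   bands).
#' @export
stimulus_spec <- function(tmr_db, band_mask, in_quiet = FALSE) {
  if (!is.finite(tmr_db)) stop("tmr_db must be finite")
  m <- as.logical(band_mask)
  if (length(m) < 1L || anyNA(m)) stop("band_mask must be a logical vector without NA")
  structure(list(tmr_db = as.numeric(tmr_db), band_mask = m,
                 in_quiet = isTRUE(in_quiet)),
            class = "qbif_stimulus")
}

#' @export
print.qbif_stimulus <- function(x, ...) {
  cat(sprintf("Stimulus: TMR %+g dB%s, bands %s\n", x$tmr_db,
              if (x$in_quiet) " (quiet)" else "",
              paste(as.integer(x$band_mask), collapse = "")))
  invisible(x)
}

#' Band audibility
#'
#' Maps a per-band TMR (dB) to the proportion of speech information audible
#' in that band: the TMR is clamped to \[-15, 15\] dB and mapped linearly onto
#' \[0, 1\], i.e. `A = (clamp(TMR, -15, 15) + 15) / 30`.
#'
#' @param tmr_prime_db per-band TMR in dB (vectorized).
#' @return audibility in \[0, 1\].
#' @examples
#' band_audibility(c(-15, 0, 15, 30))
#' @export
band_audibility <- function(tmr_prime_db) {
  x <- as.numeric(tmr_prime_db)
  if (any(!is.finite(x))) stop("tmr_prime_db must be finite")
  (pmin(pmax(x, -15), 15) + 15) / 30
}

#' Speech Intelligibility Index of a stimulus
#'
#' `SII = sum_i w_i * n_i * A_i` where `n_i` is the band switch and `A_i` the
#' band audibility.  All presented bands share the broadband mixing TMR
#' (target and masker are mixed once, then filtered), so `A_i` is constant
#' across presented bands; omitted bands contribute zero.
#'
#' @param weights spectral weights (length `n_band`, summing to 1).
#' @param stimulus a [stimulus_spec()].
#' @return SII in \[0, 1\].
#' @examples
#' w <- rep(1 / 6, 6)
#' compute_sii(w, stimulus_spec(15, rep(TRUE, 6)))
#' @export
compute_sii <- function(weights, stimulus) {
  w <- as.numeric(weights)
  if (length(w) != length(stimulus$band_mask))
    stop("weights and stimulus band_mask have different lengths")
  a <- if (stimulus$in_quiet) 1 else band_audibility(stimulus$tmr_db)
  sum(w[stimulus$band_mask]) * a
}

#' Logistic link from SII to probability correct
#'
#' `p = 1 / (1 + exp(-beta * (30 * SII - 15 - SRT)))`.  The SII is rescaled
#' to the +/-15 dB audibility axis so that the SRT is expressed as a TMR in
#' dB.  Computed with [stats::plogis()], which is overflow-safe for extreme
#' slopes.
#'
#' @param sii SII value(s) in \[0, 1\].
#' @param params a [link_params()] object.
#' @return probability in (0, 1).
#' @export
logistic_link <- function(sii, params) {
  s <- as.numeric(sii)
  if (any(!is.finite(s)) || any(s < 0 | s > 1)) stop("sii must be in [0, 1]")
  plogis(params$beta * (30 * s - 15 - params$srt_db))
}

#' Classical asymmetric SII transfer function
#'
#' The transfer function used in the classical SII literature and to drive
#' simulated listeners: `p = (1 - 10^(-SII * P / Q))^N`.  Unlike the logistic
#' link it is asymmetric about its midpoint.
#'
#' @param sii SII value(s) in \[0, 1\].
#' @param P proficiency scaling (default 1).
#' @param Q fitting constant (> 0); smaller values steepen the function.
#' @param N fitting exponent (> 0); larger values lower the probability.
#' @return probability in \[0, 1).
#' @examples
#' traditional_link(1, P = 1, Q = 0.3, N = 5)
#' @export
traditional_link <- function(sii, P = 1, Q, N) {
  if (!is.finite(Q) || Q <= 0) stop("Q must be > 0")
  if (!is.finite(N) || N <= 0) stop("N must be > 0")
  s <- as.numeric(sii)
  if (any(!is.finite(s)) || any(s < 0 | s > 1)) stop("sii must be in [0, 1]")
  # exp(N * log1p(-10^(-s P / Q))) is accurate near both ends of the range
  out <- exp(N * log1p(-10^(-s * P / Q)))
  out[s == 0] <- 0
  out
}

#' Spectral centroid of a band importance function
#'
#' Weight-averaged deviation of the band center frequencies from 1 kHz, in
#' octaves: `sum_i w_i * log2(f_i / 1000)`.  Summarizes where along the
#' spectrum a listener concentrates their weights.
#'
#' @param weights spectral weights.
#' @param grid a [band_grid()].
#' @return centroid in octaves re 1 kHz.
#' @export
spectral_centroid <- function(weights, grid = band_grid()) {
  w <- spectral_weights(weights, grid)
  sum(w * log2(grid$centers / 1000))
}
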