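#' Sample a simulated listener
#'
#' Draws a ground-truth listener for validation studies.  Spectral weights
#' are drawn uniformly on (0, 1) per band and normalized to sum to 1.
#' Responses follow the classical asymmetric transfer function
#' ([traditional_link()]) with proficiency `P = 1`, `Q ~ U(0.2, 0.5)` and
#' `N ~ U(2, 12)` -- deliberately a different family than the logistic link
#' used for fitting, so recovery exercises robustness to link
#' misspecification.
#'
#' @param grid a [band_grid()].
#' @param seed integer seed for the draw.
#' @return object of class `qbif_listener`: `weights`, `P`, `Q`, `N`,
#'   `grid`.
#' @export
sample_listener <- function(grid = band_grid(), seed = 1L) {
  stream <- new_rng_stream(seed)
  draws <- with_stream(stream, list(u = runif(grid$n_band),
                                    Q = runif(1, 0.2, 0.5),
                                    N = runif(1, 2, 12)))
  structure(list(weights = draws$u / sum(draws$u), P = 1, Q = draws$Q,
                 N = draws$N, grid = grid),
            class = "qbif_listener")
}

#' @export
print.qbif_listener <- function(x, ...) {
  cat("Simulated listener:", x$grid$n_band, "bands\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat(sprintf("  P = %g, Q = %.3f, N = %.2f\n", x$P, x$Q, x$N))
  invisible(x)
}

#' Probability that a listener answers a stimulus correctly
#'
#' Deterministic part of the response model: the listener's true SII for the
#' stimulus passed through the asymmetric transfer function.
#'
#' @param listener a [sample_listener()] object.
#' @param stimulus a [stimulus_spec()].
#' @export
response_probability <- function(listener, stimulus) {
  traditional_link(compute_sii(listener$weights, stimulus),
                   P = listener$P, Q = listener$Q, N = listener$N)
}

#' Draw a Bernoulli response from a simulated listener
#'
#' Uses the current RNG state of the caller; wrap with [listener_callback()]
#' for a self-contained reproducible stream.
#'
#' @inheritParams response_probability
#' @return logical: correct / incorrect.
#' @export
respond <- function(listener, stimulus) {
  runif(1) < response_probability(listener, stimulus)
}

#' Response callback with a private RNG stream
#'
#' @param listener a [sample_listener()] object.
#' @param seed integer seed of the response stream.
#' @return `function(stimulus) -> logical`, reproducible given the seed.
#' @export
listener_callback <- function(listener, seed = 1L) {
  force(listener)
  stream <- new_rng_stream(seed)
  function(stimulus) with_stream(stream, respond(listener, stimulus))
}

#' Normalized RMS error between weight vectors
#'
#' Root-mean-square deviation between estimated and true weights, scaled by
#' `n_band / 6` so that the error is expressed per octave on the fixed
#' six-octave span: because weights sum to 1, raw per-band errors shrink
#' mechanically as the band count grows, and the rescaling makes grids of
#' different sizes comparable.
#'
#' @param estimated,truth weight vectors of equal length.
#' @param n_band band count used for the normalization; defaults to the
#'   vector length.
#' @export
normalized_rmse <- function(estimated, truth, n_band = length(truth)) {
  if (length(estimated) != length(truth))
    stop("estimated and truth have different lengths")
  sqrt(mean((as.numeric(estimated) - as.numeric(truth))^2)) * n_band / 6
}

# Fit checkpoints for one listener's trial stream.  X, y are the full design
# and responses; returns the normalized weight-recovery error at each
# checkpoint (NA where the fit is degenerate).
.checkpoint_errors <- function(X, y, checkpoints, truth, ridge) {
  coef <- NULL
  vapply(checkpoints, function(k) {
    fit <- tryCatch(
      fit_logistic_ridge(X[seq_len(k), , drop = FALSE], y[seq_len(k)],
                         ridge = ridge, coef_init = coef),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NA_real_)
    coef <<- fit$coef
    est <- tryCatch(to_sii_params(fit$coef), error = function(e) NULL)
    if (is.null(est)) return(NA_real_)
    normalized_rmse(est$weights, truth)
  }, numeric(1))
}

#' Run a strategy-comparison simulation
#'
#' For each simulated listener, generates a full trial stream under one of
#' the three sampling strategies, refits the penalized logistic regression
#' on the trials collected so far at regular checkpoints, converts the
#' coefficients to spectral weights, and scores the normalized RMS error
#' against the listener's true weights.  Also records each listener's
#' overall percent-correct.
#'
#' @param strategy `"qbif"`, `"compound"`, or `"random"`.
#' @param n_listeners number of simulated listeners.
#' @param n_trials trials per listener.
#' @param checkpoint_step refitting interval in trials.
#' @param seed root seed; listeners, schedules and responses derive child
#'   seeds from it, so runs are reproducible.
#' @param grid a [band_grid()].
#' @param mode selection mode for the adaptive strategy (bulk default
#'   `"fisher"`).
#' @param ridge ridge penalty of the fits.
#' @return object of class `qbif_experiment`: `curve` (an error curve with
#'   `trial_counts`, `mean_nrmse`, `sd_nrmse`, `n_listeners`), the
#'   per-listener `nrmse` matrix, per-listener percent-correct `scores`, and
#'   their `score_mean` / `score_sd`.
#' @seealso [trials_to_criterion()], [nband_sweep()]
#' @export
run_strategy_experiment <- function(strategy = c("qbif", "compound", "random"),
                                    n_listeners = 100L, n_trials = 500L,
                                    checkpoint_step = 10L, seed = 1L,
                                    grid = band_grid(), mode = "fisher",
                                    ridge = 0.01) {
  strategy <- match.arg(strategy)
  if (n_listeners < 1L) stop("n_listeners must be >= 1")
  checkpoints <- unique(c(seq(checkpoint_step, n_trials, by = checkpoint_step),
                          n_trials))
  nrmse <- matrix(NA_real_, n_listeners, length(checkpoints))
  scores <- numeric(n_listeners)
  presented_range <- c(2L, grid$n_band - 1L)
  for (i in seq_len(n_listeners)) {
    lseed <- child_seed(seed, paste0(strategy, "-listener-", i))
    listener <- sample_listener(grid, seed = lseed)
    if (strategy == "qbif") {
      cfg <- qbif_config(grid = grid, presented_range = presented_range,
                         n_trials = n_trials, ridge = ridge, mode = mode,
                         seed = child_seed(seed, paste0("qbif-session-", i)))
      sess <- run_qbif(listener, cfg)
      X <- design_matrix(lapply(sess$records, `[[`, "stimulus"))
      y <- as.numeric(sess$trials$correct)
    } else {
      sched <- switch(strategy,
        compound = compound_schedule(grid$n_band, n_trials,
                                     seed = child_seed(seed, paste0("sched-", i))),
        random = random_schedule(grid$n_band, n_trials,
                                 seed = child_seed(seed, paste0("sched-", i))))
      cb <- listener_callback(listener,
                              seed = child_seed(seed, paste0("resp-", i)))
      y <- vapply(sched, function(s) as.numeric(cb(s)), numeric(1))
      X <- design_matrix(sched)
    }
    scores[i] <- 100 * mean(y)
    nrmse[i, ] <- .checkpoint_errors(X, y, checkpoints, listener$weights, ridge)
  }
  structure(list(
    strategy = strategy,
    curve = structure(list(trial_counts = checkpoints,
                           mean_nrmse = colMeans(nrmse, na.rm = TRUE),
                           sd_nrmse = apply(nrmse, 2, sd, na.rm = TRUE),
                           n_listeners = n_listeners),
                      class = "qbif_error_curve"),
    nrmse = nrmse, scores = scores,
    score_mean = mean(scores), score_sd = sd(scores),
    n_trials = n_trials, seed = seed), class = "qbif_experiment")
}

#' @export
print.qbif_experiment <- function(x, ...) {
  cat(sprintf("Strategy simulation (%s): %d listeners x %d trials\n",
              x$strategy, x$curve$n_listeners, x$n_trials))
  cat(sprintf("  percent correct: mean %.1f%%, SD %.1f%%\n",
              x$score_mean, x$score_sd))
  cat(sprintf("  final mean normalized RMSE: %.4f\n",
              tail(x$curve$mean_nrmse, 1)))
  invisible(x)
}

#' Trials needed to reach an error criterion
#'
#' Locates the first crossing of the across-listener mean error curve below
#' `threshold`, linearly interpolating between checkpoints.
#'
#' @param x a `qbif_experiment` or `qbif_error_curve`.
#' @param threshold normalized RMS error criterion (default 0.05).
#' @return interpolated trial count, or `NA` if the curve never crosses.
#' @export
trials_to_criterion <- function(x, threshold = 0.05) {
  curve <- if (inherits(x, "qbif_experiment")) x$curve else x
  m <- curve$mean_nrmse
  t <- curve$trial_counts
  below <- which(m <= threshold)
  if (length(below) == 0L) return(NA_real_)
  j <- below[1L]
  if (j == 1L) return(t[1L])
  t[j - 1L] + (t[j] - t[j - 1L]) * (m[j - 1L] - threshold) / (m[j - 1L] - m[j])
}

#' Band-count sweep of the adaptive procedure
#'
#' Repeats the adaptive-strategy simulation for several band counts.  For
#' `n_band != 6` the pool keeps the same TMR grid and generalizes the
#' presented-band range to 2 to `n_band - 1`; grids are nominal octave grids
#' from 250 Hz (the simulation never touches audio).
#'
#' @param n_band_values integer vector of band counts.
#' @param n_listeners listeners per band count.
#' @param n_trials trials per listener.
#' @param checkpoint_step refitting interval.
#' @param seed root seed.
#' @param mode selection mode (bulk default `"fisher"`).
#' @return named list (one `qbif_experiment` per band count).
#' @export
nband_sweep <- function(n_band_values = c(4L, 6L, 8L, 10L), n_listeners = 100L,
                        n_trials = 500L, checkpoint_step = 10L, seed = 1L,
                        mode = "fisher") {
  out <- lapply(n_band_values, function(nb) {
    if (nb < 2L) stop("n_band must be >= 2")
    run_strategy_experiment("qbif", n_listeners = n_listeners,
                            n_trials = n_trials,
                            checkpoint_step = checkpoint_step, seed = seed,
                            grid = octave_grid(nb), mode = mode)
  })
  names(out) <- as.character(n_band_values)
  out
}
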