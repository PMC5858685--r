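#' Select the next stimulus by one-step-ahead entropy minimization
#'
#' Scans the stimulus pool and returns the candidate minimizing the expected
#' post-trial posterior log-determinant (see [expected_post_logdet()]).
#' Candidates within 1e-12 of the minimum are treated as tied and broken
#' uniformly at random with the session stream.
#'
#' @param state current `qbif_posterior`.
#' @param pool a [build_pool()] object.
#' @param records trial records behind `state` (needed for `refit` mode).
#' @param mode `"refit"` (literal expectation over outcomes) or `"fisher"`
#'   (rank-one approximation).
#' @param stream optional `qbif_rng` stream for tie-breaking; ties are broken
#'   with the first tied candidate when absent.
#' @param ridge penalty for refit-mode refits.
#' @return the selected [stimulus_spec()]; the pool index is attached as
#'   attribute `"index"` and the criterion value as `"criterion"`.
#' @export
select_next <- function(state, pool, records = NULL,
                        mode = c("refit", "fisher"), stream = NULL,
                        ridge = 0.01) {
  mode <- match.arg(mode)
  crit <- if (mode == "fisher") {
    fisher_criterion(state, pool$design)
  } else {
    vapply(pool$stimuli, function(s)
      expected_post_logdet(state, records, s, mode = "refit", ridge = ridge),
      numeric(1))
  }
  tied <- which(crit <= min(crit) + 1e-12)
  pick <- if (length(tied) == 1L) tied else if (is.null(stream)) tied[1L] else
    with_stream(stream, tied[sample.int(length(tied), 1L)])
  out <- pool$stimuli[[pick]]
  attr(out, "index") <- pick
  attr(out, "criterion") <- crit[pick]
  out
}

#' Session configuration
#'
#' Collects the tunables of an adaptive session.  Defaults are the standard
#' operating point: six octave bands, TMRs -5 to 15 dB in 5-dB steps, 2 to 5
#' presented bands (a 280-stimulus pool), a 300-trial budget, ridge 0.01,
#' and the literal refit-mode selection criterion.
#'
#' @param grid a [band_grid()].
#' @param tmr_grid_db admissible TMRs in dB.
#' @param presented_range presented-band count range.
#' @param n_trials total trial budget (training + adaptive).
#' @param ridge ridge penalty of the logistic fits.
#' @param mode selection criterion mode, `"refit"` or `"fisher"`; bulk
#'   simulations use `"fisher"` for speed.
#' @param link link family of the regression; only `"logistic"` is
#'   implemented (an asymmetric-link variant is a recognized but
#'   unimplemented option).
#' @param seed root seed; child streams for training shuffles, tie-breaks
#'   and simulated-listener responses are derived from it.
#' @return list of class `qbif_config`.
#' @export
qbif_config <- function(grid = band_grid(), tmr_grid_db = seq(-5, 15, by = 5),
                        presented_range = c(2, 5), n_trials = 300L,
                        ridge = 0.01, mode = c("refit", "fisher"),
                        link = "logistic", seed = 1L) {
  mode <- match.arg(mode)
  if (!identical(link, "logistic"))
    stop("config field 'link': only the logistic link is implemented")
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("config field 'n_trials' must be >= 1")
  if (!is.numeric(ridge) || ridge < 0)
    stop("config field 'ridge' must be >= 0")
  pr <- as.integer(presented_range)
  if (length(pr) != 2L || pr[1] < 1L || pr[2] > grid$n_band || pr[1] > pr[2])
    stop("config field 'presented_range' must lie within [1, n_band]")
  if (is.null(seed)) stop("config field 'seed' is mandatory")
  structure(list(grid = grid, tmr_grid_db = as.numeric(tmr_grid_db),
                 presented_range = pr, n_trials = as.integer(n_trials),
                 ridge = ridge, mode = mode, link = link,
                 seed = as.integer(seed)),
            class = "qbif_config")
}

#' Run a full adaptive session
#'
#' Executes the staged training schedule, then alternates posterior refit /
#' one-step-ahead stimulus selection / presentation until the trial budget is
#' reached.  The posterior is refitted after every trial (training trials
#' included) and the interim coefficient estimates are logged per trial.
#'
#' @param respond either a response callback `function(stimulus) -> logical`
#'   or a [sample_listener()] object (wrapped with its own response stream).
#' @param config a [qbif_config()].
#' @return object of class `qbif_session` with elements:
#'   \describe{
#'     \item{records}{list of trial records (`stimulus`, `correct`).}
#'     \item{trials}{data frame: trial, phase, tmr_db, mask, correct,
#'       predicted probability at selection (NA during training), interim
#'       `ln|cov|`.}
#'     \item{interim_coef}{matrix of per-trial interim coefficients.}
#'     \item{final}{list: `weights`, `srt_db`, `beta`, `posterior`.}
#'     \item{n_training, n_adaptive, config}{bookkeeping.}
#'   }
#' @examples
#' listener <- sample_listener(seed = 7)
#' s <- run_qbif(listener, qbif_config(n_trials = 60, mode = "fisher", seed = 7))
#' s$final$weights
#' @export
run_qbif <- function(respond, config = qbif_config()) {
  grid <- config$grid
  pool <- build_pool(grid, config$tmr_grid_db, config$presented_range)
  train_stream <- new_rng_stream(child_seed(config$seed, "training"))
  tie_stream <- new_rng_stream(child_seed(config$seed, "tie-break"))
  if (inherits(respond, "qbif_listener")) {
    listener <- respond
    respond <- listener_callback(listener,
                                 seed = child_seed(config$seed, "listener"))
  }
  if (!is.function(respond)) stop("respond must be a function or a qbif_listener")

  n_max <- config$n_trials
  p <- grid$n_band + 1L
  X <- matrix(0, n_max, p)
  y <- numeric(n_max)
  records <- vector("list", n_max)
  phase <- character(n_max)
  tmr <- numeric(n_max)
  masks <- character(n_max)
  phat <- rep(NA_real_, n_max)
  lndet <- rep(NA_real_, n_max)
  interim <- matrix(NA_real_, n_max, p)

  present <- function(k, stimulus) {
    ok <- tryCatch(isTRUE(respond(stimulus)), error = function(e) e)
    if (inherits(ok, "error")) {
      cond <- structure(
        class = c("qbif_partial_result_error", "error", "condition"),
        list(message = paste0("response callback failed at trial ", k, ": ",
                              conditionMessage(ok)),
             call = sys.call(-1),
             records = records[seq_len(k - 1L)]))
      stop(cond)
    }
    ok
  }

  k <- 0L
  coef_last <- NULL
  fit_last <- NULL
  refit <- function() {
    fit <- fit_logistic_ridge(X[seq_len(k), , drop = FALSE], y[seq_len(k)],
                              ridge = config$ridge, coef_init = coef_last)
    post <- .as_posterior(fit)
    coef_last <<- post$coef_mean
    fit_last <<- post
    interim[k, ] <<- post$coef_mean
    lndet[k] <<- log_det_cov(post)
    post
  }

  # ---- training phase ------------------------------------------------------
  tmr_train <- max(pool$tmr_grid_db)
  tstate <- new_training_state(grid, tmr_db = tmr_train,
                               min_presented = config$presented_range[1],
                               stream = train_stream)
  while (!tstate$finished && k < n_max) {
    step <- training_next(tstate)
    tstate <- step$state
    if (is.null(step$stimulus)) break
    k <- k + 1L
    st <- step$stimulus
    ok <- present(k, st)
    tstate <- training_update(tstate, ok)
    records[[k]] <- list(stimulus = st, correct = ok)
    X[k, ] <- design_row(st)
    y[k] <- as.numeric(ok)
    phase[k] <- "training"
    tmr[k] <- st$tmr_db
    masks[k] <- paste(as.integer(st$band_mask), collapse = "")
    refit()
  }
  n_training <- k

  # ---- adaptive phase ------------------------------------------------------
  post <- fit_last
  while (k < n_max) {
    st <- select_next(post, pool, records = records[seq_len(k)],
                      mode = config$mode, stream = tie_stream,
                      ridge = config$ridge)
    k <- k + 1L
    phat[k] <- plogis(sum(design_row(st) * post$coef_mean))
    ok <- present(k, st)
    records[[k]] <- list(stimulus = st, correct = ok)
    X[k, ] <- design_row(st)
    y[k] <- as.numeric(ok)
    phase[k] <- "adaptive"
    tmr[k] <- st$tmr_db
    masks[k] <- paste(as.integer(st$band_mask), collapse = "")
    post <- refit()
  }

  final <- tryCatch(to_sii_params(fit_last), error = function(e) NULL)
  structure(list(
    records = records[seq_len(k)],
    trials = data.frame(trial = seq_len(k), phase = phase[seq_len(k)],
                        tmr_db = tmr[seq_len(k)], mask = masks[seq_len(k)],
                        correct = y[seq_len(k)] == 1,
                        phat = phat[seq_len(k)], lndet = lndet[seq_len(k)],
                        stringsAsFactors = FALSE),
    interim_coef = interim[seq_len(k), , drop = FALSE],
    final = c(final, list(posterior = fit_last)),
    n_training = n_training, n_adaptive = k - n_training,
    config = config), class = "qbif_session")
}

#' @export
print.qbif_session <- function(x, ...) {
  cat("qBIF session:", length(x$records), "trials (", x$n_training,
      "training,", x$n_adaptive, "adaptive )\n")
  if (!is.null(x$final$weights)) {
    cat("  weights:", paste(sprintf("%.3f", x$final$weights), collapse = " "), "\n")
    cat(sprintf("  SRT: %.2f dB   beta: %.3f\n", x$final$srt_db, x$final$beta))
  }
  cat(sprintf("  percent correct: %.1f%%\n",
              100 * mean(x$trials$correct)))
  invisible(x)
}
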