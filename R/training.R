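#' Initialize the training schedule
#'
#' A session opens with a staged "training" block that seeds the regression
#' before one-step-ahead selection activates (training of the algorithm, not
#' the listener).  All training stimuli use the maximum TMR of the pool
#' (15 dB by default).  The schedule omits 1 band per trial first (each band
#' once, in random order), then 2 omitted bands (all pairs, random order),
#' then 3, then 4; a phase's masks are shuffled on entry and drawn without
#' replacement.  After every response the stopping rules are checked:
#' training ends when (a) more than 10 training trials have been run and the
#' cumulative proportion correct drops below 65%, or (b) more than 50
#' training trials have been run.
#'
#' @param grid a [band_grid()].
#' @param tmr_db TMR used for all training trials (dB).
#' @param min_presented smallest presented-band count admitted by the pool;
#'   caps the deepest phase at `n_band - min_presented` omitted bands.
#' @param stream a `qbif_rng` stream used for the per-phase shuffles.
#' @return a training-state list; advance it with [training_next()] and
#'   [training_update()].
#' @keywords internal
new_training_state <- function(grid, tmr_db = 15, min_presented = 2,
                               stream = new_rng_stream(1)) {
  structure(list(grid = grid, tmr_db = tmr_db,
                 max_phase = min(4L, grid$n_band - as.integer(min_presented)),
                 phase = 0L, queue = list(), n_trials = 0L, n_correct = 0L,
                 finished = FALSE, stream = stream),
            class = "qbif_training")
}

# All masks with `omit` bands omitted, shuffled under the state's stream.
.phase_queue <- function(state, omit) {
  n <- state$grid$n_band
  combos <- combn(n, omit, simplify = FALSE)
  masks <- lapply(combos, function(idx) {
    m <- rep(TRUE, n)
    m[idx] <- FALSE
    m
  })
  with_stream(state$stream, masks[sample.int(length(masks))])
}

#' Next training stimulus
#'
#' @param state a training state.
#' @return list with `stimulus` (a [stimulus_spec()], or `NULL` when the
#'   schedule is finished) and the advanced `state`.
#' @keywords internal
training_next <- function(state) {
  if (state$finished) return(list(stimulus = NULL, state = state))
  while (length(state$queue) == 0L) {
    if (state$phase >= state$max_phase) {
      state$finished <- TRUE
      return(list(stimulus = NULL, state = state))
    }
    state$phase <- state$phase + 1L
    state$queue <- .phase_queue(state, state$phase)
  }
  mask <- state$queue[[1L]]
  state$queue <- state$queue[-1L]
  list(stimulus = stimulus_spec(state$tmr_db, mask), state = state)
}

#' Record a training response and evaluate the stopping rules
#'
#' @param state a training state.
#' @param correct logical response.
#' @return the advanced state; `state$finished` is `TRUE` once a stopping
#'   rule fires.
#' @keywords internal
training_update <- function(state, correct) {
  state$n_trials <- state$n_trials + 1L
  state$n_correct <- state$n_correct + as.integer(isTRUE(correct))
  score <- state$n_correct / state$n_trials
  if ((state$n_trials > 10L && score < 0.65) || state$n_trials > 50L)
    state$finished <- TRUE
  state
}
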