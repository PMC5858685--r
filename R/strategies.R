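#' Compound sampling schedule
#'
#' The paired-trial baseline strategy: one band at a time serves as the
#' target band (cycling band 1 to `n_band`).  For the current target band,
#' every pair of context bands drawn from the remaining bands appears once,
#' in shuffled order; each context pair contributes two consecutive trials --
#' speech through the context bands plus the target band, then through the
#' context bands alone.  With 6 bands that is 10 context pairs (20 trials)
#' per target and 120 trials per full pass.  All stimuli present speech in
#' quiet.  The schedule is truncated (possibly mid-pair) at `total_trials`.
#'
#' @param n_band number of bands (>= 3).
#' @param total_trials schedule length.
#' @param seed integer seed for the shuffles.
#' @return list of [stimulus_spec()] objects with `in_quiet = TRUE`.
#' @export
compound_schedule <- function(n_band = 6L, total_trials = 500L, seed = 1L) {
  n_band <- as.integer(n_band)
  if (n_band < 3L) stop("the compound strategy needs at least 3 bands")
  if (total_trials < 1L) stop("total_trials must be >= 1")
  stream <- new_rng_stream(seed)
  out <- vector("list", total_trials)
  k <- 0L
  target <- 0L
  while (k < total_trials) {
    target <- target %% n_band + 1L
    pairs <- combn(setdiff(seq_len(n_band), target), 2L, simplify = FALSE)
    pairs <- with_stream(stream, pairs[sample.int(length(pairs))])
    for (ctx in pairs) {
      with_target <- rep(FALSE, n_band)
      with_target[c(ctx, target)] <- TRUE
      without <- rep(FALSE, n_band)
      without[ctx] <- TRUE
      for (m in list(with_target, without)) {
        if (k >= total_trials) break
        k <- k + 1L
        out[[k]] <- stimulus_spec(0, m, in_quiet = TRUE)
      }
      if (k >= total_trials) break
    }
  }
  out
}

#' Random sampling schedule
#'
#' The non-adaptive baseline: speech in quiet through a random subset of the
#' bands.  All masks with 2 to `n_band - 1` presented bands (56 masks for 6
#' bands) are shuffled and presented once each; fresh shuffles are
#' concatenated until `total_trials` is reached.
#'
#' @param n_band number of bands (>= 3 so that the presented range 2 to
#'   `n_band - 1` is non-empty).
#' @param total_trials schedule length.
#' @param seed integer seed for the shuffles.
#' @return list of [stimulus_spec()] objects with `in_quiet = TRUE`.
#' @export
random_schedule <- function(n_band = 6L, total_trials = 500L, seed = 1L) {
  n_band <- as.integer(n_band)
  if (n_band < 3L) stop("the random strategy needs at least 3 bands")
  if (total_trials < 1L) stop("total_trials must be >= 1")
  stream <- new_rng_stream(seed)
  masks <- list()
  for (np in 2:(n_band - 1L)) {
    masks <- c(masks, lapply(combn(n_band, np, simplify = FALSE), function(idx) {
      m <- rep(FALSE, n_band)
      m[idx] <- TRUE
      m
    }))
  }
  out <- vector("list", total_trials)
  k <- 0L
  while (k < total_trials) {
    block <- with_stream(stream, masks[sample.int(length(masks))])
    for (m in block) {
      if (k >= total_trials) break
      k <- k + 1L
      out[[k]] <- stimulus_spec(0, m, in_quiet = TRUE)
    }
  }
  out
}
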