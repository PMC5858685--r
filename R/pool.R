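#' Build the stimulus pool
#'
#' Enumerates every combination of a TMR from `tmr_grid_db` with a band mask
#' whose presented-band count lies in `presented_range`.  With the defaults
#' (6 bands, TMRs -5 to 15 dB in 5-dB steps, 2 to 5 bands presented) this
#' yields 56 distinct masks and 280 stimuli.  Ordering is deterministic:
#' TMR-major, masks in lexicographic order (band 1 most significant).
#'
#' @param grid a [band_grid()].
#' @param tmr_grid_db numeric vector of admissible TMRs (dB).
#' @param presented_range length-2 integer vector: minimum and maximum number
#'   of presented bands.
#' @return object of class `qbif_pool`: `stimuli` (list of
#'   [stimulus_spec()]), `tmr_grid_db`, `presented_range`, `grid`, plus the
#'   matrix forms `mask_matrix` and `tmr` and the precomputed `design`
#'   matrix used by the adaptive engine.
#' @examples
#' pool <- build_pool()
#' length(pool$stimuli)      # 280
#' nrow(unique(pool$mask_matrix))  # 56
#' @export
build_pool <- function(grid = band_grid(), tmr_grid_db = seq(-5, 15, by = 5),
                       presented_range = c(2, 5)) {
  if (length(tmr_grid_db) < 1L || any(!is.finite(tmr_grid_db)))
    stop("tmr_grid_db must be a non-empty finite numeric vector")
  pr <- as.integer(presented_range)
  if (length(pr) != 2L || pr[1] > pr[2] || pr[1] < 1L || pr[2] > grid$n_band)
    stop("presented_range must be within [1, n_band] with min <= max")
  n <- grid$n_band
  # lexicographic masks, band 1 most significant
  masks <- as.matrix(expand.grid(rev(rep(list(c(TRUE, FALSE)), n)),
                                 KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  ord <- do.call(order, as.data.frame(!masks))
  masks <- masks[ord, , drop = FALSE]
  k <- rowSums(masks)
  masks <- masks[k >= pr[1] & k <= pr[2], , drop = FALSE]
  dimnames(masks) <- NULL
  if (nrow(masks) == 0L) stop("presented_range admits no masks")

  tmr_sorted <- sort(unique(as.numeric(tmr_grid_db)))
  tmr <- rep(tmr_sorted, each = nrow(masks))
  mask_matrix <- masks[rep(seq_len(nrow(masks)), times = length(tmr_sorted)), ,
                       drop = FALSE]
  stimuli <- lapply(seq_along(tmr), function(i)
    stimulus_spec(tmr[i], mask_matrix[i, ]))
  design <- cbind(mask_matrix * band_audibility(tmr), 1)
  structure(list(stimuli = stimuli, tmr_grid_db = tmr_sorted,
                 presented_range = pr, grid = grid, tmr = tmr,
                 mask_matrix = mask_matrix, design = design),
            class = "qbif_pool")
}

#' @export
print.qbif_pool <- function(x, ...) {
  cat("Stimulus pool:", length(x$stimuli), "stimuli (",
      nrow(x$mask_matrix) / length(x$tmr_grid_db), "masks x",
      length(x$tmr_grid_db), "TMRs ),",
      "presented bands", x$presented_range[1], "-", x$presented_range[2], "\n")
  invisible(x)
}
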