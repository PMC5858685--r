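#' Predictor row of the logistic-regression parameterization
#'
#' The SII model with a logistic link is nonlinear in `(w, SRT, beta)` but
#' becomes an ordinary logistic regression after reparameterization: with
#' per-band slopes `c_i = 30 * beta * w_i` and intercept
#' `c_0 = -beta * (15 + SRT)`, the linear predictor for a stimulus is
#' `sum_i c_i * n_i * A_i + c_0`.  This function returns the corresponding
#' predictor row: band-wise `mask * audibility`, then a trailing 1 for the
#' intercept.
#'
#' @param stimulus a [stimulus_spec()].
#' @return numeric vector of length `n_band + 1`.
#' @export
design_row <- function(stimulus) {
  a <- if (stimulus$in_quiet) 1 else band_audibility(stimulus$tmr_db)
  c(as.numeric(stimulus$band_mask) * a, 1)
}

#' Design matrix for a list of stimuli
#'
#' @param stimuli list of [stimulus_spec()] objects.
#' @return matrix with one [design_row()] per stimulus.
#' @export
design_matrix <- function(stimuli) {
  do.call(rbind, lapply(stimuli, design_row))
}

# Ridge-penalized logistic regression by Newton iteration with step halving.
# Returns coefficients, the covariance (inverse of the penalized observed
# information at the optimum), and convergence information.  `coef_init`
# enables warm starts during sequential refitting.
fit_logistic_ridge <- function(X, y, ridge = 0.01, coef_init = NULL,
                               max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)), ridge >= 0)
  coef <- if (is.null(coef_init)) rep(0, p) else as.numeric(coef_init)

  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      0.5 * ridge * sum(b^2)
  }

  ll <- pen_ll(coef)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% coef)
    pr <- plogis(eta)
    wt <- pr * (1 - pr)
    H <- crossprod(X, X * wt)
    diag(H) <- diag(H) + ridge
    g <- drop(crossprod(X, y - pr)) - ridge * coef
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking: the penalized likelihood must not decrease
    lam <- 1
    repeat {
      cand <- coef + lam * step
      ll_new <- pen_ll(cand)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- max(abs(lam * step))
    coef <- coef + lam * step
    ll <- ll_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # information at the final iterate
  eta <- drop(X %*% coef)
  pr <- plogis(eta)
  H <- crossprod(X, X * (pr * (1 - pr)))
  diag(H) <- diag(H) + ridge
  cov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (!is.null(cov)) cov <- (cov + t(cov)) / 2
  list(coef = coef, cov = cov, converged = converged, loglik = ll,
       n = nrow(X))
}

#' Fit the posterior over SII coefficients from trial records
#'
#' Maximizes the Bernoulli log-likelihood of the correct/incorrect flags
#' given the predictor rows of [design_row()], minus a ridge penalty
#' `ridge/2 * ||c||^2` on all coefficients (intercept included).  The
#' penalty keeps the optimum finite under complete separation, which is
#' routine in the first trials of a session.  The returned covariance is the
#' inverse of the penalized observed information at the optimum; together
#' with the coefficient vector it defines the Gaussian posterior whose
#' entropy drives adaptive stimulus selection.
#'
#' @param records list of trial records, each a list with elements
#'   `stimulus` (a [stimulus_spec()]) and `correct` (logical).
#' @param ridge penalty weight (>= 0); default 0.01.
#' @param coef_init optional warm-start coefficient vector.
#' @param max_iter,tol Newton iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return object of class `qbif_posterior`: `coef_mean`, `coef_cov`,
#'   `n_trials_fit`, `loglik`.
#' @seealso [to_sii_params()] to convert coefficients to weights/SRT/slope.
#' @export
fit_posterior <- function(records, ridge = 0.01, coef_init = NULL,
                          max_iter = 100L, tol = 1e-8) {
  if (length(records) < 1L) stop("at least one trial record is required")
  if (ridge < 0) stop("ridge must be >= 0")
  X <- design_matrix(lapply(records, `[[`, "stimulus"))
  y <- vapply(records, function(r) as.numeric(isTRUE(r$correct)), numeric(1))
  fit <- fit_logistic_ridge(X, y, ridge = ridge, coef_init = coef_init,
                            max_iter = max_iter, tol = tol)
  .as_posterior(fit)
}

.as_posterior <- function(fit) {
  if (!fit$converged || is.null(fit$cov)) {
    cond <- structure(
      class = c("qbif_convergence_error", "error", "condition"),
      list(message = "logistic fit did not converge within the iteration cap",
           call = sys.call(-1), last = fit))
    stop(cond)
  }
  structure(list(coef_mean = fit$coef, coef_cov = fit$cov,
                 n_trials_fit = fit$n, loglik = fit$loglik),
            class = "qbif_posterior")
}

#' @export
print.qbif_posterior <- function(x, ...) {
  cat("SII coefficient posterior from", x$n_trials_fit, "trials\n")
  cat("  coef:", paste(sprintf("%.3f", x$coef_mean), collapse = " "), "\n")
  cat("  ln|cov|:", sprintf("%.3f", log_det_cov(x)), "\n")
  invisible(x)
}

#' Convert regression coefficients to SII parameters
#'
#' Inverts the reparameterization of [design_row()].  Because the weights sum
#' to 1, `beta = sum_i c_i / 30` (using the raw coefficients),
#' `SRT = -c_0 / beta - 15`, and the reported weights are the slopes clipped
#' at zero and renormalized: `max(c_i, 0) / sum_j max(c_j, 0)`.  Negative
#' interim slopes are legitimate during adaptation (the unconstrained fit
#' keeps the Gaussian posterior well-defined); clipping applies only to the
#' reported weights.
#'
#' @param state a `qbif_posterior` or a raw coefficient vector
#'   `(c_1, ..., c_nband, c_0)`.
#' @return list with `weights`, `srt_db`, `beta`.
#' @export
to_sii_params <- function(state) {
  coef <- if (inherits(state, "qbif_posterior")) state$coef_mean else as.numeric(state)
  p <- length(coef) - 1L
  cb <- coef[seq_len(p)]
  c0 <- coef[p + 1L]
  pos <- pmax(cb, 0)
  if (sum(pos) <= 0) {
    cond <- structure(
      class = c("qbif_degenerate_fit_error", "error", "condition"),
      list(message = "all band slopes are <= 0; weights are undefined",
           call = sys.call(-1)))
    stop(cond)
  }
  beta <- sum(cb) / 30
  list(weights = pos / sum(pos), srt_db = -c0 / beta - 15, beta = beta)
}

#' Log-determinant of the posterior covariance
#'
#' The entropy of the Gaussian posterior is an affine function of
#' `ln|coef_cov|`, so this is the quantity the adaptive engine minimizes in
#' expectation.  Computed via a Cholesky factorization.
#'
#' @param state a `qbif_posterior` (or a covariance matrix).
#' @return `ln|coef_cov|`.
#' @export
log_det_cov <- function(state) {
  cov <- if (inherits(state, "qbif_posterior")) state$coef_cov else as.matrix(state)
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) {
    cond <- structure(
      class = c("qbif_numerical_state_error", "error", "condition"),
      list(message = "covariance is not positive definite",
           call = sys.call(-1)))
    stop(cond)
  }
  2 * sum(log(diag(R)))
}

#' Expected posterior log-determinant after a candidate trial
#'
#' The one-step-ahead criterion: the expected value, over the two possible
#' responses to `candidate`, of the post-trial `ln|cov|`.  The expectation is
#' weighted by the current-state predicted probability of a correct
#' response.
#'
#' Two evaluation modes:
#' \describe{
#'   \item{`refit`}{For each hypothetical outcome, refit the penalized
#'     logistic regression on `records` plus the candidate trial and take the
#'     log-determinant of the refitted covariance.  This is the literal
#'     expectation over outcomes and the session default.}
#'   \item{`fisher`}{Outcome-independent rank-one information update: by the
#'     matrix determinant lemma,
#'     `ln|cov| - ln(1 + p(1-p) * x' cov x)` with `x = design_row(candidate)`.
#'     A fast approximation that skips the refits; default in bulk
#'     simulations.}
#' }
#'
#' @param state current `qbif_posterior`.
#' @param records the trial records `state` was fitted on (required for
#'   `refit` mode).
#' @param candidate candidate [stimulus_spec()].
#' @param mode `"refit"` or `"fisher"`.
#' @param ridge penalty used for refits.
#' @return expected log-determinant (scalar).
#' @export
expected_post_logdet <- function(state, records = NULL, candidate,
                                 mode = c("refit", "fisher"), ridge = 0.01) {
  mode <- match.arg(mode)
  x <- design_row(candidate)
  phat <- plogis(sum(x * state$coef_mean))
  if (mode == "fisher") {
    quad <- drop(crossprod(x, state$coef_cov %*% x))
    return(log_det_cov(state) - log1p(phat * (1 - phat) * quad))
  }
  if (is.null(records)) stop("refit mode requires the trial records")
  X <- rbind(design_matrix(lapply(records, `[[`, "stimulus")), x)
  y <- vapply(records, function(r) as.numeric(isTRUE(r$correct)), numeric(1))
  ld <- vapply(c(1, 0), function(outcome) {
    fit <- fit_logistic_ridge(X, c(y, outcome), ridge = ridge,
                              coef_init = state$coef_mean)
    log_det_cov(.as_posterior(fit))
  }, numeric(1))
  phat * ld[1] + (1 - phat) * ld[2]
}

# Vectorized fisher-mode criterion over a pool design matrix (one row per
# candidate); used by select_next for speed.  Returns the expected
# log-determinant for every candidate.
fisher_criterion <- function(state, Xpool) {
  eta <- drop(Xpool %*% state$coef_mean)
  phat <- plogis(eta)
  quad <- rowSums((Xpool %*% state$coef_cov) * Xpool)
  log_det_cov(state) - log1p(phat * (1 - phat) * quad)
}
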