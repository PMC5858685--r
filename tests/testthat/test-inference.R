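# Penalized logistic posterior: design rows, fitting, the coefficient <->
# SII-parameter conversion, and the entropy bookkeeping.

test_that("design rows are band audibilities gated by the mask, plus intercept", {
  expect_equal(design_row(stimulus_spec(15, rep(TRUE, 6))), rep(1, 7))
  expect_equal(design_row(stimulus_spec(0, c(TRUE, TRUE, rep(FALSE, 4)))),
               c(0.5, 0.5, 0, 0, 0, 0, 1))
  expect_equal(design_row(stimulus_spec(0, rep(FALSE, 6))), c(rep(0, 6), 1))
  # quiet stimuli force audibility 1 in presented bands
  expect_equal(design_row(stimulus_spec(0, c(TRUE, rep(FALSE, 5)), in_quiet = TRUE)),
               c(1, rep(0, 5), 1))
})

test_that("fit_posterior recovers known coefficients from simulated trials", {
  truth <- c(rep(1, 6), -2.4)
  pool <- build_pool()
  stimuli <- sample_pool_stimuli(pool, 400, seed = 31)
  stream <- qbif:::new_rng_stream(32)
  records <- lapply(stimuli, function(s) {
    p <- plogis(sum(design_row(s) * truth))
    list(stimulus = s, correct = qbif:::with_stream(stream, runif(1) < p))
  })
  post <- fit_posterior(records, ridge = 0.01)
  se <- sqrt(diag(post$coef_cov))
  expect_true(all(abs(post$coef_mean - truth) < 3 * se))
  expect_identical(post$n_trials_fit, 400L)
  # covariance symmetric and positive definite
  expect_lt(max(abs(post$coef_cov - t(post$coef_cov))), 1e-8)
  expect_true(all(eigen(post$coef_cov, symmetric = TRUE)$values > 0))
})

test_that("the ridge penalty keeps separated data finite", {
  pool <- build_pool()
  records <- lapply(sample_pool_stimuli(pool, 30, seed = 7),
                    function(s) list(stimulus = s, correct = TRUE))
  post <- fit_posterior(records, ridge = 0.01)
  expect_true(all(is.finite(post$coef_mean)))
  expect_true(all(eigen(post$coef_cov, symmetric = TRUE)$values > 0))
})

test_that("duplicating every record preserves the MLE and halves the covariance", {
  truth <- c(rep(1, 6), -2.4)
  pool <- build_pool()
  stimuli <- sample_pool_stimuli(pool, 300, seed = 91)
  stream <- qbif:::new_rng_stream(92)
  records <- lapply(stimuli, function(s) {
    p <- plogis(sum(design_row(s) * truth))
    list(stimulus = s, correct = qbif:::with_stream(stream, runif(1) < p))
  })
  single <- fit_posterior(records, ridge = 0)
  doubled <- fit_posterior(c(records, records), ridge = 0)
  expect_equal(doubled$coef_mean, single$coef_mean, tolerance = 1e-6)
  expect_equal(doubled$coef_cov, single$coef_cov / 2, tolerance = 1e-6)
})

test_that("ridge -> 0 converges to the unpenalized ML fit (glm oracle)", {
  pool <- build_pool()
  truth <- c(rep(1, 6), -2.4)
  for (rep_i in 1:50) {
    stimuli <- sample_pool_stimuli(pool, 150, seed = 1000 + rep_i)
    stream <- qbif:::new_rng_stream(2000 + rep_i)
    X <- design_matrix(stimuli)
    y <- vapply(stimuli, function(s) {
      p <- plogis(sum(design_row(s) * truth))
      as.numeric(qbif:::with_stream(stream, runif(1) < p))
    }, numeric(1))
    gfit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    # skip quasi-separated draws where the MLE itself is unstable
    if (any(abs(gfit$coefficients) > 20)) next
    ours <- qbif:::fit_logistic_ridge(X, y, ridge = 1e-10)
    expect_equal(ours$coef, unname(gfit$coefficients), tolerance = 1e-4)
  }
})

test_that("coefficient <-> SII parameter conversion is an exact round trip", {
  # forward construction: c_i = 30 beta w_i, c0 = -beta (15 + SRT)
  est <- to_sii_params(c(rep(1, 6), -2.4))
  expect_equal(est$beta, 0.2)
  expect_equal(est$weights, rep(1 / 6, 6))
  expect_equal(est$srt_db, -3)
  est2 <- to_sii_params(c(2, 0, 0, 0, 0, 0, 0))
  expect_equal(est2$weights, c(1, 0, 0, 0, 0, 0))
  expect_equal(est2$beta, 1 / 15)
  expect_equal(est2$srt_db, -15)
  # random round trips through the forward construction
  set.seed(5)
  for (i in 1:20) {
    w <- runif(6); w <- w / sum(w)
    beta <- runif(1, 0.05, 1); srt <- runif(1, -10, 10)
    coef <- c(30 * beta * w, -beta * (15 + srt))
    back <- to_sii_params(coef)
    expect_equal(back$weights, w)
    expect_equal(back$beta, beta)
    expect_equal(back$srt_db, srt)
  }
  # scaling (c, c0) doubles beta but leaves weights untouched
  coef <- c(1.2, 0.3, 0.8, 0.5, 0.2, 0.6, -1.5)
  expect_equal(to_sii_params(2 * coef)$weights, to_sii_params(coef)$weights)
  expect_equal(to_sii_params(2 * coef)$beta, 2 * to_sii_params(coef)$beta)
  expect_error(to_sii_params(c(rep(-1, 6), 2)), class = "qbif_degenerate_fit_error")
})

test_that("log_det_cov matches direct determinants and eigenvalue sums", {
  mk <- function(cov) structure(list(coef_mean = rep(0, nrow(cov)),
                                     coef_cov = cov, n_trials_fit = 1L),
                                class = "qbif_posterior")
  expect_equal(log_det_cov(mk(diag(7))), 0)
  expect_equal(log_det_cov(mk(diag(2, 7))), 7 * log(2))
  set.seed(8)
  A <- matrix(rnorm(49), 7)
  cov <- crossprod(A) + diag(7)
  expect_equal(log_det_cov(mk(cov)),
               sum(log(eigen(cov, symmetric = TRUE)$values)))
  bad <- diag(7); bad[1, 1] <- -1
  expect_error(log_det_cov(mk(bad)), class = "qbif_numerical_state_error")
})

test_that("fisher-mode expected log-determinant follows the determinant lemma", {
  # identity covariance, p-hat 0.5, ||x||^2 = 4  =>  reduction of exactly ln 2
  state <- structure(list(coef_mean = rep(0, 7), coef_cov = diag(7),
                          n_trials_fit = 1L), class = "qbif_posterior")
  cand <- stimulus_spec(15, c(TRUE, TRUE, TRUE, rep(FALSE, 3)))  # row (1,1,1,0,0,0,1)
  expect_equal(expected_post_logdet(state, candidate = cand, mode = "fisher"),
               log_det_cov(state) - log(2))
  # a stimulus whose only leverage is a tiny-variance intercept is uninformative
  cov <- diag(7) * 1e-8
  state2 <- structure(list(coef_mean = rep(0, 7), coef_cov = cov,
                           n_trials_fit = 1L), class = "qbif_posterior")
  none <- stimulus_spec(0, rep(FALSE, 6))
  red <- log_det_cov(state2) -
    expected_post_logdet(state2, candidate = none, mode = "fisher")
  expect_lt(red, 1e-8)
})

test_that("fisher mode never reports an information loss", {
  pool <- build_pool()
  cb <- logistic_listener(c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1), srt_db = -2,
                          beta = 0.3, seed = 21)
  records <- collect_records(sample_pool_stimuli(pool, 120, seed = 22), cb)
  state <- fit_posterior(records)
  ld <- log_det_cov(state)
  crit <- qbif:::fisher_criterion(state, pool$design)
  expect_true(all(crit <= ld + 1e-12))
})

test_that("fisher mode tracks refit mode over the candidate pool", {
  pool <- build_pool()
  cb <- logistic_listener(c(0.15, 0.25, 0.25, 0.15, 0.1, 0.1), srt_db = -1,
                          beta = 0.25, seed = 51)
  records <- collect_records(sample_pool_stimuli(pool, 200, seed = 52), cb)
  state <- fit_posterior(records)
  ld <- log_det_cov(state)
  rel_gap <- vapply(pool$stimuli, function(s) {
    rf <- expected_post_logdet(state, records, s, mode = "refit")
    fi <- expected_post_logdet(state, candidate = s, mode = "fisher")
    abs((ld - fi) - (ld - rf)) / abs(ld - rf)
  }, numeric(1))
  expect_gte(mean(rel_gap <= 0.10), 0.90)
})

test_that("SRT and weights are recovered from logistic-link listeners", {
  # listeners obeying the fitted model family exactly: median errors must be
  # small even at a few hundred trials
  pool <- build_pool()
  n_sessions <- 100
  srt_err <- numeric(n_sessions)
  w_err <- matrix(NA_real_, n_sessions, 6)
  for (i in seq_len(n_sessions)) {
    set.seed(3000 + i)
    w <- runif(6); w <- w / sum(w)
    srt <- runif(1, -8, 8); beta <- runif(1, 0.1, 0.5)
    cb <- logistic_listener(w, srt, beta, seed = 4000 + i)
    records <- collect_records(sample_pool_stimuli(pool, 500, seed = 5000 + i), cb)
    est <- to_sii_params(fit_posterior(records))
    srt_err[i] <- abs(est$srt_db - srt)
    w_err[i, ] <- abs(est$weights - w)
  }
  expect_lt(median(srt_err), 1)
  expect_true(all(apply(w_err, 2, median) < 0.05))
})

test_that("non-convergence raises a classed error carrying the last iterate", {
  pool <- build_pool()
  records <- lapply(sample_pool_stimuli(pool, 40, seed = 61),
                    function(s) list(stimulus = s, correct = TRUE))
  # unpenalized fit on separated data cannot converge
  err <- tryCatch(fit_posterior(records, ridge = 0, max_iter = 5L),
                  qbif_convergence_error = function(e) e)
  expect_s3_class(err, "qbif_convergence_error")
  expect_true(is.numeric(err$last$coef))
})
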