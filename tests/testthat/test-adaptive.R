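# Pool enumeration, the staged training schedule and its stopping rules,
# one-step-ahead selection, and full adaptive sessions.

test_that("pool enumeration is exact for the default configuration", {
  pool <- build_pool()
  expect_length(pool$stimuli, 280)
  expect_equal(nrow(unique(pool$mask_matrix)), 56)
  counts <- rowSums(pool$mask_matrix)
  expect_true(all(counts >= 2 & counts <= 5))
  # no duplicate (tmr, mask) pairs
  keys <- paste(pool$tmr, apply(pool$mask_matrix, 1, paste, collapse = ""))
  expect_equal(anyDuplicated(keys), 0L)
  # deterministic ordering: TMR-major
  expect_true(all(diff(pool$tmr) >= 0))
})

test_that("pool sizes follow the combinatorics for other configurations", {
  p2 <- build_pool(octave_grid(4), seq(-5, 15, 5), c(2, 3))
  expect_length(p2$stimuli, 50)          # (C(4,2)+C(4,3)) * 5
  p3 <- build_pool(band_grid(), 0, c(6, 6))
  expect_length(p3$stimuli, 1)
  expect_error(build_pool(band_grid(), numeric(0), c(2, 5)), "tmr_grid")
  expect_error(build_pool(band_grid(), 0, c(0, 7)), "presented_range")
})

test_that("training omits each band once in the first phase, in random order", {
  st <- qbif:::new_training_state(band_grid(), stream = qbif:::new_rng_stream(10))
  omitted <- integer(6)
  for (i in 1:6) {
    step <- qbif:::training_next(st)
    st <- step$state
    expect_equal(step$stimulus$tmr_db, 15)
    expect_equal(sum(!step$stimulus$band_mask), 1L)
    omitted[i] <- which(!step$stimulus$band_mask)
    st <- qbif:::training_update(st, TRUE)
  }
  expect_setequal(omitted, 1:6)          # a permutation of the bands
  # then pairs of omitted bands
  step <- qbif:::training_next(st)
  expect_equal(sum(!step$stimulus$band_mask), 2L)
})

test_that("an always-correct listener trains for exactly 51 trials", {
  st <- qbif:::new_training_state(band_grid(), stream = qbif:::new_rng_stream(3))
  n <- 0L
  phases <- integer(0)
  repeat {
    step <- qbif:::training_next(st)
    st <- step$state
    if (is.null(step$stimulus)) break
    n <- n + 1L
    phases <- c(phases, sum(!step$stimulus$band_mask))
    st <- qbif:::training_update(st, TRUE)
    if (st$finished) break
  }
  expect_equal(n, 51L)                   # rule (b): n > 50
  # printed phase lengths: 6 single-omission then 15 pair-omission trials
  expect_equal(sum(phases == 1), 6L)
  expect_equal(sum(phases == 2), 15L)
  expect_equal(sum(phases == 3), 20L)
  expect_equal(sum(phases == 4), 10L)    # truncated by the stopping rule
})

test_that("a sub-65% score after trial 10 stops training", {
  st <- qbif:::new_training_state(band_grid(), stream = qbif:::new_rng_stream(4))
  responses <- c(rep(TRUE, 7), rep(FALSE, 4))  # 7/11 = 0.636 < 0.65 at n = 11
  n <- 0L
  for (r in responses) {
    step <- qbif:::training_next(st)
    st <- step$state
    n <- n + 1L
    st <- qbif:::training_update(st, r)
    if (st$finished) break
  }
  expect_equal(n, 11L)
  expect_true(st$finished)
  # the same score at n = 10 would not have stopped (rule needs n > 10)
  st2 <- qbif:::new_training_state(band_grid(), stream = qbif:::new_rng_stream(4))
  for (r in c(rep(TRUE, 6), rep(FALSE, 4))) {   # 6/10 = 0.6 at n = 10
    step <- qbif:::training_next(st2)
    st2 <- step$state
    st2 <- qbif:::training_update(st2, r)
  }
  expect_false(st2$finished)
})

test_that("select_next agrees with brute-force enumeration of the pool", {
  pool <- build_pool()
  cb <- logistic_listener(c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1), srt_db = 0,
                          beta = 0.2, seed = 71)
  records <- collect_records(sample_pool_stimuli(pool, 80, seed = 72), cb)
  state <- fit_posterior(records)
  for (mode in c("fisher", "refit")) {
    chosen <- select_next(state, pool, records, mode = mode)
    scan <- vapply(pool$stimuli, function(s)
      expected_post_logdet(state, records, s, mode = mode), numeric(1))
    expect_equal(attr(chosen, "criterion"), min(scan), tolerance = 1e-10)
    expect_equal(scan[attr(chosen, "index")], min(scan), tolerance = 1e-10)
  }
})

test_that("a single-stimulus pool is returned as-is", {
  pool <- build_pool(band_grid(), 0, c(6, 6))
  state <- structure(list(coef_mean = rep(0, 7), coef_cov = diag(7),
                          n_trials_fit = 1L), class = "qbif_posterior")
  expect_equal(select_next(state, pool, mode = "fisher")$band_mask, rep(TRUE, 6))
})

test_that("selection seeks out the band with inflated uncertainty", {
  pool <- build_pool()
  target_band <- 4L
  cov <- diag(c(rep(1e-4, 6), 1e-4))
  cov[target_band, target_band] <- 1e-2   # 100x the others
  state <- structure(list(coef_mean = c(rep(1, 6), -2.4), coef_cov = cov,
                          n_trials_fit = 100L), class = "qbif_posterior")
  hits <- 0L
  for (i in 1:100) {
    s <- select_next(state, pool, mode = "fisher",
                     stream = qbif:::new_rng_stream(900 + i))
    if (s$band_mask[target_band]) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("full sessions recover a logistic-link listener's weights", {
  w <- c(0.05, 0.3, 0.25, 0.2, 0.15, 0.05)
  cb <- logistic_listener(w, srt_db = -2, beta = 0.2, seed = 81)
  cfg <- qbif_config(n_trials = 500, mode = "fisher", seed = 81)
  sess <- run_qbif(cb, cfg)
  expect_lt(sqrt(mean((sess$final$weights - w)^2)), 0.05)
  # every presented stimulus after training belongs to the pool
  pool <- build_pool()
  keys <- paste(pool$tmr, apply(pool$mask_matrix, 1, function(r)
    paste(as.integer(r), collapse = "")))
  adaptive <- sess$trials[sess$trials$phase == "adaptive", ]
  expect_true(all(paste(adaptive$tmr_db, adaptive$mask) %in% keys))
  # every training stimulus is at 15 dB with 1-4 omitted bands
  training <- sess$trials[sess$trials$phase == "training", ]
  expect_true(all(training$tmr_db == 15))
  omitted <- 6 - nchar(gsub("0", "", training$mask))
  expect_true(all(omitted >= 1 & omitted <= 4))
})

test_that("selected stimuli concentrate near 50% predicted correct", {
  l <- sample_listener(seed = 19)
  sess <- run_qbif(l, qbif_config(n_trials = 500, mode = "fisher", seed = 19))
  expect_gt(mean(tail(sess$trials$phat, 200)), 0.4)
  expect_lt(mean(tail(sess$trials$phat, 200)), 0.6)
})

test_that("posterior entropy is non-increasing across adaptive refits", {
  l <- sample_listener(seed = 23)
  sess <- run_qbif(l, qbif_config(n_trials = 300, mode = "fisher", seed = 23))
  lndet <- sess$trials$lndet[sess$trials$phase == "adaptive"]
  expect_true(all(diff(lndet) <= 1e-6))
})

test_that("a budget equal to the training length leaves no adaptive trials", {
  cb <- function(stimulus) TRUE
  sess <- run_qbif(cb, qbif_config(n_trials = 20, mode = "fisher", seed = 5))
  expect_equal(sess$n_adaptive, 0L)
  expect_equal(sess$n_training, 20L)
})

test_that("sessions are reproducible given the seed", {
  l <- sample_listener(seed = 13)
  cfg <- qbif_config(n_trials = 120, mode = "fisher", seed = 13)
  s1 <- run_qbif(l, cfg)
  s2 <- run_qbif(l, cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$final$weights, s2$final$weights)
})

test_that("callback failures abort with a partial-result error", {
  flaky <- local({
    k <- 0L
    function(stimulus) {
      k <<- k + 1L
      if (k >= 8L) stop("listener left the booth")
      TRUE
    }
  })
  err <- tryCatch(run_qbif(flaky, qbif_config(n_trials = 50, seed = 2)),
                  qbif_partial_result_error = function(e) e)
  expect_s3_class(err, "qbif_partial_result_error")
  expect_length(err$records, 7L)
})

test_that("refit mode runs a short session end to end", {
  cb <- logistic_listener(rep(1 / 6, 6), srt_db = 0, beta = 0.2, seed = 41)
  sess <- run_qbif(cb, qbif_config(n_trials = 25, mode = "refit", seed = 41))
  expect_equal(length(sess$records), 25L)
  expect_equal(sess$n_training + sess$n_adaptive, 25L)
})
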