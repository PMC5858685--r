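# qbif

Quick estimation of individualized band importance functions under the
Speech Intelligibility Index (SII) framework.

## The problem

The SII predicts speech understanding as a weighted sum of per-frequency-band
audibilities,

    SII = sum_i w_i * n_i * A_i ,

where the weights `w_i` (the *band importance function*, summing to 1) say
how much each band contributes to intelligibility, `n_i` switches bands in
or out of the stimulus, and `A_i = (clamp(TMR, -15, 15) + 15) / 30` maps the
band's target-to-masker ratio onto [0, 1].  Recognition probability follows
a logistic link,

    p = 1 / (1 + exp(-beta * (30*SII - 15 - SRT))) ,

with the speech recognition threshold (SRT, dB) and slope `beta`.  Classical
estimates of `w_i` need thousands of trials pooled over listeners; this
package implements a Bayesian adaptive procedure that estimates the weights,
SRT and slope for an *individual* listener in a few hundred trials.  The key
ideas:

* **Reparameterization.** With `c_i = 30*beta*w_i` and
  `c0 = -beta*(15 + SRT)` the model is an ordinary logistic regression on
  masked band audibilities, refitted (with a small ridge penalty) after
  every trial.
* **Entropy-minimizing stimulus selection.** Each next stimulus -- a TMR
  from {-5..15} dB and a 2-to-5-band subset of six octave bands, 280
  candidates -- is chosen to minimize the expected log-determinant of the
  posterior covariance after the upcoming response (exact refit mode, or a
  fast matrix-determinant-lemma approximation for bulk simulation).
* **A staged training block** (single, pair, triple, quadruple band
  omissions at 15 dB TMR with published stopping rules) seeds the
  regression before adaptation activates.

The package is aimed at hearing scientists and psychoacousticians: it
contains the full adaptive engine, offline refitting of trial logs, the
Compound and Random baseline sampling strategies, simulated listeners
driven by the classical asymmetric transfer function
`p = (1 - 10^(-SII*P/Q))^N` for validation studies, and the audio signal
chain (TMR mixing, 12th-order Butterworth octave filterbank, band-subset
reconstruction, WAV I/O).

## Worked example

Simulate a listener (asymmetric link, randomly drawn weights), run a
500-trial adaptive session, and compare the recovered weights to the truth:

```r
library(qbif)
listener <- sample_listener(seed = 3)
print(listener)
#> Simulated listener: 6 bands
#>   weights: 0.058 0.279 0.133 0.113 0.208 0.209
#>   P = 1, Q = 0.237, N = 4.95

sess <- run_qbif(listener, qbif_config(n_trials = 500, mode = "fisher", seed = 3))
print(sess)
#> qBIF session: 500 trials ( 51 training, 449 adaptive )
#>   weights: 0.072 0.326 0.123 0.127 0.155 0.197
#>   SRT: -8.88 dB   beta: 0.532
#>   percent correct: 64.4%

normalized_rmse(sess$final$weights, listener$weights)
#> [1] 0.0308
spectral_centroid(sess$final$weights)
#> [1] 0.559
```

The recovered weight profile tracks the truth to a normalized RMS error of
0.031 -- about half a percentage point of weight per octave -- even though
the listener's response function is not the logistic family being fitted.
The spectral centroid (weight-averaged octave offset from 1 kHz) summarizes
where the listener concentrates information.

Results can be serialized (`write_results()` writes a JSON-lines trial log,
estimate JSON and metrics CSV with a hash manifest) and refitted offline
with `fit_posterior()` / `to_sii_params()`.  A thin command-line front end
lives at `inst/cli/qbif.R` (subcommands `run`, `fit`, `pool`, `schedule`,
`replicate-fig2`, `stimgen`).

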