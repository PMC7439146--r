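# sleephmm

Personalized, unsupervised sleep/wake scoring from consumer wearable
data. Given a wearer's minute-level heart rate and 15-minute step
counts, `sleephmm` fits a two-state hidden Markov model to *that
wearer's own data* — no polysomnography labels, no population training
set — decodes a per-minute sleep/wake sequence, and post-processes it
with the Webster rescoring rules. It is aimed at researchers doing
longitudinal, free-living sleep monitoring with consumer trackers, where
labelled ground truth is unobtainable and interindividual variability
makes one-size-fits-all scorers unreliable.

## The model

Observed minutes are bivariate, **x**_t = (x_t^HR, x_t^ACT), with
x^ACT = log(x^STEP + 1) and the 15-minute step totals evenly downscaled
to minutes (U^STEP/15 each, totals preserved). A hidden two-state chain
z_t with initial distribution π and transition matrix Γ, γ_ij =
P(z_{t+1} = s_j | z_t = s_i), emits from state-conditional Gaussians:

* scheme **M1** — joint bivariate normal with per-state correlation ρ_i
  (13 free parameters);
* scheme **M2** — conditional independence, the product of the marginal
  normals (11 free parameters);
* `HR_ONLY` / `ACT_ONLY` — univariate comparison models (7 each).

The likelihood is evaluated with the scaled forward algorithm (minutes
with missing data contribute the observed channel's marginal density, or
density 1 if fully missing), maximized by Baum–Welch EM, compared across
schemes by AIC/BIC, decoded with the Viterbi algorithm, and checked with
ordinary normal pseudo-residuals. The state with higher mean heart rate
and activity is wake. Per-day refits with weekday/weekend t tests and a
device-realistic synthetic data generator round out the toolkit.

## Worked example

Simulate a two-week device-format study from a reference wearer profile,
screen nonwear days, fit both emission schemes, pick the better one, and
score sleep:

```r
library(sleephmm)

profile <- participant_profile(example_profiles()$older_adult_1$params,
                               n_days = 14, nonwear_prob = 0.1)
study <- simulate_recording(profile, seed = 42)

nonwear <- detect_nonwear_days(study$recording)
epochs  <- build_epoch_series(study$recording, nonwear)
fits    <- list(fit_hmm(epochs, "M1", seed = 1),
                fit_hmm(epochs, "M2", seed = 1))
best    <- select_model(fits)   # AIC, with the BIC ranking attached
print(best)
```

```
Two-state sleep/wake HMM fit (scheme M1)
  log L = -78926.1  df = 13  AIC = 157878.1  BIC = 157979.0  T = 17280
  29 iterations, converged: TRUE
Two-state HMM parameters
  pi:     0.0000 1.0000
  Gamma:  0.9830 0.0170
          0.0061 0.9939
             state1   state2
mu_hr       74.5428 106.4998
sigma2_hr  158.6286 328.2216
mu_act       0.3418   3.1804
sigma2_act   0.0139   0.2752
rho          0.0396   0.4060
```

Two of fourteen days were screened out as nonwear, leaving 17,280
minutes. State 1 (sleep) idles near 74.5 bpm with essentially no
movement; state 2 (wake) runs near 106.5 bpm with high, variable
activity and a within-state heart-rate/activity correlation of 0.41.
The rows of Γ say a sleeping minute stays sleep with probability 0.983
and a waking minute stays wake with 0.994 — sleep/wake bouts are long,
which is exactly why a Markov model beats minute-by-minute
thresholding. AIC and BIC both prefer the correlated scheme M1 here.

```r
scored <- score_series(best, epochs)          # Viterbi + Webster rules
tst    <- total_sleep_time(scored, "22:00", "06:30")
head(tst, 3)
```

```
       night sleep_minutes minutes_present window_minutes complete
1 2018-01-01            89             510            510     TRUE
2 2018-01-02           126             510            510     TRUE
3 2018-01-03           149             510            510     TRUE
```

Nightly totals count rescored sleep minutes inside the habitual bedtime
window (here 22:00–06:30; this simulated chain sleeps in bouts around
the clock, so its in-window totals are modest). Against the generator's
hidden states the final scoring agrees on 88.1% of minutes — the
15-minute step granularity blurs state transitions, a limitation
discussed in the methods vignette (`vignettes/sleep-wake-hmm.Rmd`).

A thin command-line wrapper over these functions ships in
`inst/cli/sleephmm` (subcommands `preprocess`, `fit`, `score`, `tst`,
`daily`, `simulate`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference
simulation-and-refit quantities from scratch: it simulates 100,000
minutes from each of the two shipped reference parameter sets, refits
scheme M1 by EM with 5 restarts under 20 seeds, and writes the median
recovered parameters (wake mean heart rate, per-state heart-rate
variances, wake-to-sleep transition probability, wake correlation) as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
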