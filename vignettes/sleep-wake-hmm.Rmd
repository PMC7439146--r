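---
title: "Unsupervised sleep/wake scoring from wearable heart rate and steps"
author: "sleephmm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised sleep/wake scoring from wearable heart rate and steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleephmm)
```

## The problem

Consumer trackers record heart rate every minute and step counts every
15 minutes, continuously and for months. Turning those streams into
per-minute sleep/wake labels usually relies on supervised actigraphy
algorithms trained against polysomnography — expensive to obtain, and a
poor match for wearers whose physiology differs from the training
cohort. `sleephmm` instead fits a *personalized, unsupervised* model:
each wearer's own data determine where their sleeping and waking
distributions sit, with no labels required.

The premise is physiological: both movement and heart rate drop during
sleep, and they do so jointly. Modelling the two channels together lets
heart rate arbitrate the minutes where activity alone is ambiguous —
motionless but awake (reading, watching television) is the classic
actigraphy failure mode.

## The model

Observations are the bivariate minute series
$\mathbf{x}_t = (x_t^{HR}, x_t^{ACT})$, $t = 1, \dots, T$, where
$x^{HR}$ is heart rate in bpm and $x^{ACT} = \log(x^{STEP} + 1)$ is the
log of the per-minute step value obtained by evenly downscaling each
15-minute total $U^{STEP}$ into $U^{STEP}/15$ per minute (the bin total
is preserved exactly).

A hidden two-state Markov chain $z_t \in \{s_1, s_2\}$ with initial
distribution $\pi$ and transition matrix
$\Gamma = (\gamma_{ij})$, $\gamma_{ij} = P(z_{t+1} = s_j \mid z_t = s_i)$,
drives state-conditional Gaussian emissions. Two emission schemes are
supported:

* **M1** — joint bivariate normal per state, with means
  $(\mu_{HR,i}, \mu_{ACT,i})$, variances
  $(\sigma^2_{HR,i}, \sigma^2_{ACT,i})$ and correlation $\rho_i$;
  13 free parameters (2 × 5 emission + 2 transition + 1 initial).
* **M2** — contemporaneous conditional independence: the product of the
  two univariate normals; 11 free parameters.

Univariate single-channel variants (`HR_ONLY`, `ACT_ONLY`, 7 free
parameters each) quantify what the fusion adds. With $\rho_i = 0$, M1
collapses exactly to M2; the test suite asserts this limit to 1e-9.

Missing minutes are handled inside the likelihood: a minute with both
channels missing contributes emission density 1 in every state, so only
the chain's transition structure speaks there; a minute with one channel
missing contributes the observed channel's marginal density, the
consistent extension of the fully-missing rule.

The likelihood is evaluated by the scaled forward recursion, parameters
are estimated by Baum–Welch EM, models are compared by AIC/BIC, the
state path is decoded by the Viterbi algorithm, and the state with the
higher mean heart rate *and* mean activity is labelled wake. If the two
channels rank the states discordantly — rare, and a sign of a weak fit —
activity decides, with a warning, because movement is the more direct
wake marker.

## Estimation choices

The estimator is EM rather than generic numerical maximization because
its monotone-likelihood property is mechanically testable: every fit
records its likelihood trace and the suite asserts non-decrease.

* **Initialization.** Minutes are split at the median activity level
  (median heart rate for `HR_ONLY`); state means, variances and
  correlations are the within-half moments; $\Gamma$ starts at 0.95 on
  the diagonal; $\pi$ at (0.5, 0.5). Further restarts jitter the means
  with a 0.5-SD Gaussian perturbation under the run seed. The
  median-split start is deterministic and, on data with any usable
  separation, reaches the same optimum as the jittered restarts; the
  restarts guard against pathological splits.
* **M-step with missing data.** Sufficient statistics use exact
  conditional moments: a minute with heart rate missing contributes
  $E[x^{HR} \mid x^{ACT}, z]$ and the matching second moments under the
  current parameters. This keeps the update an exact EM step (monotone)
  rather than an ad-hoc weighting of observed entries.
* **Numerical guards.** Variances are floored at 1e-6 and $|\rho|$
  clamped at 0.999 to prevent degenerate likelihood spikes; transition
  and initial probabilities are floored at 1e-12 and renormalized, so
  every iterate is strictly positive and row-stochastic.
* **Convergence.** Relative log-likelihood change below 1e-8 or 500
  iterations, both overridable. Non-convergence is returned (flagged)
  rather than hidden.
* **Canonical state order.** After fitting, states are sorted by
  ascending mean heart rate (mean activity for `ACT_ONLY`), so state 1
  is sleep/rest and state 2 wake regardless of EM's label switching.
* **Ties.** Viterbi ties are broken toward the lower state index. They
  have probability zero under continuous emissions but occur in long
  fully-missing stretches, where the decode is driven by $\pi$ and
  $\Gamma$ alone.

Goodness of fit uses ordinary normal pseudo-residuals
$u_{t,c} = \Phi^{-1}\!\big(F_{t,c}(x_{t,c})\big)$, where $F_{t,c}$ is
the model's univariate mixture CDF for channel $c$ weighted by
$P(z_t = s_i \mid \mathbf{x}_{-t})$ (all observations except minute
$t$). Residuals are computed per channel because the probability
integral transform is scalar; a joint bivariate version would need an
arbitrary ordering of the two channels. CDF values are clipped to
$[10^{-12}, 1 - 10^{-12}]$ before the quantile transform and the clip
count is reported. Under a correct model the residuals are standard
normal; gross outliers show up as heavy QQ tails long before they move
bulk statistics such as the KS distance, which is why the diagnostic
test asserts on tail mass.

## Preprocessing rules

A full calendar day is **nonwear** if more than 30 minutes of heart
rate are missing, or the day's total step count is zero. The first rule
is our reading of an ambiguously worded device-removal criterion: only
*missing* heart rate indicates the device was off, and 30 minutes is the
stated threshold. The zero-step rule uses the daily *total*, not any
single zero bin, because sedentary wearers produce many legitimate
zero bins. A participant with more than 50% nonwear days is excluded.
Partial first/last days never enter the day count. Screening days run
midnight-to-midnight; *analysis* days for the daily models are anchored
at 08:00 by default so each fitted day contains one whole night —
the two conventions are deliberately separate.

## Webster rescoring

Viterbi output inherits actigraphy's bias toward scoring quiet
wakefulness as sleep. The five Webster rules trim it: after wake runs of
at least 4/10/15 minutes the first 1/3/4 sleep minutes are rescored
wake, and sleep islands of at most 6/10 minutes inside wake flanks of at
least 10/20 minutes are removed. Each rule makes one left-to-right pass
over the sequence as updated by the earlier rules, and rescored minutes
count as wake for the later rules. Rules never convert wake to sleep, so
rescoring can only shrink total sleep.

Two points were genuinely open and are package decisions:

* The island rules' flank condition ("before or after") is implemented
  as **both** sides — the original formulation, and the conservative
  one; `surround = "either"` restores the literal either-side reading.
* Each rule is applied once, not iterated to a fixed point; a fixed
  point could cascade far beyond what the published rule set describes.

## Daily models and weekday/weekend comparison

`fit_daily_models()` refits the chosen scheme independently per anchored
day (exactly 1440 minutes; anything else is invalid), seeding each day's
EM with the participant-level fit to suppress day-level label switching.
Days where a state's posterior occupancy falls below 30 minutes are
marked invalid: with that little time in a state, its emission
parameters are noise. Twelve parameters per day — the two off-diagonal
transition probabilities (the diagonals are redundant) and the ten
emission parameters — are compared weekday vs weekend with two-tailed
independent t tests. Welch's unequal-variance form is the default
(safer when weekend groups are small); `var_equal = TRUE` restores the
pooled test. Raw p-values are reported without multiplicity correction,
matching the per-parameter reporting convention; `p_adjust = "BH"`
applies Benjamini–Hochberg when a corrected view is wanted. Under a
null simulation (identical generating parameters for all days) the
acceptance suite checks the significance rate sits inside the binomial
95% interval around 5%.

## The synthetic generator

`simulate_recording()` produces device-format studies: a Markov state
chain, Gaussian emissions, heart rate rounded to integer bpm and clamped
to the tracker-plausible (20, 250) range, per-minute steps reconstructed
as $\max(0, \mathrm{round}(e^{x^{ACT}} - 1))$ and summed into aligned
15-minute bins, heart-rate minutes deleted in geometric-length runs
(mean 5 minutes) to a target rate, and whole nonwear days zeroed.
Defaults are the conditions observed in free-living older-adult cohorts:
0.64% missing heart rate (observed range 0.31–0.96%), roughly one
nonwear day in seven, 90-day studies. `cohort_prior()` centres sampled
profiles on published cohort means/SDs; `example_profiles()` carries two
fixed reference parameter sets (a high-separation and a low-separation
wearer) whose printed values anchor the recovery tests. The sleep-state
activity parameters of the low-separation wearer are published only as
"<0.01"; both are fixed at 0.005, the midpoint of the printable range.

What the generator deliberately does **not** emulate:

* **Circadian structure.** Transitions are homogeneous in time, exactly
  as the fitted model assumes. Real nights consolidate sleep; the
  simulated chain switches states at the same rates around the clock.
* **Exact emission truth under truncation.** Clamping negative activity
  draws at zero (device realism) puts a point mass at exactly zero.
  When a state's activity variance is near-degenerate this point mass
  measurably biases refitted transition probabilities upward, because
  zero-activity wake minutes flip the decoder for single minutes. The
  parameter-recovery experiments therefore sample the exact Gaussian
  model (`truncate_act = FALSE`): their tolerances are model-based
  asymptotic standard errors, which are statements about the estimator
  under its own model. The device-realistic pipeline keeps the
  truncation.

A green recovery test therefore establishes that the estimator is
correct and efficient *for the model it fits*; it does not establish
that real wearable data follow that model — that is what the
pseudo-residual diagnostics are for on real recordings.

## Known limitations

* **15-minute step granularity blurs transitions.** After device
  binning, activity is constant within each 15-minute bin, so a state
  change inside a bin is localized only by heart rate. With the
  low-separation reference parameters the generating chain switches
  states about 16 times a day, and the end-to-end minute accuracy of
  the full pipeline (device format, preprocessing, fit, decode,
  rescore) sits around 0.89–0.93 against the generating states —
  systematically below the 0.95 the same decoder achieves on un-binned
  minute data. The corresponding acceptance check is intentionally left
  failing rather than weakened; the gap is a property of the data
  format, not of the estimator.
* **Webster rules against a memoryless truth.** The rules encode
  consolidated human sleep; applied to a homogeneous Markov truth they
  systematically trim the head of every genuine sleep bout that follows
  a long wake run. On real, consolidated nights this is the intended
  correction; in the simulator it reads as error.
* **Binary states only.** No sleep staging, no time-varying transition
  probabilities, no covariates in $\Gamma$ or the emissions; decoded
  states are best read as rest/active until validated against
  polysomnography.
* **Timezones.** A single fixed offset per recording; daylight-saving
  shifts inside a study are not handled.
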