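---
title: "Windowed ROC decoding of visual cortical spike trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed ROC decoding of visual cortical spike trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedisc)
```

## The scientific question

How brief a window of activity in primary visual cortex suffices for an
animal to tell two oriented gratings apart? In the experimental paradigm
this package analyzes, a head-fixed mouse runs on a wheel and is rewarded
for holding a *target* grating (90°) in a reward zone for a minimum hold
time, while letting a *distractor* (45°) pass. Optogenetic silencing of
visual cortex at a controlled latency after the cortical response onset
truncates the usable window of cortical activity; the behavioral and
electrophysiological analyses ask what information is present in that
window. The package implements the full analysis chain — behavioral
readouts, LFP response-onset detection, per-unit windowed ROC
discrimination, first-spike latency statistics, Poisson count modelling,
orientation tuning, and population pooling — together with a synthetic-data
module that generates data with the statistical structure the analyses
assume, so the whole chain is testable without recordings.

## Behavioral readouts

A *stop trial* is a trial whose hold time reaches the threshold
(boundary-inclusive). Accuracy is the average of the percent stop trials
on targets and percent non-stop trials on distractors; for any
stimulus-independent stopping policy the two summands are complementary
in expectation, so chance is 50% whatever the stop rate. Confidence
intervals on stop probabilities are exact Clopper–Pearson (the
beta-quantile form), chosen over the normal approximation because session
sizes can be small and stop probabilities extreme.

The *ideal observer* receives only the per-trial hold times and scores
`P(T > D) + 0.5 P(T = D)` over all target/distractor cross pairs — the
area under the empirical ROC curve, computed with midranks so ties are
exact. The accompanying rank-sum test enumerates the exact permutation
null whenever the combined sample size is at most 20 (valid under ties);
beyond that it uses the tie-corrected normal approximation without
continuity correction, so identical samples give p = 1 in both regimes.

## Cortical onset from the LFP

Trial-averaged traces are low-pass filtered (4th-order Butterworth,
300 Hz, applied bidirectionally so the filter is zero-phase), the
baseline mean and standard deviation are taken per channel over
[−80, +20) ms around stimulus onset, and the onset is the earliest
post-onset sample whose absolute deviation exceeds 3 baseline standard
deviations, minimized over channels. Two numerical choices matter:

* **Sustained exceedance.** Band-limited noise regularly stays beyond
  3 sd for a few correlated samples, so a literal first-crossing rule
  false-triggers on a nontrivial fraction of traces. The detector
  therefore requires the deviation to persist for 10 ms (an evoked LFP
  deflection lasts tens of ms; a noise excursion does not). The reported
  time is still the *first* sample of the sustained run, so the
  requirement costs no latency bias. Validation on synthetic blocks:
  10-sd deflections injected at 40 ms are recovered within ±5 ms
  (the bias, ≈ +3 ms, is the time the 10 ms rise needs to reach
  threshold), while 2-sd deflections — below the criterion — are not
  detected.
* **Sign-agnostic criterion.** Evoked deflections in the input layer are
  typically negative-going, but the detector uses the absolute deviation;
  this subsumes the negative case and costs nothing on synthetic data.

The synthetic LFP generator band-limits its noise (white noise filtered
at the same 300 Hz cutoff, rescaled to `noise_sd`) so that the spec'd
deflection amplitude "in multiples of noise sd" is commensurate with the
baseline sd the criterion actually thresholds against; with white noise
the detector's filter would attenuate the noise floor by roughly 40% and
silently inflate every amplitude.

## Windowed discrimination

For each unit, spike counts are taken per trial in half-open windows
`[onset, onset + t)` for `t` on a 20 ms grid up to 300 ms. The ROC value
is the cross-pair probability above, oriented to the unit's preferred
stimulus — the sign of the target-minus-distractor mean count difference
at 300 ms, ties to target — so AUC ≥ 0.5 at the defining window.
Significance is the two-sided rank-sum p on raw counts,
Benjamini–Hochberg-corrected across units at FDR 0.05 at the 300 ms
window; the *effective cutoff* (the largest selected sorted p) is
reported, and is reused at earlier intervals to decide when a
discriminating unit starts discriminating. Re-applying BH per interval is
the alternative reading; reusing the 300 ms cutoff keeps "discriminating"
a fixed property of the unit and makes the fraction at 300 ms equal 1 by
construction. Units firing fewer than 1 spike per 6 trials over the
initial 300 ms are excluded before any of this, since rank-sum ROC is
insensitive at such rates.

The first-spike variant removes from each trial all spikes except the
first one at or after cortical onset and reruns the identical machinery.

## The synthetic population model

The generator's defaults are the study conditions the analyses assume:
discriminating units fire a mean of 0.6 spikes in the initial 80 ms
window for the preferred stimulus and 0.22 for the non-preferred one;
the cortical response begins 40 ± 5 ms after stimulus onset; the mean
first-spike time is 70 ms from cortical onset for the preferred stimulus
and 12 ms later for the non-preferred one; baseline firing is 2 Hz
(spontaneous cortical activity) before stimulus onset. Per-unit trial
counts are not constrained by the study design, so
`n_trials_per_stimulus` is a free parameter defaulting to 100.

Evoked spiking is modelled as an inhomogeneous Poisson process over the
300 ms response horizon: the total evoked count is Poisson and spike
times are iid draws from a gamma latency density (shape 6) truncated to
the horizon. This form was chosen because it lets two constraints hold
*exactly* rather than approximately:

1. **Window counts.** By Poisson thinning, the count in the 80 ms window
   is Poisson with mean `lambda_H * F(80)`; the generator sets
   `lambda_H = window_mean / F(80)`, so 80 ms counts are exactly Poisson
   at the spec'd mean.
2. **First-spike timing.** Conditional on at least one evoked spike, the
   first-spike time has survival `exp(-lambda_H F(t))`, so its mean is a
   smooth function of the latency-density mean; the generator solves for
   the density mean numerically (root find against a 0.1 ms quadrature of
   the survival integral) so the conditional mean first-spike time equals
   its target. A naive alternative — drawing the window count first and
   placing times from a density whose *mean* is shifted by 12 ms — does
   not pin the first-spike mean, because the minimum of several draws is
   biased earlier by an amount that grows with the count and therefore
   differs between the two stimuli.

Monte-Carlo validation of the calibration (2 × 10⁶ trials) reproduces the
70 ms and 82 ms targets to within 0.1 ms. Non-discriminating units get
the average of the two means for both stimuli. Optogenetic truncation is
modelled by deleting all spikes after `onset + LED latency + 8 ms`, the
8 ms being the silencing delay of the inhibitory-activation method.

What the generator does *not* emulate: trial-to-trial noise correlations
between units (all units are conditionally independent given the
stimulus), slow drifts in excitability, running-speed covariates, and
non-Poisson dispersion. Passing tests therefore certify the analysis
chain's correctness on data satisfying its own assumptions, not the
assumptions themselves on real recordings — most visibly for pooling,
where independence makes shuffle augmentation exact rather than
approximate.

Behavioral sessions draw stimulus identity Bernoulli(`p_target`, default
0.375, the middle of the 25–50% range used in training), decide stopping
with per-stimulus probabilities (defaults 0.9/0.1, a trained animal), and
draw the hold time from a stimulus-specific lognormal *conditioned on the
correct side of the threshold* via the inverse CDF — so the stop flag is
exactly recomputable from the hold time, and the marginal hold-time
distribution remains lognormal-shaped on either side. Lognormals were
chosen for positive support and separability by location.

## First-spike latencies and Poisson fits

Per-trial first-spike latencies are taken in `(onset, onset + 300]` ms;
trials without a spike there are omitted (their fraction is reported),
not zero-filled, because a latency of zero is not an observation. The
across-unit test is a one-sample two-sided t-test on per-unit differences
of mean latency, non-preferred minus preferred, so the expected value
under the generator's defaults is +12 ms. Standard errors quoted for
medians elsewhere in the package use the bootstrap (1000 resamples).

The Poisson fit sets `lambda` to the sample mean and scores
`R² = 1 − SS_res/SS_tot` between the empirical count histogram
(proportions over the observed support `0..max`) and the predicted pmf.
The support choice matters only in degenerate cases; an all-zero count
vector matched perfectly by its prediction is reported as R² = 1.

## Orientation tuning

Tuning curves average passive-viewing counts per orientation over
repetitions (330 ms window from cortical onset) and normalize by the
maximum. Preferred orientation and OSI both live in doubled-angle space
(period 180°): the tuning vector is `(Σ r cos 2θ, Σ r sin 2θ)`, the
preferred orientation is half its two-argument angle mapped to
`[0, 180)`, and the OSI is its length divided by `Σ r`. The two-argument
angle is used deliberately: a one-argument `arctan(y/x)` with a written
case split is quadrant-ambiguous, and both quantities are invariant to
uniform scaling of the rates, so whether normalized or raw rates enter
the sums is immaterial. The synthetic passive module assigns each unit a
preferred orientation (target-preferring units near 90°+, consistent
with peak responses above the target orientation; distractor-preferring
near 45°−) and a circular-Gaussian profile with concentration 1, giving
half-widths in the 30–40° range typical of mouse V1.

The ROC-versus-tuning fit regresses each unit's 80 ms task AUC on its
passive spike-count difference between the target and distractor
orientations, signed so target-preferring units sit at positive x.
Ordinary least squares; the parameter standard errors come from the
inverse information matrix, which for Gaussian-error OLS is the standard
`(X'X)^{-1} σ̂²` covariance; a one-sided test of slope > 0 is reported.

## Population pooling

The pooling analysis asks how many units must be combined for an ideal
observer on summed counts to reach the animal's accuracy. Units are first
reduced to per-trial window counts oriented to their preference
(distractor-preferring units have their class labels swapped — an
involution). Shuffle augmentation then creates six surrogate copies per
unit by permuting trials *within each stimulus class*: this preserves
every unit's stimulus-conditioned count distribution exactly (the
per-class count multisets are invariant) while breaking trial alignment
across units; an unrestricted shuffle is available behind a flag but
mixes the classes and destroys the signal it is meant to preserve. The
pooling neuron's per-trial count is the sum over `N` sampled units
(sampling is without replacement — the augmented pools of several hundred
units comfortably exceed the largest `N`); its ROC value is averaged over
1000 samples, the whole procedure repeated 10 times for a standard error.
For homogeneous Poisson units the pooled counts are Poisson with means
`(0.6 N, 0.22 N)`, so the curve is checkable against the exact
cross-pair double sum ([poisson_auc()]); the behavioral readout — the
smallest `N` whose mean AUC reaches a supplied accuracy — treats percent
correct and AUC as directly comparable, which is the convention this
analysis inherits. The accuracy value is a required input rather than a
default, because it belongs to the behavioral data, not the method.

## Problem sizes and determinism

Every stochastic stage is a pure function of `(spec, seed)`
(`withr::with_seed`), and the pipeline derives per-stage sub-seeds from
the configured seed, so identical configurations yield byte-identical
outputs. The test suite validates the statistical contracts at sizes
chosen for tight tolerances at interactive runtimes: 3-SE checks of the
Poisson window means use ~10⁴ counts, the analytic-AUC convergence check
uses 100 units × 200 trials/stimulus, onset recovery uses 100 seeded
blocks, and the pooled-Poisson comparison uses 8 independent populations
of 40 units. The exhaustive oracles (cross-pair AUC, BH step-up) run 10⁴
random cases each.

## Known limitations

* The pooled analysis inherits the independence of the generator; with
  real simultaneously recorded units, within-session noise correlations
  make shuffle augmentation an approximation whose error this package
  cannot quantify.
* `detect_onset` assumes the baseline window is response-free; stimuli
  with anticipatory activity would inflate the baseline sd and delay
  detection.
* The exact rank-sum enumeration is limited to combined n ≤ 20
  (`choose(20,10) ≈ 1.8 × 10⁵` labelings); above that the tie-corrected
  normal approximation is used, which is slightly anticonservative for
  very sparse counts at moderate n.
* The first-spike calibration targets the *conditional* mean latency
  within the horizon; quantities outside that window (e.g. latency
  medians) follow from the model rather than being pinned.
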