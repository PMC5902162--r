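# spikedisc

Spike-train and behavioral analysis of rapid visual discrimination: how
brief a window of visual cortical activity carries enough information to
tell a rewarded *target* grating (90°) from an unrewarded *distractor*
(45°), and what single neurons fire within that window.

The package is aimed at systems neuroscientists analyzing trial-aligned
extracellular recordings from a go/no-go ("stop"/"non-stop") visual
foraging task. It provides, as composable functions plus a one-call
pipeline:

* **Behavior** — stop classification (`hold time ≥ threshold`), choice
  accuracy (average of percent stops on targets and percent non-stops on
  distractors; chance 50%), exact Clopper–Pearson 95% CIs, rank-sum
  choice tests, and a hold-time ideal-observer ROC.
* **Cortical onset** — zero-phase 300 Hz Butterworth filtering of
  trial-averaged LFP traces and detection of the earliest sustained
  deviation exceeding 3 baseline SDs (baseline [−80, +20) ms).
* **Windowed ROC discrimination** — per unit and interval `t`, the area
  under the ROC curve for target vs distractor spike counts in
  `[onset, onset + t)`,

  `AUC = P(C_pref > C_non) + ½ P(C_pref = C_non)`,

  with rank-sum significance, Benjamini–Hochberg correction across units
  at the 300 ms window (effective cutoff reported and reused at earlier
  intervals), a low-rate exclusion filter (< 1 spike per 6 trials over
  300 ms), and a first-spike-only variant.
* **Spike statistics** — first-spike latencies in (0, 300] ms from onset,
  the across-unit paired latency-difference t-test, Poisson fits to count
  histograms (`λ` = sample mean, R² on the pmf), PSTHs, count→rate
  conversion.
* **Tuning** — orientation tuning curves, preferred orientation
  `½·atan2(Σr sin 2θ, Σr cos 2θ)` and OSI (doubled-angle vector
  strength), receptive-field center of mass, and the OLS fit of task AUC
  against passive count differences.
* **Pooling** — shuffle augmentation (6 surrogate copies per unit,
  within-class trial permutation), preference flipping, and the
  "pooling neuron" ROC as a function of pool size `N`, with the smallest
  `N` reaching a given behavioral accuracy.
* **Synthetic data** — generators for trial tables, spike trains
  (Poisson window counts, calibrated 12 ms preferred/non-preferred
  first-spike shift, 40 ± 5 ms onset latency), passive orientation
  responses, and LFP blocks with known ground truth, so every stage is
  testable offline.

## Worked example

```r
library(spikedisc)

pop <- generate_population(population_spec(), seed = 5)   # one session
lfp <- generate_lfp(lfp_spec(), seed = 5)

onset <- detect_onset(lfp)
onset
#> <onset_result> onset 43.2 ms (channel 1)

filt <- exclusion_filter(pop$units, onset$onset_ms)
disc <- discrimination_curve(filt$retained, pop$trials, onset$onset_ms)
disc
#> <discrimination_result> 72 units, 49 discriminating (68%), BH cutoff p <= 0.0243
```

The detected onset (43.2 ms) recovers the generator's ~40 ms cortical
latency up to the threshold-crossing time on the deflection's rise. 49 of
72 units are flagged as discriminating — the generator made 70% of them
discriminating by design — and the effective Benjamini–Hochberg cutoff
(p ≤ 0.0243 here) is the data-dependent threshold reused at shorter
intervals. Pooling the discriminating units' 80 ms counts:

```r
prefs <- setNames(disc$units$preference, disc$units$unit_id)
pool  <- pool_counts(filt$retained, pop$trials, onset$onset_ms, 80, prefs)
pool  <- augment_pool(pool, n_copies = 6, seed = 5)
pooling_curve(pool, Ns = c(2, 5, 10, 20), n_samples = 200, n_repeats = 5,
              seed = 5, behavior_accuracy = 0.76)
#> <pooling_curve>
#>   N mean_auc       sem
#>   2   0.7061 3.417e-04
#>   5   0.8227 1.748e-04
#>  10   0.9095 1.238e-04
#>  20   0.9721 6.355e-05
#>   smallest N reaching accuracy 0.76: 5
```

Summing ~5 units' 80 ms spike counts already matches a 76% behavioral
accuracy; the curve agrees with the exact Poisson prediction
(`poisson_auc(0.6 * N, 0.22 * N)`) because pooled Poisson counts stay
Poisson. The whole chain, including the first-spike and tuning stages and
a results directory with CSV/JSON outputs, runs as:

```r
run_pipeline(analysis_config(rng_seed = 5), out_dir = "results/run1")
```

or from a shell via the thin CLI: `exec/spikedisc report --seed 5
--out-dir results/run1` (subcommands `simulate`, `behavior`, `onset`,
`discriminate`, `firstspike`, `tuning`, `pooling`, `report`).

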