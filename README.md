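# omrfocus

Attentional switching analysis for larval zebrafish optomotor behavior.

Larval zebrafish in a coherent-dot optomotor (OMR) assay do not perform the
task steadily: across trials they alternate between an **engaged** state, in
which turns track the stimulus direction, and a **disengaged** state, in which
performance sits at chance. The per-trial performance score — the fraction of
bouts turned toward the target, rescaled to [-1, 1] — is therefore bimodal,
and summary statistics such as the mean hide what is actually two behavioral
modes. omrfocus is for behavioral and computational neuroscientists who need
to quantify that structure and compare it across groups of fish.

The package implements three linked models:

* a **Gaussian-gamma mixture** over per-trial scores,

  `P = (1 - w) · TruncNormal(0, σ) + w · TruncGamma(1/κ, θ)`,

  with σ = 0.18 and θ = 15 fixed. The Gaussian sits at chance and captures
  disengaged trials; the gamma lives on the ceiling distance
  `d = (1 - score)/2` and captures engaged trials. The fitted weight **w
  ("focus")** is the probability of engaging with the task, and **κ
  ("competence")** controls how tightly engaged scores hug perfect
  performance — two independent descriptors of behavior;

* a **gamma-emission hidden Markov model** over each fish's trial sequence
  (EM fitting, forward-backward posteriors, Viterbi paths, dwell times, and
  cross-validated choice of the state count, which selects two states on
  two-state data);

* **fish-level permutation tests**: fish are pooled, repartitioned 10,000
  times, the mixture refitted per repartition, and the observed Δw and Δκ
  located in the null difference distributions.

Because the underlying study's datasets are not deposited, the package also
ships a fully seeded bout-level simulator (`generate_cohort()`): Poisson bout
timing, a two-state attention chain, a gated leaky drift-diffusion decision
process for engaged trials, directional-persistence turning for baseline and
disengaged bouts, and a reflected random walk in the unit dish. Every
downstream estimator is validated against cohorts with known ground truth.
Binomial ("coin flip") and persistence null models of baseline turning are
included, along with the standard filters (wall exclusion at 90% radius,
first 30 s of baseline ignored, tracked-time bout rates) and the fixed 21-bin
score histogram layout used by all fits.

## Worked example

```r
library(omrfocus)

cfg    <- cohort_config(n_fish = 64, seed = 42)   # 64 fish x 30 trials
cohort <- generate_cohort(cfg)
cohort
#> <omr_cohort> 64 fish x 30 trials, 373748 bouts (150 s baseline + 30 s stimulus)

trials <- trial_summaries(cohort$bouts, cohort$schedule)

fit <- fit_mixture(trials$score) |> bootstrap_fit(B = 500)
fit
#> <omr_mixture_fit> w = 0.677, kappa = 19.20 (sigma = 0.18, theta = 15.0)
#>   MSE fit 0.000193 vs null 0.018 (1.1%); bootstrap SE(w) = 0.011, SE(kappa) = 2.63 [B = 500]
```

The fitted focus w = 0.68 recovers the generator's engaged-state occupancy
(enter rate 0.3 / (0.3 + exit rate 0.15) = 2/3): this cohort attends to the
task on about two trials in three. κ ≈ 19 says that when engaged, scores are
pushed hard against +1. The fit's MSE is 1.1% of the uniform-null MSE.

```r
hmm <- fit_hmm(trials, k = 2, seed = 1)
hmm
#> <omr_hmm> k = 2 states, loglik = 11161.65 (64 sequences)
#>   state 1: mean score 1.00 (shape 0.12, rate 62.13), stay prob 0.84
#>   state 2: mean score 0.01 (shape 4.20, rate 8.52), stay prob 0.68
```

The HMM recovers the same picture trial-by-trial: an engaged state at score
≈ 1 and a disengaged state at chance, with stay probabilities close to the
generating chain (0.85 and 0.70). `posterior_decode()` gives per-trial
engagement posteriors, `dwell_times()` the run-length distributions, and
`cross_validate_states()` the held-out likelihood across state counts.
`tidy()`, `glance()` and `autoplot()` methods are provided for the mixture,
HMM and permutation objects, and `permutation_test(group_a, group_b)`
compares fitted w and κ between two groups of fish. `run_pipeline()` chains
simulate → score → fit-mixture → fit-HMM → permutation test and writes every
artifact plus a reproducible run manifest.

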