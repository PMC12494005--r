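---
title: "Models and methods behind omrfocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omrfocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

omrfocus quantifies attentional switching in the larval zebrafish optomotor
response (OMR). Fish in a coherent-dot assay either track the stimulus
("engaged") or ignore it ("disengaged"), and their per-trial performance
scores form a bimodal cloud: a Gaussian lump at chance plus a skewed lump near
perfect performance. The package provides the full chain of machinery needed
to study this: a bout-level simulator, trial scoring, null models of baseline
turning, a Gaussian-gamma mixture that splits performance into *focus* (w) and
*competence* (kappa), a gamma-emission hidden Markov model (HMM) over trials,
and fish-level permutation tests.

This vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the simulation-based tests do and do not
establish about real data.

## Trial structure and scoring

A trial is 150 s of 0%-coherence dots (the baseline period) followed by 30 s
of directed motion (the stimulus period); 30 trials per fish, with every
successive trial pair containing one leftward and one rightward stimulus in
random order. The baseline period is scored against an independently drawn
random target so that baseline scores have a proper chance distribution.

The per-trial performance score is the fraction of bouts turned toward the
target, with a forward swim (turn angle exactly 0) counting half, rescaled to
[-1, 1]:

    score = 2 * (n_correct + 0.5 * n_forward) / n_bouts - 1.

Standard filters precede all scoring: untracked bouts are removed, bouts
initiated at a radius above 90% of the dish radius are removed (forced wall
turns), and the first 30 s of every baseline period is ignored (residual
turning from the previous stimulus). Bout rates divide counts by the tracked
portion of the window and are quoted in bouts/min. Score distributions use a
fixed 21-bin layout with centers at -1.0, -0.9, ..., +1.0; the end bins are
clipped to the domain. This layout is the only one consistent with both "bins
of 0.1" and "21 bins", and every histogram and fit in the package shares it.

## The synthetic cohort generator

`generate_cohort()` composes five processes, each tested in isolation:

* **Bout timing.** A Poisson renewal process with period-specific rates,
  defaults 62.9 (baseline) and 75.2 (stimulus) bouts/min — the mean rates
  reported for the assay this package models.
* **Attention chain.** A two-state Markov chain over trials with per-trial
  enter rate `p` (disengaged to engaged) and exit rate `q`. The initial state
  is drawn from the stationary distribution, so the expected engaged occupancy
  is `p/(p+q)` at every trial. Defaults `p = 0.3`, `q = 0.15` give occupancy
  2/3 and a median engaged dwell of about 5 trials. Log-odds-linear covariate
  modulation by baseline bout rate and trial index is exposed but defaults to
  zero coefficients, because no functional form for that dependence is
  established; the chain is homogeneous unless the user opts in.
* **Engaged decisions: a gated, leaky drift-diffusion integrator.** Evidence
  follows `dx = (gate * drift_gain * coherence - leak * x) dt + noise_sd dW`.
  Closing the attention gate zeroes only the sensory drive, so gated
  trajectories are distributed exactly like 0%-coherence ones. At each bout
  the evidence is read out: right above `+threshold`, left below
  `-threshold`, forward in between. The generator samples the integrator with
  the exact Ornstein-Uhlenbeck transition kernel at bout times (no
  discretization error); `integrate_evidence()` provides the Euler-Maruyama
  form, and a test checks that the two agree.
* **Disengaged and baseline turning: directional persistence.** The fish
  holds a latent side bias, turns toward it with probability 0.85, emits a
  forward swim with probability 0.3, and flips the bias with probability
  0.015 per bout. Disengaged stimulus-period bouts use this same process —
  gating removes the stimulus from the decision and the fish reverts to its
  intrinsic program — which is what makes disengaged trials statistically
  indistinguishable from baseline ones.
* **Position.** A reflected 2-D random walk in the unit disk with per-bout
  step lengths uniform on (0.02, 0.08); only the radius statistics matter
  downstream. Optional wall distraction converts engagement to disengagement
  with a probability that grows logistically with the trial's mean radius
  (gain 0 disables it).

All randomness flows from one master seed; per-fish streams are split
deterministically, so identical configurations yield byte-identical tables.

### Calibration of generator defaults

Defaults were fixed once, to reproduce the study conditions the assay
reports, and are not tuned per analysis:

* Turn magnitudes are half-normal with scale 35 degrees around a forward
  component, giving the characteristic central peak with side lobes.
* The persistence defaults put the baseline score SD near 0.36 on the
  [-1, 1] axis — the width that defines the mixture's fixed sigma (0.18 on
  the rescaled [0, 1] axis).
* The drift-diffusion operating point (drift gain 7 /s per unit coherence,
  leak 2 /s, noise 1.5 /sqrt(s), threshold 0.45) puts engaged trials near
  score 1, saturates first-bout accuracy by roughly 0.75 s after stimulus
  onset, and yields a monotone psychometric curve with chance performance at
  0% coherence.

### Evidence resetting

The integrator resets at stimulus onset and, by default, **not** after each
turn. With per-turn resetting, the accuracy of second and later bouts rises
with their waiting time just as the first bout's does, contradicting the
observed signature that only the first bout shows a latency effect; without
resetting, evidence sits at its equilibrium for every later bout and the
effect disappears (the package checks this against the inter-bout interval,
the waiting time that precedes a non-first bout). `reset_on_turn = TRUE`
restores per-turn resetting for users who prefer that convention.

## Null models of baseline turning

`coinflip_score_distribution()` is the exact binomial model: each bout is a
fair coin, achievable scores for n bouts are `(2k - n)/n`, and the final
distribution averages the exact per-n distributions over the observed bout
counts. `persistence_score_distribution()` adds the memory component: a
latent side bias followed with probability `persist_prob` and flipped with
probability `switch_prob` per bout. Its exact mode sums over all direction
sequences via a dynamic program over (bias, number of right turns) — the same
terms as explicit 2^n enumeration, verified against a joint brute-force
enumeration in the tests — and is limited to n <= 20; the Monte Carlo mode
converges to it. At `persist_prob = 0.5` the model reduces exactly to the
coin flip, and distribution width grows with persistence, which is what makes
the baseline distribution wider than binomial.

## The Gaussian-gamma performance mixture

Stimulus-period score distributions are modeled as

    P = (1 - w) * TruncNormal(0, sigma) + w * TruncGamma(1/kappa, theta),

with sigma = 0.18 and theta = 15 held fixed. The Gaussian sits at chance and
represents disengaged trials; `w` ("focus") is the engaged weight. The gamma
component is defined on the ceiling distance `d = (1 - score)/2`, with shape
`1/kappa` and rate theta truncated to d in [0, 1]. This orientation is an
interpretive commitment: the printed form Gamma(1/kappa, theta) is
right-skewed from zero, yet larger kappa must mean better performance, and
only a gamma on the distance-to-ceiling satisfies both — large kappa gives a
small shape, mass piles up at d = 0, i.e. score = +1. A test verifies that
the gamma-component mean score is strictly increasing in kappa.

sigma is quoted on the rescaled [0, 1] axis (so 0.36 in score units), because
it is defined as the SD of the Gaussian matching the baseline score
distribution after that rescaling; `sigma_scale = "score"` switches the
convention if desired.

Fitting minimizes the unweighted squared error between the model's exact bin
probabilities (component CDF differences over the 21 bins, no quadrature) and
the empirical histogram. The model is linear in w, so w is profiled out in
closed form at every kappa and the search is one-dimensional over log(kappa)
in [log 0.1, log 100]: the loss is evaluated at a fixed 17-point log grid
plus `n_starts` random initial points (default 25), then polished with Brent
around the best candidate. This keeps each fit around a millisecond, which is
what makes 5000-fit bootstraps and 10000-fit permutation nulls tractable, and
it is insensitive to the random-start draw (different RNG states agree in
loss to 1e-8). A histogram with a single occupied bin is fit but flagged
unreliable. Fit quality is reported as the MSE against the empirical
histogram, alongside the MSE of the uniform null (probability 1/21 per bin)
and their ratio as a percentage.

`bootstrap_fit()` resamples trials with replacement (default B = 5000) and
reports the SD of the refitted parameters; these SEs quantify estimation
uncertainty only.

## The gamma-emission HMM

Per-trial scores, transformed to ceiling distances (clipped at 1e-6 so
perfect trials keep finite densities), are modeled as a k-state HMM with
Gamma(alpha_k, beta_k) emissions, initial distribution pi and transition
matrix A. Sequences are per-fish chains — transitions across fish are
meaningless, so chains are never concatenated. Fitting is EM: scaled
forward-backward in the E step (vectorized across equal-length chains), and
in the M step closed-form updates for pi and A plus weighted gamma maximum
likelihood via Newton iteration on the digamma equation. The training
log-likelihood is asserted non-decreasing at every iteration. Ten random
moment-matched initializations are used by default (emissions split at
jittered quantile cuts, moment-matched per group); the best training
likelihood wins. Reported states are canonically ordered by mean performance,
state 1 being the engaged state.

The number of states is chosen by five-fold cross-validation with folds split
at the fish level (whole chains held out; held-out likelihood of a partial
chain is ill-defined without its prefix), comparing mean held-out
log-likelihood across k in 1..10. On two-state synthetic data the k = 2 model
clearly beats k = 1 and k >= 3 adds essentially nothing, reproducing the
model-selection logic of the assay. Dwell-time distributions come either
empirically from the maximum a posteriori path or analytically from A
(geometric with the state's stay probability).

Shape bounds of [1e-4, 1e6] in the gamma M step guard against the classic
degeneracy in which one state collapses onto near-duplicate emissions.

## Permutation tests for w and kappa

Group contrasts repartition *fish* (whole score sets), preserving the
original group sizes, refit the mixture on each repartitioned group, and
compare the observed `w` and `kappa` differences against the resulting null
distributions (default 10000 repartitions; 5 fit restarts inside the loop, 25
for the observed fits). The default two-sided p-value is the add-one-corrected
tail probability of |difference|, which is never below 1/(n_perm + 1), is
exactly 1 for a self-comparison, and has one-sided variants via a flag. A
small tolerance in the tail comparison absorbs optimizer-level jitter.

Type-I error of this procedure is calibrated by construction (fish are
exchangeable under the null); the test suite confirms a rejection rate of
0.05 +/- 0.03 at alpha = 0.05 over 200 null replicates and >= 95% power for a
focus contrast of w = 0.9 vs 0.3 at 32 fish per group.

## Numerical and design notes

* Angle histograms use 5-degree bins on the half-open domain (-180, 180].
* Trials with no surviving stimulus bouts score NA and are dropped from
  distributions (and counted in the pipeline log).
* Scores of exactly -1/+1 land in the clipped end bins; ties at bin edges
  follow the half-open (lo, hi] convention.
* The mixture's kappa is bounded to [0.1, 100]; w to [0, 1] by the profiled
  closed form.
* `emission_transform()` is monotone decreasing and invertible up to its
  1e-6 clip.
* Gate-closed versus baseline comparisons must match the scored windows and
  bout rates, because score dispersion scales as 1/sqrt(bouts per trial); the
  packaged check uses a 60 s baseline (30 s scored) against the 30 s stimulus
  window at equal rates.

## Problem sizes used by the test suite

Module tests run on small cohorts (4-40 fish). The deeper simulation checks
use: 1e5 scores for mixture recovery (w within 0.03, kappa within 15%), a
(w, kappa) grid at 1920 trials, 50 fish x 30 trials for EM recovery
(transitions within 0.05, decoding above 90%), 200 null replicates at 500
permutations for calibration, 40 replicate experiments for power, 10000
trials per coherence for the psychometric shape, and a 334-fish cohort for
the gate-closed distribution check.

## What the simulations do and do not show

The generator reproduces the statistical structure the analysis assumes —
renewal bout timing, Markov attention switching, persistence-widened baseline
turning, gated evidence accumulation, wall-biased positions. Passing tests
demonstrate that the estimators recover known parameters under that
structure; they cannot certify the structure itself against real fish, where
bout timing is not exactly Poisson, attention need not be first-order Markov,
kinematics are richer than a reflected random walk, and tracking artifacts
are not random. Real-data quantities that depend on a particular cohort
(specific p-values, dwell medians, facility-level parameter values) are
outside what simulation can or should reproduce.
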