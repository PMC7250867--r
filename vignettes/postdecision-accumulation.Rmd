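---
title: "Models and methods: post-decisional evidence accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: post-decisional evidence accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
generative models, the estimation machinery, the numerical conventions, and
the places where a design had to be chosen because more than one reasonable
option existed. Nothing here reports an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The scientific problem

In a two-stage perceptual decision a subject first chooses (left/right motion)
and rates confidence, then views a second evidence sample — always in the
true direction — and decides again. Because the post-decision evidence is
always veridical, an initially *correct* choice is followed by confirmatory
evidence and an initially *incorrect* choice by disconfirmatory evidence.
The question the machinery addresses: does confidence in the first decision
change how the second sample is accumulated — by shifting the starting point
of accumulation toward the chosen bound, by selectively amplifying
choice-consistent drift, or both?

Two measurement routes are implemented. The behavioural route fits diffusion
models to final-decision choices and RTs. The neural route decodes a
trial-by-trial decision variable (DV) from sensor-space recordings and reads
its intercept and slope as starting-point and drift analogues.

## The diffusion model family

Accuracy coding is used throughout: the upper bound is the correct response,
so drift toward the upper bound means accumulation of veridical evidence.
The Wiener process has drift $v$, boundary separation $a$, relative starting
point $z \in (0,1)$, non-decision time $t_0$, and diffusion scale fixed at
$s = 1$ — the modern convention; all other parameters are relative to it.

Trial covariates: confidence $c$ scaled affinely from the rating range
$[0.5, 1]$ to $[-1, 1]$ (binary high/low ratings code to $\pm 1$); initial
decision $d = +1$ (correct → confirmatory) or $-1$; their product $c\,d$; and
post-decision evidence strength $w = \pm 1$ (strong/weak — a symmetric coding
chosen because only the contrast matters). The ten models cross three
dependency families (confidence; decision; confidence + decision +
interaction, the interaction family retaining its lower-order terms as the
full model's printed form does) with three targets (starting point only,
drift only, both), on top of a baseline in which only $w$ moves drift.
Every model keeps a confidence dependency of the boundary separation;
parametric (not binarized) confidence is used there, since a symmetric
boundary change cannot mimic choice-dependent effects either way.

Link functions preserve invariants the linear predictors would otherwise
violate: logistic for $z$ (keeps it in $(0,1)$), exponential for $a$ and
$t_0$ (keeps them positive), identity for $v$. The trial likelihood is a
mixture of the Wiener first-passage density with a uniform contaminant of
weight 0.05 spanning the observed RT range and both response options; RTs
faster than 200 ms are removed before fitting. Both constants are the
package defaults in `fit_config()` and can be changed there.

### Estimation

Subject-level intercepts for $z$ (logit scale), $v$, $\log a$ and $\log t_0$
are drawn from group normal distributions; covariate coefficients are fixed
group-level effects. The sampler is adaptive Metropolis-within-Gibbs: one
jointly-proposed random-walk block per subject, a random-walk block per
coefficient group, conjugate Gibbs updates for group means, random-walk
updates on log group spreads (half-normal priors), with Robbins–Monro scale
adaptation during warm-up targeting 30%/44% acceptance. Priors are weakly
informative (coefficients $\mathcal N(0, 2^2)$; group means
$\mathcal N(0, 2^2)$–$\mathcal N(0, 5^2)$ on their natural scales).

Default chain settings are desk-scale — 4 chains × 3,000 iterations with
1,000 warm-up — and every reported draw count is the *actual* retained count
`(n_samples − n_burn)/thin` per chain rather than a quoted constant, because
stated sample/burn-in/thinning combinations do not always multiply out to
the advertised number. Convergence is monitored by the Gelman–Rubin
statistic (the classic $\sqrt{\hat V / W}$, floored at 1 because the plug-in
ratio can fall below 1 by sampling noise); fits failing the configured
threshold are flagged, never silently accepted. Model comparison uses
DIC $= \bar D + p_D$ with $p_D = \bar D - D(\hat\theta)$.

The Wiener density uses the standard small-time/large-time series split with
term counts chosen by the error-bound rule at tolerance $10^{-7}$. The
simulator is Euler–Maruyama with a Brownian-bridge correction for
within-step bound crossings, which removes the leading-order discretization
bias (validated against the analytic density and absorption probability in
the test suite).

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every recovery and calibration claim in the test suite is made.

* **Design**: 2 × 2 factorial, 90 trials per cell by default; incorrect
  coherences fixed at 5% (LPE) / 15% (HPE); correct coherences staircased;
  post-decision coherences derived by averaging, strong = weak × 1.3.
* **Staircase**: the calibration reference describes only an
  accuracy-targeting adaptive procedure, so a transformed weighted up/down
  rule is used (down-step = up-step × (1−p)/p), which equilibrates at the
  target accuracy p for any monotone psychometric function; step sizes are
  exposed as arguments. Non-convergence (tail accuracy off target, or
  coherence pinned at a bound) sets an explicit flag.
* **Observer**: logistic psychometric function over the correct-minus-
  incorrect coherence difference (slope 6 per unit coherence, a value that
  puts the 71%-correct threshold near 15% coherence difference, in the range
  of human motion psychophysics). The pre-decision stage is a diffusion
  whose drift is tied to the psychometric slope so staircase calibration and
  diffusion accuracy agree.
* **Confidence**: logistic in decision time (fast decisions → high
  confidence, which also couples confidence to accuracy) plus a
  positive-evidence offset proportional to total coherent motion. This
  reproduces the design's key dissociation — higher confidence at matched
  accuracy under HPE — which the test suite verifies on 10,000 simulated
  trials. The high/low variant median-splits within subject.
* **Post-decision stage**: drift and starting point follow exactly the
  model-10 regression structure with observer-settable ground-truth
  coefficients; defaults put moderate positive effects on the decision and
  interaction terms, so high-confidence errors are "stickier" (fewer
  changes of mind), the behavioural signature of interest.
* **Epochs**: noise (Gaussian, exponentially correlated across the channel
  index, correlation length 5 channels) plus a rank-one signal: a smooth
  unit-norm spatial pattern times a side-signed amplitude. Pre-decision
  amplitude is locked to the initial choice and grows over the window;
  post-decision amplitude has a choice-locked intercept and a
  direction-locked slope whose per-trial value follows a ground-truth
  regression on confidence, decision and their interaction. Default
  geometry is 273 channels × 821 samples at 100 Hz (−200..8000 ms); window
  onsets are arguments because task timelines differ between studies.
  Intercept coefficients default small relative to slope coefficients —
  matching the empirical pattern that neural effects load on the slope, and
  giving a decodability profile that builds over the post-decision window.
  The default noise scale (0.5 per channel per sample against a unit-norm
  pattern) is the SNR at which the package's slope-recovery validation is
  specified to operate; at that SNR single-trial choice decodability spans
  roughly AUC 0.55–0.80 across the window.

What the generator does **not** emulate: eye/muscle artifacts, sensor drift
and line noise, realistic source geometry or channel covariance, non-rank-one
signals, staircase non-stationarity, lapses, or confidence criteria that
drift over a session. Passing recovery tests on this generator therefore
demonstrates the *pipeline's* correctness and calibration, not that real
recordings will be as kind.

## The neural decision variable

Features are 100 ms boxcar means stepped at 10 ms; windows are
*right-aligned* to their nominal timepoint and clipped at the epoch edge (an
alignment convention had to be fixed; it is documented and configurable).
Features are z-scored per channel across trials at each timepoint; every
decoding routine re-standardizes with training-set statistics only, so no
information leaks from held-out trials (the z-scoring description alone does
not fix a fold protocol; the leakage-free reading is the defensible one).

Decoders are linear SVMs at the libsvm default $C = 1$. The DV is the
*geometric* signed distance to the hyperplane — the decision value divided by
$\lVert w \rVert$ — positive for rightward predictions. Normalizing by
$\lVert w \rVert$ keeps the DV scale comparable across timepoints (raw SVM
decision values shrink as data become more separable, which would distort
within-trial trends). DV extraction uses leave-one-out training;
temporal generalization uses stratified 4-fold cross-validation repeated
(default 100×) with AUC as the accuracy measure, reported separately per
confidence × change-of-mind cell, plus a pooled all-trials matrix.

Peak decodability is the maximum of the pooled matrix's diagonal, computed
on the group-average diagonal and applied to all subjects (per-subject peaks
are available by calling `peak_decodability()` per subject); ties break to
the earlier timepoint, and a flat diagonal returns the earliest point with a
warning. The per-trial line fit runs from post-decision stimulus onset to
that timepoint, time centered at window onset in seconds. The group-average
figures weight subjects by trial count where weighting is needed — the
"weighted average" convention is otherwise underdetermined.

## Group statistics

* `hier_regress()`: mixed models with subject random intercepts (lme4);
  Gaussian outcomes report $t$ with *residual* degrees of freedom
  (observations − fixed effects), matching the t(8000+)-style convention for
  trial-level models, rather than Satterthwaite; logistic outcomes report
  Wald $z$.
* `cluster_permutation()`: cells with one-sample $|t|$ above the two-tailed
  $p<0.05$ quantile form clusters under 4-connectivity (the conservative
  adjacency reading of "adjacent timepoints"); cluster mass is the summed
  $t$. The default null compares each cluster's |mass| to the permutation
  maximum of |cluster mass| over both signs, giving family-wise control at
  5% for the whole two-sided map — the calibration the test suite verifies
  on 200 simulated null datasets. The directed per-sign variant (each sign
  against its own 5% permutation quantile) is available as
  `null = "per_sign"`; note it doubles the map-wise error rate when both
  directions are read.
* `mediation()`: two-stage multilevel scheme — per-subject path regressions
  (linear for the mediator, logistic for the binary outcome; the indirect
  effect is the product of coefficients on the latent scale), averaged
  across subjects; uncertainty from a cluster bootstrap resampling subjects
  with replacement and then trials within subject. Intervals are
  percentile (the bias-corrected alternative is a possible extension; with
  percentile intervals the CI-covers-estimate invariant holds for all
  simulated settings in the test suite but is not guaranteed in pathological
  cases). Defaults scale the bootstrap to 5,000 draws; the six-figure draw
  counts used for publication-grade intervals are reachable through
  `n_boot`.

## Serialization and orchestration

Trial tables are plain CSV with a fixed column set and no missing values.
Epoch sets and fit bundles are single RDS containers — R's native
serialization preserves the arrays, tibbles and attributes losslessly and
round-trips at full precision (verified in the suite). `run_pipeline()`
validates its configuration against the full default tree before any stage
runs (unknown keys are errors), derives per-stage seeds deterministically
from the global seed, and emits a report whose checksum covers the headline
tables but not wall-clock durations, so identical runs give identical
checksums.

## Problem sizes used by the test suite

Chosen as the smallest sizes at which each property is comfortably
demonstrated: coefficient recovery at 20 subjects × 400 trials with 2 chains
of 2,600 iterations; DIC selection at 6 subjects × 200 trials; DV slope
recovery on one subject × 120 trials with 32 channels at the default SNR;
family-wise error calibration on 200 null datasets of 24 subjects × 30 × 30
cells with 500 permutations; mediation calibration on 100 replicates of
6 subjects × 60 trials with 400 bootstrap draws. The acceptance script uses
20 staircase replicates of 5,000 trials.

## Known limitations

* The MCMC sampler is a random-walk scheme: adequate at these problem sizes,
  but slower-mixing than gradient-based samplers for large designs;
  subject-level $v_0$/$t_0$ pairs mix slowest and drive most convergence
  flags at short chain lengths.
* Boundary separation and non-decision time carry no trial covariates beyond
  the confidence–boundary term; within-trial drift variation, collapsing
  bounds and race architectures are out of scope.
* The decoding layer is strictly linear (no nonlinear kernels, no source
  localization, no artifact rejection).
* Mediation with a binary outcome mixes a linear mediator model with
  logistic outcome models; the "total = direct + indirect" decomposition is
  exact only on the linear scale and approximate on the latent logistic
  scale.
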