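---
title: "Encoding dynamics in taste categorization sessions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding dynamics in taste categorization sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tastedyn)
```

This vignette documents the models behind `tastedyn`, the choices made
where the procedures were genuinely open, and what the bundled simulator
does and does not establish about real recordings.

## The task and the data model

A session is three tables on a shared millisecond clock: trials
(stimulus concentration, choice, outcome, event timestamps), spikes
(neuron, time), licks (trial, spout, time). Six concentrations
{0, 0.5, 1.3, 3.2, 7.9, 20 %w/v} are used, water (0%) on half the
trials. Three events anchor the analyses: stimulus delivery at the
central spout, the last central-spout lick (the start of the choice
movement), and feedback — defined as the second lick on the chosen
lateral spout, the moment reward is delivered or omitted. Trials with
fewer than two lateral licks (early aborts) are retained but carry no
feedback time and drop out of outcome-epoch analyses.

Analysis epochs are −400 to +800 ms around stimulus delivery and −300
to +800 ms around the other two events, tiled with 100 ms windows
moving in 10 ms steps. Windows are half-open `[t0, t0 + w)` so boundary
spikes are never double-counted, and each window is timestamped at its
centre, which keeps latency-to-peak measures symmetric (the
edge-vs-centre convention is otherwise arbitrary).

## The synthetic session generator

The generator exists so that every downstream stage can be tested
against known ground truth; its defaults define the study conditions
used throughout the test suite.

* **Behaviour.** The probability of a "sucrose" report is
  `clip(a·c^b, ε, 1−ε)` with defaults a = 0.38, b = 0.30, ε = 0.05,
  giving an absolute threshold `(0.5/a)^(1/b)` ≈ 2.5 %w/v and ~77%
  correct — near the 80% training criterion of well-trained rats. The
  defaults deliberately keep `a·20^b < 1 − ε` so the power law is
  unclipped at every sucrose concentration and psychometric fitting can
  recover (a, b); a clipped curve would bias the fit by design rather
  than by data.
* **Licking.** Inter-lick intervals are Normal(140, 15) ms truncated at
  60 ms — 140 ms being the canonical lick-cycle length used later as
  the warping constant — with 2–3 dry central licks (the stimulus
  arrives at the first), a movement gap, and ≥4 lateral licks; rewarded
  rats continue licking to consume the reward (10–14 lateral licks)
  while unrewarded rats stop early (4–6). That asymmetry is what makes
  the lick train genuinely informative about the outcome, which the
  lick-warping control is designed to expose.
* **Spiking.** Inhomogeneous Poisson by thinning: rate λ0 plus, on
  trials of a neuron's preferred condition, a Gaussian bump
  ΔΛ·exp(−(t−μ)²/2σ²) at a neuron-specific latency. "Switching" neurons
  carry a second, opposite-preference bump later in the epoch. Poisson
  spiking is the simplest process satisfying every assumption the
  analyses make; rank-based auROC is insensitive to refractory
  structure, so none is modelled. Template amplitudes (ΔΛ 20–30 Hz on
  baselines 2–8 Hz, σ 50–70 ms) are chosen so that detection power at
  ~200 trials is high but not saturated; the paper-scale effect sizes
  of real neurons are unknown, so these are the package's own choices,
  recorded in the template manifest.
* **Templates.** `encoders_mixed` (15 stimulus / 20 choice incl. 4
  switching / 30 outcome / 35 untuned, bump centres tiling 60–740 ms),
  `null` (50 untuned), `perfect_sequence` (20 non-overlapping bumps at
  20, 60, …, 780 ms). All randomness derives from one master seed via
  counter-based splitting, so sessions are bit-reproducible.

What passing tests on this generator **do not** show: real neurons are
non-Poisson, correlated across the population, drift within sessions,
and mix tuning continuously rather than categorically. Recovery results
here validate the *implementation*, not the biological effect sizes.

## The encoding screen

Per neuron and window, the auROC between the two class rate
distributions is the Mann–Whitney U statistic scaled to [0, 1] with
half credit for ties (class orientation fixed: water / water-response /
non-rewarded low, sucrose / sucrose-response / rewarded high).
Significance per window is a two-tailed permutation test on
|auROC − 0.5| (default 10,000 label shuffles, p = (1 + #extreme)/(n+1)).
One shuffle set per window is shared across neurons — the labels being
permuted are common to all neurons — which collapses the null
computation into one matrix product per window without changing any
marginal p-value. A neuron is an encoder when ≥5 consecutive windows
have p ≤ 0.05 and auROC ≥ 0.6 or ≤ 0.4. Two-tailed testing is used for
all three contrasts: the symmetric 0.4/0.6 thresholds already treat
both preference directions identically.

**Stimulus vs choice disambiguation.** Because correct trials make the
stimulus and the report collinear, the stimulus screen computes two
auROCs from the *same* trials — correct and error trials included —
arranged either by the delivered stimulus (A) or by the animal's
response (C, the choice probability index), and requires A > C (A < C
on the low side) in each qualifying window. The all-trials design is
essential: restricted to correct trials the two arrangements are
identical and the rule cannot fire, and computing A on correct trials
only while C uses all trials makes A and C estimates of the same
quantity that differ only by noise, so pure choice neurons pass the
rule about half the time. With both indices on all trials, a planted
pure-choice population leaks into the stimulus-encoder set at a rate of
0/20 in the bundled template, while stimulus-tuned neurons are kept
(the mismatching error trials attenuate C but not A).

**Operating characteristics.** The 5-consecutive-window rule is the
published guard against multiplicity; no across-window correction is
applied. Adjacent windows share 90% of their spikes, so null
exceedances come in runs, and the neuron-level false-positive rate
depends on the class balance: measured on 200 untuned Poisson neurons
at ~200 trials, ≈1.5% for the stimulus contrast (the A>C rule roughly
halves the null rate), ≈5% for choice (137/63 split), ≈7% for outcome —
the 78/22 outcome imbalance puts the fixed ±0.1 auROC thresholds at
only ~2 null SD. This is a property of the published rule, reported
here rather than patched; interpret outcome-encoder percentages
accordingly.

The two-proportion z-test used for cross-region count comparisons is
the pooled form z = (p̂₁−p̂₂)/√(p̂(1−p̂)(1/n₁+1/n₂)).

## Sequentiality

Selectivity matrices are rectified — |auROC − 0.5| where the deviation
reaches 0.1, zero otherwise — over windows centred in 0–800 ms after
the alignment event (display windows start earlier; the indices do
not). Peak entropy is the normalized entropy of per-neuron peak
windows; temporal sparsity is one minus the normalized mean per-window
entropy of activity shares, averaging only over windows with positive
total activity (an all-zero window is not a distribution). Entropies
use natural logs normalized by ln B and ln N, making the base
irrelevant. The combining rule is the geometric mean,
**SqI = √(PE·TS)**: it is the unique simple rule consistent with the
published index triples (e.g. √(0.939·0.515) = 0.695), reproducing
five of six to within one unit in the third decimal — the residual
discrepancies are exactly what rounding PE and TS to three decimals
produces. Ties in peak location break to the earliest window; peak
sorting for display is cosmetic and never affects the indices or the
split-half MSE (row-matched MSE is invariant to common row
permutations). Note that PE is bounded by ln(distinct peaks)/ln B, so
small populations cannot reach PE = 1 on a fine window grid.

Split-half reproducibility stratifies the random half-split by class
(odd counts favour half 1), recomputes both auROC matrices, and
compares their row-matched MSE against a null of 10,000 row shuffles of
the second matrix; p is the fraction of null MSEs at or below the
observed one.

## Decoding

Pseudo-trials homogenize neurons and trials by resampling with
replacement: per condition, 8 pseudo-trials whose feature for each
neuron is an independently drawn trial of that condition; one draw per
pseudo-trial is reused across time windows, preserving within-trial
dynamics. 15 neuron × 10 trial resamples give 150 accuracy estimates
per window (reported mean ± SEM), each from an 8-fold stratified CV of
a one-vs-one SVM (`e1071::svm`; linear, radial, or degree-3 polynomial
kernel at solver defaults, features unscaled — raw rates are already
commensurate). With 8 trials per condition and 8 folds, every fold
holds exactly one pseudo-trial per condition. The chance control
shuffles labels before each resample's CV and stratifies folds on the
shuffled labels; stratifying on the true labels instead biases null
accuracy measurably below 1/#classes. The six-class schema needs ≥8
correct trials per concentration per neuron, which a ~200-trial session
often fails for the hardest concentrations; six-class analyses in the
tests therefore use 400-trial sessions. Confusion matrices pool
predictions over 300–840 ms windows and all resamples, row-normalized;
they are compared by elementwise MSE against the identity ("fine")
pattern and a "gross" pattern — water row (1,0,…,0), sucrose rows
uniform 1/5 over sucrose columns — whose numeric content is this
package's formalization of fine vs gross discrimination
(MSE(fine, gross) = 1/9 ≈ 0.1111 sets the scale).

The licking control warps each trial's spikes onto a normalized lick
clock (lick k → k·140 ms, piecewise linear between licks; spikes
outside the lick train have no behavioural phase and are discarded)
and decodes reward delivery vs omission from the warped population
rates and, separately, from the warped lick rate, linear kernel, −400
to +800 ms around warped feedback. Warping removes lick-timing jitter,
so the lick arm retains only lick-count information — exactly the
confound the control is meant to isolate. Per-window significance is a
two-sided bootstrap (10,000 draws) over the 150 resample accuracies of
each arm.

## Psychometrics and neurometrics

The psychometric power law f(x) = a·x^b is fitted by least squares in
linear probability space (the paper does not state the fitting space;
linear-space residuals weight all concentrations equally), starting
from the log-log regression and polished by Nelder–Mead; x = 0 is
excluded from the fit (0^b is degenerate) but kept on the curve. For a
multi-session design the package fits per session and parameters can be
averaged afterwards; both the per-session fit and a fit to averaged
points are one function call. The neurometric threshold search is
exhaustive over midpoints of adjacent sorted unique rates plus ±∞ (so
the one-class classifier is representable), both directions, ties to
the smallest threshold and the high→sucrose direction for determinism.

## State space

Condition-averaged rates are smoothed at 1 ms resolution with a
Gaussian kernel of σ = 20 ms — the "20 ms width" is read as σ, not
FWHM; the choice is stated so results are reproducible — without edge
renormalization (truncated kernel, matching default density-estimation
behaviour). Neurons × (time·condition) matrices (condition-major) are
mean-centred per neuron; PCA is the eigendecomposition of the
neuron-space covariance; projections are reshaped into per-condition
trajectories and smoothed by `lowess` with span 0.1 of the epoch
(parameter exposed). Trajectory distances default to the leading 3
components — the components one would plot — since the exact count
behind the published distance panels is unstated. Inclusion thresholds
(≥5 correct trials per condition for the stimulus analysis, ≥2
otherwise) are applied; in single-session data all neurons share
trials, so the per-neuron rule degenerates to dropping underpowered
conditions.

## Numerical and reproducibility notes

* All seeds derive from one master seed by a splitmix-style integer
  map kept below 2³¹; serial and repeated runs agree bit-for-bit.
* Permutation p-values use the +1-corrected estimator and compare with
  a 1e-12 slack so rank ties do not flip significance by floating
  error; auROC threshold comparisons carry the same slack.
* Problem sizes in the test suite — 100-neuron templates, 200/400-trial
  sessions, 1,000 permutations per window, 150 decoding resamples over
  strided windows — are the package's chosen desk-scale study
  conditions; they keep the full suite under a few minutes while
  leaving every detection margin wide.
* Known limitations: no multi-session pooling of pseudo-populations
  (single-session containers only), no empirical recalibration of the
  0.4/0.6 auROC thresholds, no across-window multiplicity correction
  beyond the 5-window rule (see its measured operating characteristics
  above), no biophysical spiking structure in the simulator.
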