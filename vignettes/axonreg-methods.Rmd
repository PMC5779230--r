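---
title: "Quantification methods for maturation-dependent axon regeneration assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for maturation-dependent axon regeneration assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonreg)
```

`axonreg` implements the measurement rules of an in-vitro programme
studying why maturing CNS neurons stop regenerating their axons:
patch-clamp feature extraction, kymograph vesicle-transport
classification, laser-axotomy regeneration scoring, neurite
fluorescence polarity, an FPKM trend classifier, and the statistical
routing those assays use. Every stage is paired with a seeded
synthetic-data generator that plants known ground truth, so the test
suite verifies each rule by parameter recovery rather than by
re-deriving laboratory numbers. This vignette records the models, the
tunable parameters and the design choices, in the spirit of a methods
section.

## Electrophysiology

The stimulus is a sequence of 800 ms current steps applied in an
alternating negative/positive pattern whose magnitude grows by 20 pA
per same-sign step; the largest positive step (200 pA by default) is
the response step used for spike features.

An action potential is an event whose membrane-potential
*acceleration* exceeds 20 mV/ms² and that reaches 0 mV. Design
choices, all configurable:

* **Acceleration** is the discrete central second difference of Vm on
  the raw trace, in mV/ms². No smoothing is applied by default (the
  criterion carries the units of a bare second derivative); a 5-point
  Savitzky–Golay switch exists for rough data.
* **Confirmation window** (10 ms): a threshold crossing only becomes a
  spike if Vm reaches 0 mV within it. Longer than any physiological
  upstroke, short enough not to pair a crossing with an unrelated
  later peak. With noisy baselines the acceleration criterion alone
  fires constantly; the 0 mV gate is what rejects those crossings, so
  detected *counts* are robust to noise while threshold *timing* is
  exact only on clean data.
* **Refractory release** (0.5 mV): scanning resumes once Vm falls back
  below the event threshold plus this tolerance. The tolerance matters
  because a noise-free repolarization approaches the plateau
  asymptotically and would otherwise never release the guard.

Passive properties: resting potential is the mean over the 200 ms
immediately before the first step ("before any current"); input
resistance uses the smallest-magnitude of the first three negative
steps (most likely to stay in the linear regime), reading the steady
state from the final 100 ms. Spontaneous activity applies the same
spike criterion to a ≥ 2 min zero-current recording.

The synthetic spike is a difference of exponentials,
`A(exp(-t/τ_d) − exp(-t/τ_r))`, with τ_r = 0.25 ms and τ_d solved
numerically so the half-width equals a requested value (1.5 ms
default); the amplitude is scaled for a +20 mV absolute peak. The
waveform starts with a slope discontinuity, so its discrete second
difference at onset is large and controllable — planted spikes satisfy
the detection criterion by construction, while "distractor" humps
peaking at −20 mV exercise the amplitude gate. The closed form of this
template (root-finding on the continuous waveform) is the oracle for
width and amplitude tests.

## Kymograph vesicle transport

Tracks are positions along a neurite (positive = away from the soma)
at 1 Hz for 3 min within a 30 µm imaging strip. Movement segmentation
partitions a track into maximal monotone runs, ignoring reversals
smaller than 0.2 µm — a hysteresis that mirrors how a human reader
tolerates localization jitter. Runs whose *net displacement* (not path
length) exceeds 2 µm become movements; "more than 2 µm" is read
strictly (> 2), with the boundary case configurable. A track with
directed movements only one way is anterograde or retrograde; both
ways, bidirectional; otherwise it is reported as *stationary* — a
fourth class kept so direction fractions sum to 1 rather than dropping
sub-threshold vesicles. Per-cell velocity averages the speed (net
displacement / run duration) of every directed movement across the
cell's tracks.

The tracer for rendered kymographs is deliberately simple: per-row
local maxima above a threshold, sub-pixel parabolic refinement,
non-maximum suppression within 3 px (noise splits a Gaussian spot into
twin maxima surprisingly often), nearest-neighbour linking within
6 px/frame, gap bridging up to 2 frames, and a 10 s minimum duration.
Crossing or ambiguous tracks are split, not guessed. The recovery
harness therefore scores fragments fairly: recovered fragments are
assigned to the planted track they match best and coverage is pooled.

The generator plants directed tracks (runs with pauses; vesicles
reaching the strip boundary park there, as real vesicles leave the
focal plane), bidirectional tracks with 3–6 µm excursions each way,
and stationary tracks as smooth sub-2 µm oscillations. A `lanes` mode
confines each track to its own spatial band to produce the
non-crossing geometry used for tracker benchmarks.

## Laser axotomy

A time course is the axon-tip position along its path every 20–30 min
(spacing drawn uniformly and stored explicitly — no stage assumes
uniform frames) for at least 10 hr after the cut at t = 0; only the
first 10 hr are used for outcome classification. The taxonomy: death
(disintegration/cell-disruption flag within 10 hr), branch loss
(retraction to the nearest proximal branch point with no bulb), bulb
formation; death and branch loss are excluded from factor analysis.

Positional proxies replace the paper-and-pencil morphology calls:

* **Bulb stabilization**: the bulb forms at the first frame opening
  `k_stab = 2` consecutive steps smaller than `δ_stab = 10 µm`. The
  bulb position averages the stable frames (noise suppression);
  retraction distance is the cut distance minus that position, so
  retraction + bulb position = axotomy distance identically.
* **Regeneration initiation**: the earliest frame from which every
  step advances (beyond a configurable back-step tolerance, 0 µm by
  default) and the net gain over the following 1 hr reaches
  `v_min = 10 µm/hr`. The minimum rate is needed because bulbs are
  motile; without it bulb wobble would count as extension.
* **Regrowth**: length extended in the 2 hr after initiation, as path
  length along the recorded trajectory with the window edges linearly
  interpolated (frames rarely align with initiation + 2 hr exactly);
  growth-cone area averages the frames nearest 20, 40 and 60 min after
  initiation, with interpolation available.

The generator realises each planted outcome on the jittered frame
grid and records the *realised* values as ground truth: retraction
ramps use per-frame steps of at least 20 µm so the stabilization rule
cannot trigger early (a bulb-time request incompatible with that step
floor is shortened, and the truth records what was actually drawn), and
cohort retraction draws are floored at 12 µm — a retraction below the
10 µm stabilization resolution cannot be distinguished from bulb
motility by any positional rule, and such draws occur in well under
0.1 % of the planted mixture.
Closed-loop tests then demand exact lengths and times within one frame
interval. Inter-frame positional noise is a free parameter — the
imaging literature gives no canonical value — and the noisy recovery
tests use 5 µm.

Retraction distances are log-normal, so cohort statistics run on
log10 values. The mixture model is a hand-written EM on the log10
scale comparing k = 1 and k = 2 normal components by BIC
(−2·logLik + p·log n), with ten quantile-seeded restarts for k = 2 and
a 10⁻³ floor on component standard deviations; the reported boundary
is the posterior-equality point between the components, in µm. An
independent mixture implementation (mclust) serves as a cross-check in
the tests, never as the implementation. At the planted study setting
(equal mixture at 1.5/2.2 log10 µm, σ = 0.15, n = 300) BIC selects
k = 2 in ≥ 95 % of seeds and recovers each mean within 0.05.

The short/long retraction boundary is 70 µm, inclusive on the long
side (70.0 → long). The proximal/distal axotomy cut-off is an analysis
default of 500 µm — the rodent experiments never print a numeric
boundary (the human-neuron work cut at 300–500 µm) — so it is
configurable and recorded in output metadata. The regeneration ratio
counts ectopic growth as regeneration ("overall regeneration").

## Polarity

All intensities are corrected by subtracting a paired control region
adjacent to the ROI; backgrounds are supplied with the input because
region placement is a manual judgement (avoiding nearby structures),
not something to estimate automatically. Windows are half-open [a, b)
µm of traced arclength from the soma edge, which pins down the
boundary sample at 100 µm. The dendrite signal averages the brightest
*three* dendrites ranked by corrected intensity (ranking by corrected
rather than raw intensity keeps the selection consistent with every
other reported quantity), with ties broken toward the lowest neurite
id so the selection is permutation-invariant. Cells with more than one
axon are rejected. Ratios are undefined (flagged) for non-positive
denominators, and are invariant to a global positive intensity scale.

## Expression trends

A gene is increasing (decreasing) when three criteria hold between the
extreme timepoint means over DIV 1/4/8/16/24 with six replicates:
fold > 3 (a 0.01 pseudocount guards silent genes; the floor criterion
uses raw means), Welch's t between the extreme timepoints'
replicates with Benjamini–Hochberg adjusted p < 0.05 across all genes,
and some timepoint mean > 10 FPKM. "Highest/lowest FPKM value" is read
as the highest/lowest *timepoint mean* — the replicate test is defined
between those same two timepoints, which only makes sense at group
level. Ties break toward the earlier timepoint. Planted trending genes
are monotone (geometric means), but the classifier never assumes
monotonicity. Flat genes are planted in three flavours that each
defeat exactly one criterion: constant means, expressed-but-low
(fold 3.5 under the 10 FPKM floor), and high within-group variance.
A brute-force re-implementation of the three rules is kept in the test
suite and must agree exactly on every simulated matrix.

## Statistics harness

Two groups: an F-ratio variance check at α = 0.05 routes to Student's
or Welch's t (the routing is recorded in `method_path` so analyses are
auditable). Three or more: one-way ANOVA, with Bartlett's test gating
the post hoc — Games-Howell when the equal-variance assumption is
violated, otherwise Bonferroni pairwise comparisons or Dunnett against
a control. Games-Howell is written here (no installed implementation):
Welch standard errors, Welch–Satterthwaite df floored at 2, and
q = |Δ|·√2/SE referred to the studentized range distribution via base
R's `ptukey`. Dunnett's adjusted p delegates to multcomp's single-step
multivariate-t integration with an internally fixed seed for
reproducibility. Fisher's exact p uses the two-sided point-probability
convention (r × c tables fall back to a flagged Monte-Carlo p);
Kruskal–Wallis is tie-corrected with a χ² p and an exact enumeration
option for total n ≤ 12. All conventions are two-sided. Calibration is
tested by null simulation (type-I error within the 99 % binomial band
of α = 0.05 at 10,000 replicates; Games-Howell family-wise error in
[0.04, 0.06] for four null groups).

## What the synthetic data does and does not show

The generators reproduce the *statistical structure* the assays rely
on: spike trains riding on current steps, direction-biased vesicle
runs with pauses, log-normally distributed retraction with stochastic
initiation and linear elongation, polarized intensity profiles,
timepoint-trending FPKM. They do not model biophysics (no conductance
model, no photorealistic microscopy, no read-level sequencing), so
passing recovery tests demonstrates that the measurement rules are
implemented correctly and are well-conditioned at realistic noise —
not that the rules themselves are optimal for any particular
microscope or rig. Laboratory effect sizes (e.g. how far regeneration
ratios fall with maturity) are inputs to the simulations, not outputs
of the package.

## Problem sizes and determinism

Every generator is a pure function of its seed (bit-identical
re-runs); pipeline stages derive sub-seeds from one global seed, and
`run_full_analysis()` writes a manifest of parameters and output
checksums, so identical configurations give byte-identical bundles.
The verification suite uses cohorts of 100–1,000 traces/tracks/genes,
500 axotomy time courses, 100 mixture seeds at n = 300, exhaustive
Fisher enumeration for all 2 × 2 tables with n ≤ 40, and 10,000-rep
null simulations — sizes chosen to estimate each rate to well under
the margins being asserted.
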