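---
title: "Methods: multi-observer contour evaluation with contoureval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-observer contour evaluation with contoureval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contoureval)
```

## The problem

When several clinicians contour the same tumour — for radiotherapy target
definition, or to evaluate a contouring tool — three questions recur:

1. **What is the panel's consensus**, and how reliable is each annotator
   relative to it?
2. **How far, and where, does each contour deviate** from that consensus?
3. **How is the annotators' time spent**, and does a new tool actually
   change it?

`contoureval` implements this analysis as a reusable pipeline over stacks of
co-registered binary masks (NIfTI) and timestamped interaction logs, and
ships a synthetic observer-study generator so the entire analysis — and its
test suite — runs without any clinical data.

Throughout, masks are 3D arrays indexed `(z, y, x)`; voxel `(k, j, i)`
(0-based) has its centre at `origin + index * spacing`, so every distance is
in millimetres and axial slices are fixed-`z` planes.

## Consensus: STAPLE

The consensus is estimated by Simultaneous Truth And Performance Level
Estimation. Each rater $j$ is a noisy channel over the hidden true label
$T_i$ with sensitivity $p_j = P(D_{ij}=1 \mid T_i=1)$ and specificity
$q_j = P(D_{ij}=0 \mid T_i=0)$. The EM iteration alternates

$$W_i = \frac{a_i}{a_i + b_i},\qquad
  a_i = \gamma \prod_j p_j^{d_{ij}}(1-p_j)^{1-d_{ij}},\qquad
  b_i = (1-\gamma) \prod_j q_j^{1-d_{ij}}(1-q_j)^{d_{ij}},$$

$$p_j = \frac{\sum_i W_i d_{ij}}{\sum_i W_i},\qquad
  q_j = \frac{\sum_i (1-W_i)(1-d_{ij})}{\sum_i (1-W_i)}.$$

Numerical and design choices, each configurable:

* **Region of interest.** Estimation is restricted to the union of rater
  foregrounds dilated by 10 voxels. Running STAPLE over a whole scan
  swamps the prior with background and drives specificity estimates
  degenerate — a standard pitfall. With raters that produce no false
  positives the weight map is invariant (to ~1e-7) to widening this margin;
  with false-positive noise the specificity estimate necessarily depends on
  how much background is included, so exact invariance cannot hold and the
  margin is part of the method definition.
* **Prior** $\gamma$: the mean rater foreground fraction within the ROI
  (scalar; configurable).
* **Initialisation**: $p_j = q_j = 0.9999$, deterministic — no random
  restarts.
* **Log-space E-step** with probabilities clamped to
  $[10^{-10}, 1-10^{-10}]$; with nine raters the plain products underflow.
  The clamp is part of the algorithm's definition here, shared with the
  validation oracle.
* **Convergence**: max absolute change over all $(p_j, q_j)$ below 1e-7, or
  200 iterations (then `converged = FALSE` with a warning, not an error).
  The observed-data log-likelihood $\sum_i \log(a_i + b_i)$ is recorded per
  iteration and asserted non-decreasing in the tests.
* **Thresholding**: consensus mask is $W_i \ge 0.5$, ties assigned
  foreground — a fixed deterministic rule.
* **Scope**: one consensus per (case, method) by default; a pooled
  both-methods consensus is available (`staple$scope = "pooled"`), and every
  report records which was used. The underlying study design reads either
  way; per-method is the default because it lets the two arms be compared
  without one contaminating the other's reference.

## Agreement metrics

**DSC** is the voxel-count overlap $2|A\cap B| / (|A|+|B|)$.

**Added path length** is the length of the reference (consensus) contour
lying farther than a tolerance (default 2 mm) from the test contour — the
portion of the reference path an editor would still have to draw. Choices:

* **Slice-wise 2D computation.** Contours are edited slice by slice, so
  boundaries and distances are computed within each axial slice;
  cross-slice tolerance credit is disallowed, and a slice where the
  reference has contour but the test has none counts fully. A consequence:
  APL does not vanish at infinite tolerance if the test misses slices
  entirely — that remaining length genuinely has to be drawn.
* **Boundary representation**: exposed voxel-edge chains. Lengths are
  deterministic and exactly additive (a 20 × 20 voxel square at 1 mm
  spacing has perimeter exactly 80 mm), unlike sub-voxel polygon
  approximations.
* **Orientation**: measured on the reference; the reverse orientation is
  `added_path_length(test, reference)` and reports name the orientation
  used.
* APL is reported relative to the total reference contour length, since
  absolute length varies across patients.

## Deviation maps

The consensus surface is the set of foreground voxels with a six-connected
background neighbour, at voxel centres. For each surface element and each
annotator, the signed deviation is the exact anisotropy-aware Euclidean
distance to the annotator's surface (computed by a separable
lower-envelope distance transform, so 2 mm CT slices are handled
correctly), signed positive where the element lies inside the annotator's
mask. Element-wise percentiles across annotators (default
10/30/50/70/90, linear interpolation between order statistics, so two
annotators at ±2 mm have median 0) and the 10–90 range summarise local
disagreement; the numeric map is the artifact of record, the colour-coded
projections are renderings of it.

**Alignment is off by default.** All of a case's masks live in one scan's
frame; translating each contour onto the consensus centroid before
measuring would hide systematic positional disagreement. Because published
descriptions of "aligned to the consensus" are ambiguous between rigid
pre-registration and mere resampling to a common grid, centroid alignment
exists behind `deviation$align = TRUE` and reports record the flag.

## Interaction time

Logs are streams of GUI events (`move`, `drag_start/drag/drag_end` with a
tool, `tool_select`, `scroll`, `zoom`, `predict`). Each interval between
consecutive events is classified:

* **active** if it lies within a drag stroke — drawing means dragging the
  cursor; the click that triggers a DL prediction is observation, since
  inference returns in well under a second;
* **excluded** if it is outside a stroke and longer than the break
  threshold (default 85 s) — an interruption to the task;
* **observation** otherwise.

Excluded time is defined as the untracked remainder of the log span, so
active + observation + excluded equals the span by construction. An
excluded interval breaks an observation episode. Observation-interval
histograms use bins {0, 1, 10, 50, 85} s by default — the durations worth
singling out within the 85 s cap — and report both interval counts and
summed duration, because "x% of observation time" can be read either way.
Aggregation is per session first, so each case contributes equally within
an annotator; relative change between methods is `(after − before)/before`.

The 85 s threshold is a parameter, not a law: it reflects an empirical gap
analysis in the instrumented GUI this design emulates, and raising it can
only move time from excluded to observation (a monotonicity the tests
assert).

## Statistical comparison

Paired Wilcoxon signed-rank tests compare methods on DSC, relative APL,
active and observation time, pairing on (annotator, case). Zero differences
are dropped (Wilcoxon's rule, not Pratt's); the p-value is exact for up to
25 tie-free nonzero differences and otherwise uses the normal approximation
with tie and continuity corrections. The computation is delegated to
`stats::wilcox.test` with the branch chosen explicitly; an exhaustive
sign-assignment enumeration oracle validates it in the tests, and a
2,000-replicate null simulation checks type-I error at the reporting
threshold of 0.01. No multiplicity correction is applied — the report lists
all p-values so users can apply their own.

## The synthetic cohort

The generator replaces undeposited clinical data; nothing in the analysis
code knows whether its inputs were simulated.

* **Shapes** are star-convex: radius
  $r(u) = R\,(1 + \alpha S(u))$ along direction $u$ from the centre, with
  $S$ a fixed sum of random cosine modes on the sphere normalised to
  $\max|S| = 1$ and $\alpha < 1$, so the surface is one closed sheet and
  the voxelisation is connected. Default cases draw $R$ uniformly from
  12–16 mm (lung-tumour scale) with $\alpha = 0.25$ and three lobes, on a
  40 × 56 × 56 grid at 2 × 1 × 1 mm — CT-like thick slices.
* **Annotator panels** displace the base boundary along its outward normal
  by the value of a smooth displacement field: a per-annotator bias field
  (SD `sigma_inter_mm`, shared across that annotator's sessions) plus an
  independent per-session noise field (SD `sigma_intra_mm`). A voxel is
  foreground when its signed distance to the base surface is at most the
  local displacement; with all SDs zero the output equals the base voxel
  for voxel. The two components make inter- and intra-observer variability
  separately tunable. An optional focal term lets each annotator include,
  with some probability, a directional bump of tissue — the localised
  "is that collapsed lung or tumour?" disagreement pattern. The DL arm is
  modelled by scaling the inter-observer component by
  `dl_bias_scale < 1`: an assisting tool pulls annotators toward a common
  shape but leaves their session-to-session noise.
* **Voxel-flip raters** label each ROI voxel by independent coin flips with
  known sensitivity/specificity — the exact generative model STAPLE
  assumes, used to test parameter recovery.
* **Session logs** alternate log-normal observation gaps (heavy right
  tail: roughly 40% of gaps are sub-second while long pauses carry on the
  order of a fifth of observation duration) with gamma drag strokes, plus
  Poisson interruptions longer than the break threshold. A session ends
  when its drawing budget `session_duration_s * active_fraction` has been
  spent: the drawing effort is what a case determines, and observation time
  is stochastic around its expectation. (Ending on total tracked time
  instead would leak the heavy-tailed gap variance into active time and
  bias method-comparison ratios.) Expected observation per stroke cycle is
  computed from the truncated log-normal mean, so the realized pooled
  active fraction converges to `active_fraction`.
* **Seeds.** One master seed per study; every annotator, case, session and
  field derives an independent sub-stream via a stable string hash, so any
  part of a study can be regenerated in isolation and the whole study is
  bit-reproducible.

### Calibration

The shipped defaults (`default_study_config()`) emulate a two-arm study of
9 annotators × 10 cases. Displacement SDs were calibrated once —
`sigma_inter_mm = 2.8`, `sigma_intra_mm = 1.35`, `dl_bias_scale = 0.78` —
so that mean consensus DSC lands in the 0.70–0.80 band reported for
clinical lung-tumour panels (measured at seed 1: 0.736 manual, 0.772 DL;
intra-observer 0.813). The log configs put the manual arm at 22 min
tracked, 33% active, and give the DL arm unchanged observation minutes
with active time scaled to 0.77×, i.e. a 23% active-time reduction, which
the pipeline recovers to within ±0.01 over the 90 pairs.

These numbers say the pipeline *measures what was put in*; they are not
evidence about any real tool. The generator reproduces panel geometry,
boundary-displacement statistics and renewal-process timing, but not CT
texture, reader anatomy-specific behaviour, fatigue or learning effects —
so passing tests validate the measurement machinery, not clinical claims.

## Problem sizes and determinism

The defaults keep a full simulated study (180 masks, 20 STAPLE runs, 180
logs) under a minute of CPU; tests use smaller grids (balls of 7–22 voxel
radius, 1,000-voxel STAPLE ROIs for oracle comparison, a 64³ ROI for
parameter recovery). Every generator is a pure function of (config, seed);
`run_study()` reruns bit-identically and records a config hash, the seed
and all decision flags in its provenance block.

## Known limitations

* Binary masks only — no multi-label STAPLE, no spatially varying prior.
* APL and contour length are tied to the axial slice-wise editing model;
  a true 3D surface-distance variant is out of scope.
* Centroid translation is the only alignment offered; no rigid rotation or
  deformable registration.
* The session model is a renewal process: no eye-tracking-grade activity
  decomposition, no modelling of what the annotator was looking at.
* DICOM RT-STRUCT import is a documented extension point, not core: the
  analysis operates on voxel masks, and rasterising RT-STRUCT adds
  ambiguity that belongs upstream.
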