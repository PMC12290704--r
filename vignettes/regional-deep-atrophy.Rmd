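---
title: "Regional deep atrophy: attention-based longitudinal morphometry on fixed deformation fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional deep atrophy: attention-based longitudinal morphometry on fixed deformation fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Deformation-based morphometry estimates structural change from a registration
between two scans of the same person: the Jacobian determinant of the
deformation `Phi(x) = x + u(x)` measures local volume change. The question
this package addresses is *where* to integrate that signal. Hand-drawn or
segmentation-derived regions of interest import anatomical priors and miss
change outside them; integrating everywhere dilutes systematic change with
registration noise and artifacts.

The approach taken here trains an attention network to find the informative
regions itself, using only temporal metadata as supervision. A 3D U-Net
consumes the stacked (fixed, moving) pair and emits three per-voxel maps —
shrinkage, expansion, background — pushed to near-binary values by a SoftMax
with a large temperature (`tau = 100`; a pre-SoftMax logit gap of 0.06
already drives the winning channel above 0.995). The deformation field
itself is *fixed*: it comes from an external longitudinal registration (or,
here, from the phantom generator's analytic ground truth) and is never
updated during training.

For a scan pair of subject `j` at times `t1` (fixed) and `t2` (moving), the
attended volume change of region `l` (shrink or expand) is

    A_l = sum_x s_l(x) * (detJ(x) - 1) * dV,

i.e. the difference between the region's volume in moving space (change of
variables: `sum s * detJ * dV`) and in fixed space (`sum s * dV`). The
pooled measure `A_pooled = A_SHR - A_EXP` is negative under atrophy with
forward time — the sign convention used consistently here. (The opposite
sign language also appears in the field; only the orientation of the AUC
score and the expected sign flip if you change it.)

Two self-supervised losses shape the attention:

* **STO (scan temporal order)** — cross-entropy of the logit pairs
  `[-A_SHR, A_SHR]` and `[A_EXP, -A_EXP]` against the order label
  `y = sign(t2 - t1)`. Minimal when shrink regions lose and expand regions
  gain volume under forward time; the uninformative value is `2 log 2`.
* **RISI (relative interscan interval)** — for two nested scan pairs of one
  subject, the ratio of attended changes should match the ratio of the
  interval lengths. The ratio is classified into the four bands
  `[0, 0.5], (0.5, 1], (1, 2], (2, Inf)`; each band is a union of cones in
  the `(A1, A2)` plane bounded by the lines `|A1|/|A2| = 0.5, 1, 2`, scored
  as a product of boundary sigmoids (scale `alpha`), the band maximum taken
  over its cones, and the four scores renormalized to a distribution before
  cross-entropy. Renormalization is required because the raw cone products
  do not sum to one; the middle bands use four sign-quadrant cones so that
  mixed-sign change pairs are classified by their absolute ratio as well.

Training uses two branches with a single shared parameter store: each step
forwards the two pairs of a nested quadruple, computes both branch STO
losses plus the RISI loss of the pair-of-pairs, and backpropagates the
weighted sum (default weights 1 and 1).

### Normalization of the change values

Raw changes in mm^3 would saturate the sigmoids, so both losses receive
*fractional* changes: `A_l / (v_base + dV)`, where `v_base` is the
fixed-image volume of the shrink and expand regions combined and the
one-voxel epsilon guards the empty-attention corner. The sigmoid scale
`alpha = 50` then puts realistic annual changes (0.5%–8% per year over
0.25–6 years) in the informative range of the losses. `v_base` is part of
the differentiated graph: attending to uninformative voxels dilutes the
fractional change and is therefore penalized, which is what drives the maps
to concentrate on regions of systematic change rather than covering the
volume. Both `alpha` and the normalization are package choices — at this
point the method's reference description is silent — and are configurable.

### Quadruple selection

Valid pair-of-pairs require the shorter interval to lie within the longer
(`[min, max]` containment) with at most one shared endpoint, so the two
pairs span three or four distinct scans. `enumerate_quadruples()` emits
every valid unordered interval pair in both branch orders and all four
temporal orientations; a boundary interval ratio (exactly 0.5, 1 or 2) is
assigned to the lower band.

## The phantom generator

Real longitudinal MRI with curated registrations cannot ship with a
package, so every stage is exercised on synthetic cohorts with known
answers. A phantom subject is two disjoint ellipsoids in a 48^3 mm grid — a
"tissue" structure that loses volume and a "fluid" structure that gains it
— plus a static smooth per-subject texture (the stand-in for anatomy, which
makes same-subject pairs structurally similar: SSIM lands in the 0.7–0.9
range reported for well-registered pairs, while unrelated volumes score far
below 0.6) and i.i.d. Gaussian noise per scan.

Atrophy is linear in time: tissue volume at elapsed time `t` is
`V0 (1 - r t)`, fluid volume `V0f (1 + rho r t)` with coupling `rho = 1`;
subject rates `r` are drawn uniformly from 0.5%–8% per year, spanning
control-like to late-MCI-like regimes. Linearity is a deliberate
simplification — annual rates are small, so curvature over a 6-year window
is negligible. Scan times sit on a quarter-year lattice between 0.25 and 6
years from baseline, 3–4 scans per subject by default.

The ground-truth displacement field between two times is an exact radial
scaling inside each region, blended to identity across a support shell
(1 < q < 1.3 in normalized ellipsoid radius) with a smoothstep. Two
consequences worth knowing:

* inside each region the Jacobian is exactly the prescribed volume ratio;
  integration over the voxelized mask agrees to ~1% (boundary voxels);
* the blending shell necessarily contains compensatory signal — a ring of
  local *expansion* around the contracting tissue (and vice versa). A
  trained model legitimately discovers this ring for its expansion channel;
  it is a property of any compactly supported deformation, and it is why
  the end-to-end checks anchor on the *shrink* channel's localization.

Time-independent confounds emulate the nonsystematic-change taxonomy
(motion, artifacts): a small random smooth warp and/or a random constant
patch with alternating stripes, drawn independently of acquisition time.
The severe setting (probability 1, amplitude 2x the dynamic range, half
the volume extent) is the designed QC-rejection arm. Confounds perturb
rendered scans only; ground-truth masks, fields and rates are untouched.

What the phantom does *not* emulate: MRI physics (bias fields, k-space
artifacts), anatomical shape variation between subjects (all subjects share
the template geometry; the heatmap "template space" is therefore exact
rather than estimated by registration), registration error in the field
itself, and scanner upgrades. Passing the end-to-end checks shows the
estimator and losses work when the deformation faithfully encodes change —
not that any particular registration pipeline does.

## Downstream measures

* `pair_change()` gives `A_SHR`, `A_EXP`, `A_pooled`, `v_base` per pair.
* `annualized_rate()`: one baseline-anchored pair gives
  `(A_pooled / v_base) / interval`; several give the OLS slope of
  `A_pooled` vs interval divided by the baseline pair's `v_base`. The fit
  includes a free intercept by default (whether the reference description
  fit through the origin is unstated; the switch is exposed). Mixed
  anchoring is rejected rather than pooled.
* `age_adjust()` removes a reference-group linear age trend.
* `group_difference()`: one-sided Wilcoxon rank-sum (exact for combined
  n <= 25 without ties, otherwise normal approximation with correction)
  plus the AUC of `-rate`.
* `aggregate_heatmap()` warps binarized (0.5) attention maps into template
  space and reports per-voxel identification frequencies normalized by
  coverage, so sparsely covered peripheral voxels cannot exceed 1.

## Numerical choices

* Jacobians: central differences in the interior, one-sided at borders,
  spacing-scaled; `det(I + grad u)` per voxel with `|det|` guarding rare
  negative values in noisy fields. Moving-space volumes use the change of
  variables `sum s |detJ| dV` rather than inverting the field.
* SSIM: Gaussian window sigma 1.5 voxels, K1 = 0.01, K2 = 0.03, dynamic
  range = joint max - joint min, border-renormalized separable filtering.
  The canonical parameters are used because the QC rule names SSIM without
  a variant.
* U-Net: instance normalization and factor-2 trilinear up/down-sampling for
  small-batch stability; He initialization; a small-variance head so
  initial logits are near zero (maximally soft attention). Depth 3. Input
  extents must be divisible by `2^(depth-1)`; others are zero-padded and
  cropped back.
* Optimizer: Adam. The reference learning rate `1e-5` is the
  `train_config()` default; the desk-scale studies below override it.
* Ties: a zero pooled change counts as a temporal-order failure; equal
  magnitudes count as RISI failures; boundary interval ratios go to the
  lower band.

## Study sizes used by the shipped checks

The package's acceptance checks train on a 40-subject cohort (48^3 voxels,
3–4 timepoints, rates 0.5–8%/yr, fixed seeds) and evaluate on 20 held-out
subjects, with `base_channels = 4`, 32^3 training crops (random flip and
<= 8 degree rotation, shared within a pair; field vectors co-rotated),
`lr = 1e-3`, 4 epochs, <= 2 quadruples per subject per epoch. These sizes
are the package's chosen desk-scale study design: small enough to run
routinely on one CPU core, large enough that temporal-order accuracy,
interval-ratio accuracy, rate recovery (Spearman against true simulated
rates) and shrink-region heatmap enrichment are all informative. The same
configuration is exposed through the CLI defaults.

Expected behavior under this design, all recomputed at run time by
`scripts/acceptance.R` and the test suite rather than quoted from anywhere:
temporal-order accuracy >= 0.9 on pairs with r >= 2%/yr and at least a
year between scans, interval-ratio accuracy >= 0.75, rate Spearman >= 0.8,
and >= 5x shrink-heatmap enrichment inside the true tissue region.

## Known limitations

* The hand-rolled network is deliberately small; it segments
  intensity-distinct phantom structures, not MTL anatomy.
* All phantom subjects share one geometry, so the template warp only
  accounts for within-subject progression, not inter-subject registration.
* The expansion channel may bind to the blending-shell ring rather than
  the fluid region (see above); magnitude-based measures are unaffected.
* Estimated rates are proportional to, not equal to, the simulated rates:
  the learned attention region is not exactly the generating mask, so the
  normalization volume differs. Rank-based evaluation (Spearman, AUC,
  Wilcoxon) is the intended use, as it is for the real biomarker.
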