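---
title: "Measuring multi-rater variability in zonal prostate segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multi-rater variability in zonal prostate segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`raterseg` quantifies how much human raters disagree when contouring the
prostate and its transition zone on MRI, and which anatomical and
acquisition factors drive that disagreement. This vignette is the
package's methodological account: the models and conventions it
implements, the parameters that matter, what the synthetic cohort
generator does and does not emulate, and the design choices made where
several defensible options existed.

## The objects and their conventions

A segmentation is a `label_volume`: a 3D array of 0/1 voxels with a
physical spacing `(sx, sy, sz)` in mm. The package fixes one axis
convention: the third array axis is cranio-caudal, with the slice index
increasing from the apex (caudal) towards the base (cranial). All readers
normalise to it and every regional computation relies on it. Slice ranges
are expressed 1-based and inclusive — the R convention — including the
regional decomposition intervals; all third-splitting arithmetic is
tested against enumerated slice counts.

Zonal masks obey the subtraction convention of prostate reader studies:
the peripheral zone is everything in the whole gland that is not
transition zone (`derive_pz()`), with the central zone folded into the PZ
and the anterior fibromuscular stroma into the TZ. Nesting of TZ inside
WG is enforced with a configurable tolerance (default 0) because a TZ
voxel outside the WG is an annotation error, not a modelling choice.

## Agreement metrics

Three metrics summarise agreement between masks A and B:

* **DSC** `= 2|A∩B| / (|A| + |B|)` — volumetric overlap, dimensionless.
  Undefined when both masks are empty (an error, reported distinctly);
  zero when exactly one is empty.
* **HD** `= max(h(A,B), h(B,A))`, `h(A,B) = max_{a∈∂A} min_{b∈∂B} ‖a−b‖` —
  worst-case contour disagreement.
* **AHD**: the two *directed mean* boundary distances combined by their
  **maximum**. This follows the convention of the widely used
  segmentation-evaluation tooling in this field; the symmetric-mean
  variant is available (`combine = "mean"`) but is not the default.

Three conventions deserve explicit statement because published tables
rarely define them:

* **Boundary definition.** A voxel is boundary if it is foreground with at
  least one background 6-neighbour; voxels beyond the array edge count as
  background. An axis of extent 1 contributes no neighbours, so the same
  definition yields in-plane (4-neighbour) boundaries for single slices,
  which is what the slicewise metrics need. The alternative of supporting
  distances on *all* foreground voxels is kept behind `support = "all"`.
* **Units.** `"voxels"` means Euclidean distance in index space with the
  spacing ignored — the convention in which agreement tables on
  anisotropic MRI are typically printed — while `"mm"` scales each axis by
  its spacing. With isotropic spacing *s*, `HD_mm = s · HD_voxels`
  (a tested invariant).
* **Percentile.** The default is the exact (100th percentile) Hausdorff
  distance; HD95 is available via `percentile = 0.95`.

Distances are computed by an exact Euclidean distance transform (a
separable lower-envelope-of-parabolas algorithm, implemented in C++ with
per-axis weights for anisotropic grids), evaluated at the other mask's
boundary voxels. The test suite verifies exact agreement with an
all-pairs brute-force oracle on hundreds of random masks.

Slicewise (2D) metrics average the per-slice metric over axial slices:
slices where both masks are present contribute their 2D value; slices
present in exactly one mask contribute 0 to DSC and are excluded for HD
(a distance to an empty set is undefined); slices empty in both are
excluded throughout.

## STAPLE consensus

The consensus frame scores each rater against a latent reference
estimated by binary STAPLE. With rater decisions `d_ij` and a spatially
constant foreground prior γ, EM alternates:

* **E-step** — posterior that voxel *i* is truly foreground:
  `W_i = a_i / (a_i + b_i)` with
  `a_i = γ ∏_j p_j^{d_ij} (1−p_j)^{1−d_ij}` and
  `b_i = (1−γ) ∏_j (1−q_j)^{d_ij} q_j^{1−d_ij}`;
* **M-step** — `p_j = Σ_i W_i d_ij / Σ_i W_i`,
  `q_j = Σ_i (1−W_i)(1−d_ij) / Σ_i (1−W_i)`.

Numerical and design choices:

* Initialisation `p_j = q_j = 0.99999`, the classic choice of the
  reference algorithm; convergence when no parameter moves by more than
  `tol = 1e-7` between iterations (at most `max_iter = 100`, with a
  warning and `converged = FALSE` otherwise).
* The prior γ defaults to the mean foreground fraction across raters
  within the computation region (`"sample-mean"`), the common unsupervised
  choice; any fixed value in (0, 1) can be supplied.
* Computation is restricted to the bounding box of the union of the
  masks dilated by `margin = 10` voxels. A whole-field-of-view background
  would inflate the specificities towards 1 and shift γ by orders of
  magnitude; the margin makes the estimates reflect the neighbourhood of
  the structure. The margin is configurable and the posterior outside the
  box is 0.
* Voxels are compressed to unique rater-decision patterns (at most 2^J),
  making EM cost independent of volume size after one pass.
* The consensus mask thresholds the posterior at 0.5, with ties counted
  as foreground for determinism.

On synthetic cohorts the consensus mask is systematically closer to the
ground truth than individual raters, and consensus-frame DSC exceeds
pairwise DSC on average — the qualitative signature reported by reader
studies using this design.

## Regional decomposition

The cranio-caudal extent of a comparison is split into three contiguous
thirds — apex, mid-gland, base — of `floor(L/3)`, `L − 2·floor(L/3)`,
`floor(L/3)` slices. Remainder slices go to the mid-gland so the extreme
regions, which carry the effect of interest, stay equal-sized. For
pairwise comparisons the extent is the **union** of the two masks'
extents (the symmetric choice; per-mask limits would make a symmetric
metric asymmetric, and `pair_extent = "intersection"` preserves the
alternative). For consensus comparisons the limits come from the
consensus mask alone. Empty-region policy: both sub-masks empty — the
record is skipped with a reason; exactly one empty — DSC 0, distances
skipped. The three sub-masks tile the original mask exactly within the
extent, so regional intersections sum to the whole-gland intersection (a
tested invariant).

## Morphology covariates

Two per-case covariates are computed for the variability correlations:

* the clinical ellipsoid volume `V = length × width × height × 0.52`
  (dimensions in cm). Dimensions are normally user- or generator-supplied
  calliper measurements; a mask-derived surrogate (extents along the
  mask's principal axes) is provided for convenience and labelled as
  such. Both the mean and the median of per-rater volume estimates are
  reported, since reader studies summarise them inconsistently.
* the squared TZ-to-PZ contrast `((SI_TZ − SI_PZ)/(SI_TZ + SI_PZ))²`,
  scale-invariant and in [0, 1], from mean signal in spherical ROIs
  (default radius 3 mm — a sphere because it is orientation-free; the
  radius shrinks to the zone's clearance when the zone is thin, and
  `suggest_roi_centers()` places ROIs at the deepest interior points of
  the TZ and PZ).

## Statistical layer

The aggregation unit is the **case**: values are averaged over the 21
rater pairs (or over a group's raters) within each case before any test,
because cases — not pairs — are the independent samples; pooling pairs
would pseudo-replicate. A test asserts the two weightings differ where
they should.

* Related samples (WG vs TZ, region vs region, 2D vs 3D, group vs group):
  two-sided paired Wilcoxon signed-rank with **Pratt** handling of zero
  differences (zeros are ranked, then discarded from the statistic),
  exact null distribution when there are no zeros or ties and n ≤ 25,
  otherwise a continuity-corrected normal approximation with zero and tie
  variance corrections. Pratt handling is implemented in-package because
  the standard R test drops zeros before ranking; the no-zero path is
  verified against `stats::wilcox.test` to 1e-8 and the zero path
  against an independent reference value.
* Independent samples (binary factors such as a suspicious lesion or a
  protruding median lobe): two-sided Mann-Whitney U.
* Correlations: Spearman ρ with average ranks, two-sided p from the
  t-approximation, and a 95% CI from the Fisher transform with standard
  error `1/√(n−3)`.
* Multiplicity: Holm-Bonferroni within each analysis family. A family is
  one block of related contrasts as presented together in a report: the
  three metrics for a structure comparison, the three region pairs, the
  three group contrasts per metric, the three metric correlations per
  covariate. The family layout is a reconstruction — reader studies
  rarely enumerate their families — and the functions accept any subset
  of records, so other layouts are possible. On null simulations the
  layer's rejection rate at nominal 0.05 stays below 0.07 (tested over
  200 replicates).

## The synthetic cohort generator

Clinical multi-rater MRI datasets of this kind are generally not
deposited, so the package ships a generator whose defaults emulate the
study conditions of a 40-case, 7-rater reader study, and whose latent
truth enables parameter-recovery testing:

* **Ground truth.** The gland is a superellipsoid (exponent drawn in
  [2, 2.6], mildly anisotropic semi-axes) with a band-limited radial
  perturbation: a smooth random field on the sphere spanned by first- and
  second-order spherical-harmonic-style terms, RMS 0.07 of the radius.
  Gland volumes are drawn log-uniformly over 15–199 cm³ (the clinical
  range, right-skewed as observed); the TZ is a nested concentric blob at
  a volume fraction drawn from 0.25–0.55, offset anteriorly, clipped to
  the gland, and calibrated so the realised fraction lands within a few
  percent. Radial scales are calibrated against the voxelised volume, so
  realised volumes match their targets within 5%.
* **Intensity.** A two-zone image (PZ at 100, TZ hypointense as on
  T2-weighted MRI, background 30, Gaussian noise σ = 4) whose noiseless
  squared contrast equals the case's target exactly — the generator picks
  `SI_TZ = SI_PZ (1−√C)/(1+√C)`.
* **Raters.** Disagreement is modelled as a smooth random radial
  displacement field of the boundary with RMS amplitude
  `boundary_noise_mm`, plus an optional constant bias. Spatial
  correlation along the contour is essential: i.i.d. voxel flips would
  make Hausdorff distances meaningless. Because masks are star-shaped
  level sets of a radial function, simulated masks are always connected.
  The default roster is 3 experts / 2 seniors / 2 juniors at 1.0 / 1.2 /
  1.3 mm — close group-level noise, as the near-equal group DSCs of
  reader studies suggest. The amplitude is multiplied by
  `extreme_slice_noise_multiplier` (default 1.5) on the apical and basal
  thirds, where contouring is anatomically hardest.
* **Noise scaling.** Noise is a fixed *absolute* (mm) amplitude, not
  proportional to gland size, so the well-known volume-agreement
  relationship (small glands agree less in DSC) **emerges** from geometry
  instead of being assumed. `contrast_noise_coupling` optionally scales a
  case's amplitude by `1 + coupling · (1 − √contrast)`, encoding that
  poorly differentiated glands are harder to contour.
* **Determinism.** Every draw comes from a counter-based stream derived
  from `(seed, case index, purpose)`, so the cohort is a pure function of
  the spec and adding cases or raters never perturbs earlier ones. The
  latent geometry is drawn before voxelisation, so the same seed yields
  the same continuous gland at any voxel spacing — which is how the
  thick-slice "2D sequence" arm produces paired acquisitions of the same
  anatomy.

What the generator does **not** emulate: realistic MRI texture, rater
style (systematic shape preferences rather than random fields),
pathology-driven deformation (tumours, protruding median lobes),
registration or motion artefacts. Tests passing on synthetic cohorts
therefore validate the *analysis machinery* and directions of effect, not
clinical effect sizes.

## Experiment design in the validation suite

The validation experiments run at reduced problem sizes chosen for a
single-CPU workflow: cohorts of 10–20 cases on a coarse anisotropic grid
(1.5 × 1.5 × 3 mm), where a 200 cm³ gland spans roughly 10⁵ voxels. At
this resolution the absolute DSC level is lower than at sub-millimetre
clinical resolution (boundary voxels are a larger volume fraction), which
is why directions of effect, not absolute levels, are the tested claims.

One confound deserves note. In the generator the volume-DSC relationship
is very strong (Spearman ρ ≈ 0.99 across the full 15–199 cm³ range), much
stronger than in clinical data, and at n = 20 it can mask the weaker
contrast-coupling effect. The contrast experiment therefore narrows the
volume range to 40–80 cm³ — standard confound control, isolating the
mechanism under test — and then recovers a robustly positive
contrast-agreement correlation of the magnitude reader studies report.

## Known limitations

* STAPLE is the binary, spatially-constant-prior variant; multi-label
  fusion and spatial priors are out of scope, and exact numerical parity
  with other STAPLE implementations is not promised (agreement is asserted
  at the consensus-mask level, DSC ≥ 0.99, in a cross-check test).
* Readers normalise axis order by convention rather than by full
  orientation-matrix handling; DICOM series, registration and resampling
  between mismatched geometries are out of scope.
* The `"voxels"` distance unit ignores spacing by design; on anisotropic
  grids it is not a physical distance and must not be compared across
  acquisitions with different spacing.
* Features beyond volume and contrast (lesion and median-lobe flags) are
  input annotations, not image-derived quantities.
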