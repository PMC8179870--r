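# raterseg

Inter-rater variability analysis for zonal prostate segmentation on MRI.

Manual delineation of the prostate — the whole gland (WG) and its
transition zone (TZ), with the peripheral zone obtained as PZ = WG ∖ TZ —
is the reference standard behind most automated prostate-MRI pipelines, yet
raters disagree, and the disagreement is structured: it grows towards the
gland's base and apex, in small glands, and where the zonal contrast is
poor. `raterseg` provides the full analysis toolkit used in multi-reader
agreement studies of this kind, for R users working with 3D label volumes:

- **Label fusion.** Binary STAPLE (Simultaneous Truth and Performance Level
  Estimation): an EM algorithm that estimates a probabilistic consensus
  segmentation together with each rater's sensitivity *p_j* and specificity
  *q_j*.
- **Agreement metrics.** Dice score `DSC = 2|A∩B| / (|A|+|B|)`, Hausdorff
  distance `HD = max(h(A,B), h(B,A))` with
  `h(A,B) = max_{a∈∂A} min_{b∈∂B} ‖a−b‖`, and average Hausdorff distance
  (directed means combined by their maximum) — in 3D or per axial slice, in
  voxel or millimetre units, in a pairwise frame (all rater pairs) or a
  consensus frame (each rater against the STAPLE mask).
- **Regional decomposition.** The cranio-caudal extent split into apex /
  mid-gland / base thirds, with the pairwise (union-extent) and consensus
  limit conventions.
- **Morphology covariates.** The clinical ellipsoid volume estimate
  `V = length × width × height × 0.52` and the squared TZ-to-PZ signal
  contrast `((SI_TZ − SI_PZ)/(SI_TZ + SI_PZ))²` from spherical ROIs.
- **Statistics.** Paired Wilcoxon signed-rank (Pratt zero handling),
  Mann-Whitney U, Spearman ρ with Fisher-z CI, all two-sided, with
  Holm-Bonferroni correction per analysis family; aggregation is
  case-first (mean over the 21 rater pairs within a case before any test).
- **Synthetic cohorts.** A generator of multi-rater WG/TZ label volumes and
  two-zone intensity images with spatially correlated boundary noise, so
  the entire analysis is testable end-to-end without clinical data.

Masks are read and written as NIfTI-1 (`.nii`/`.nii.gz`), NRRD or
MetaImage (`.mha`/`.mhd`), with cohorts described by a CSV manifest
(`case_id,rater_id,experience_group,structure,sequence_type,path`).

## Worked example

```r
library(raterseg)

spec  <- cohort_spec(n_cases = 2, spacing_mm = c(1.5, 1.5, 3), seed = 42)
truth <- make_truth(spec, 1)
truth
#> <ground_truth_case> #1: WG 90.7 cm^3 (target 90.7), TZ fraction 0.48, contrast 0.270

masks <- lapply(1:7, function(ri)
  simulate_rater(truth, spec$raters[ri, ], "WG", 1000L + ri))
names(masks) <- spec$raters$rater_id

cons <- staple(masks)
cons
#> <staple_result> 7 raters, 11 EM iterations (converged), prior 0.0942, |consensus| = 14165
#>   rater_id sensitivity specificity
#> 1       r1   0.9546206   0.9987671
#> 2       r2   0.9220795   0.9969080
#> ...

mean(combn(7, 2, function(ij) dice(masks[[ij[1]]], masks[[ij[2]]])))
#> [1] 0.9164   # mean pairwise DSC
mean(sapply(masks, function(m) compare_to_consensus(m, cons, "DSC")))
#> [1] 0.9449   # mean consensus-frame DSC (higher, as expected)
dice(cons$consensus, truth$true_wg)
#> [1] 0.9592   # the consensus is closer to the truth than typical raters

dec <- decompose(list(masks$r1, masks$r7))
regional_metrics(masks$r1, masks$r7, dec, "DSC")
#>   region     value reason
#> 1   apex 0.8316677   <NA>
#> 2    mid 0.9644891   <NA>
#> 3   base 0.8848561   <NA>
hausdorff(masks$r1, masks$r7, "mm")
#> [1] 6       # worst-case contour disagreement in mm
```

The mid-gland third agrees best and the extremes worst — the hallmark
spatial pattern of prostate contouring variability. A full study
(consensus, metrics, regional split, covariates, statistics, CSV/JSON
reports) runs with:

```r
res <- run_study(run_config(cohort = cohort_spec(seed = 1), out_dir = "out"))
```

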