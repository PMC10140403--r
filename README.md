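# lfafcm

Energy-minimization segmentation of skull-stripped brain MRI into
cerebrospinal fluid (CSF), gray matter (GM) and white matter (WM), for
researchers who need automated tissue volumetry on T1-weighted images —
including images degraded by multiple-sclerosis (MS) lesions, where naive
clustering misassigns lesioned WM to GM.

## Methods

All segmenters minimize a fuzzy C-means (FCM) energy over per-voxel class
memberships `u_jk` (rows summing to 1) and class centroids `v_k`, with
`d_jk = |y_j − v_k|` the distance of voxel intensity `y_j` to centroid
`v_k` and fuzziness exponent `q > 1`:

* **FCM** — the classical objective `J = Σ_j Σ_k u_jk^q d_jk²`.
* **RFCM** — adds a Markov-random-field-like neighborhood penalty
  `(β/2) Σ_j Σ_k u_jk^q Σ_{l∈N_j} Σ_{m≠k} u_lm^q` over the 6-connected
  neighbors `N_j`, discouraging label disagreement between adjacent
  voxels (noise robustness at the price of boundary smoothing).
* **AR-FCM** — replaces the neighborhood term with a statistical-atlas
  constraint `γ Σ_j Σ_k u_jk^q (1 − π_jk)^w`, where `π_jk` is the
  probability of class `k` at voxel `j` under a pre-registered
  probabilistic tissue atlas; after defuzzification, boundary voxels are
  re-assigned to `argmax_k u_jk·m_jk` using a morphological label
  probability `m_jk`, countering partial-volume effects.
* **LFA-FCM** — the lesion-aware pipeline: coarse FCM on T1 → FLAIR
  hyperintensity screening against coarse-GM statistics
  (`FLAIR > μ_GM + α·σ_GM`, intersected with GM∪WM, small components
  removed) → S-Lesion-Filling of T1 lesion voxels with draws from
  `Normal(μ_NAWM, σ_NAWM/2)` per axial slice (NAWM = normal-appearing
  white matter) → AR-FCM on the filled image → boundary redistribution.

Evaluation uses the Dice similarity coefficient and volumetric similarity
(both ×100) and the 95th-percentile symmetric surface distance (HD95, mm),
computed per tissue. A seeded synthetic phantom generator (nested-ellipsoid
geometry, bias field, Gaussian noise, WM lesions hypointense on T1 /
hyperintense on FLAIR, atlas = smoothed ground truth) makes every stage
testable at desk scale.

## Worked example

```r
library(lfafcm)

spec   <- phantom_spec(shape = c(48, 48, 48), noise_sigma = 0.05,
                       lesion_count = 3, seed = 42)
bundle <- generate_phantom(spec)
bundle
#> <phantom_bundle> 48x48x48, 41616 masked voxels, 99 lesion voxel(s), seed 42

res <- run_lfa_fcm(bundle$t1, bundle$flair, bundle$atlas, bundle$mask)
coef(res$fit)
#>       CSF        GM        WM
#> 0.2001567 0.4987145 0.7981474

evaluate_segmentation(res$labels, bundle$gt_labels, spec$spacing)
#>   class      dsc        vs hd95
#> 1   CSF 99.99430  99.99430    0
#> 2    GM 99.98430 100.00000    0
#> 3    WM 99.99118  99.99118    0

dice_score(res$lesions, bundle$lesion_gt)
#> [1] 100
```

The fitted centroids recover the phantom's tissue means (0.2, 0.5, 0.8 on
the normalized intensity scale), all three tissues are segmented with
Dice ≈ 100 despite the lesions, and the FLAIR screening recovered the
lesion mask exactly. `summary()`, `plot()` (objective trace) and
`fitted()` (membership field) are available on every fit object.

## Command line

A thin Rscript wrapper over the same functions lives in
`inst/cli/lfafcm.R`:

```sh
Rscript inst/cli/lfafcm.R phantom --seed 1 --out-dir ph
Rscript inst/cli/lfafcm.R segment --method lfafcm --t1 ph/t1.nii.gz \
    --flair ph/flair.nii.gz --atlas ph/atlas.nii.gz --mask ph/mask.nii.gz \
    --seed 1 --out-prefix out
Rscript inst/cli/lfafcm.R eval --seg out_labels.nii.gz \
    --gt ph/gt_labels.nii.gz --out report.csv
```

Each `segment` run writes a JSON run-report with every effective
parameter, the per-iteration objective trace and per-stage timings;
identical (config, seed) reruns are bit-identical.

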