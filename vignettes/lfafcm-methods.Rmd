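---
title: "Energy-minimization brain MRI segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-minimization brain MRI segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in **lfafcm**, the
parameters that matter, the numerical conventions the code commits to,
and the choices made where the design was genuinely open.

## The clustering models

Segmentation is cast as energy minimization over fuzzy memberships
$u_{jk} \in [0,1]$ (one row per masked voxel $j$, one column per tissue
class $k \in \{\mathrm{CSF}, \mathrm{GM}, \mathrm{WM}\}$, rows summing
to 1) and scalar class centroids $v_k$, with $d_{jk} = |y_j - v_k|$ on
intensities $y_j$ normalized to $[0,1]$.

**FCM.**
$J = \sum_j \sum_k u_{jk}^q\, d_{jk}^2$.
Alternating the closed-form membership and centroid updates is exact
coordinate descent, so the objective is non-increasing by construction.

**RFCM** adds the neighborhood penalty
$\frac{\beta}{2} \sum_j \sum_k u_{jk}^q \sum_{l \in N_j} \sum_{m \neq k} u_{lm}^q$
with $N_j$ the 6-connected masked neighbors. The membership update
$u_{jk} \propto (d_{jk}^2 + \beta \sum_{l \in N_j} \sum_{m \neq k}
u_{lm}^q)^{-1/(q-1)}$ evaluates the neighbor memberships at the previous
iteration. Because the penalty couples memberships across voxels, this
simultaneous update is not guaranteed to descend on arbitrary data; the
engine therefore accepts a membership step only if the full objective
does not increase, halving the step toward the current memberships
(t = 1, 1/2, …, 1/16, then 0) otherwise. On spatially coherent images
the full step is virtually always accepted, so the scheme changes
nothing in practice there while making the objective trace monotone
(within floating-point tolerance) on any input — including spatially
uncorrelated noise, where the undamped update oscillates.

**AR-FCM** replaces the neighborhood term with an additive atlas
constraint
$\gamma \sum_j \sum_k u_{jk}^q (1 - \pi_{jk})^w$,
where $\pi_{jk}$ is the statistical-atlas prior of class $k$ at voxel
$j$. The constraint term is fixed per voxel, so each iteration is again
exact alternating minimization and monotonicity is structural. The form
of the constraint — an additive penalty that *replaces* the spatial
term, with weight $\gamma$ and exponent $w$ on $(1-\pi)$ — was an open
design point: the parameter tables that specify AR-FCM list exactly
$\{\gamma, w\}$ and drop $\beta$, which is what this reading encodes.
The term is isolated in one place in `fit_arfcm()` so alternative forms
can be swapped in.

After defuzzification (`hard_labels()`, maximum membership, ties to the
lower class index), **boundary redistribution** re-assigns every masked
voxel that touches a different nonzero label through a 6-neighbor to
$\arg\max_k u_{jk} m_{jk}$, where $m_{jk}$ is a morphological label
probability. Whether the morphological map is a distinct atlas product
or derived from the statistical atlas was left open by the source
method; here it is an interchangeable second `prob_atlas` argument that
defaults to the statistical atlas.

**LFA-FCM** chains: coarse FCM on T1 → FLAIR lesion screening →
S-Lesion-Filling of T1 → AR-FCM on the filled image → boundary
redistribution. The coarse stage is plain FCM (the minimal "clustered
segmentation" reading; nothing in the pipeline depends on the coarse
stage being spatially regularized, it only has to supply approximate GM
and WM masks).

## Parameters

| parameter | meaning | default | units / scale |
|---|---|---|---|
| `q` | fuzziness exponent | 2 | dimensionless, > 1 |
| `beta` | spatial penalty weight (RFCM) | 1 | on squared normalized intensity |
| `gamma` | atlas penalty weight (AR-FCM) | 0.025 | on squared normalized intensity |
| `w` | atlas penalty exponent | 1 | dimensionless |
| `n` | iteration cap | 500 (RFCM), 200 (AR-FCM/LFA-FCM) | count |
| `thr` | convergence threshold on max centroid change | 0.001 | normalized intensity |
| `alpha` | FLAIR threshold multiplier | 2 | GM standard deviations |
| `min_size` | minimum lesion component | 10 | voxels, 26-connectivity |

The method defaults reproduce the published parameter tables of the
underlying algorithms. They are only meaningful on a fixed intensity
scale, which is why `normalize_intensities()` clips masked intensities
to their 1st–99th percentiles and maps that range onto $[0,1]$: `gamma`
then competes with squared distances bounded by 1, and `thr` is a
thousandth of the full intensity range. Normalization is idempotent on
data already spanning $[0,1]$ with ≥ 1% mass at each end.

The lesion screening rule `FLAIR > μ_GM + α·σ_GM` encodes the clinical
contrast observation that MS lesions are hyperintense relative to GM on
FLAIR while CSF is suppressed; the reference statistics come from the
coarse GM segmentation. The published pipeline states only that the
GM-related part is selected and "filtering conditions" applied; here the
conditions are concrete and configurable: intersection with the coarse
GM∪WM region (CSF excluded) and removal of 26-connected components
smaller than `min_size` voxels. Screening is monotone in `alpha` by
construction.

**S-Lesion-Filling.** For each axial slice (third array axis) containing
lesion voxels, NAWM = WM minus lesions; lesion intensities are replaced
by independent draws from $\mathcal{N}(\mu_{\mathrm{NAWM}},
\sigma_{\mathrm{NAWM}}/2)$ computed on that slice. The source
description contradicts itself about the standard deviation ("half of
the calculated NAWM standard deviation" vs "fixed to half of the WM
mean"); the first, data-driven reading is implemented. Draws are not
clipped: with a normal distribution essentially all filled values fall
within $\mu \pm 3\sigma_{\mathrm{NAWM}}$, and clipping would bias the
filled-voxel statistics that the validation suite checks. A slice whose
NAWM set is empty falls back to volume-global NAWM statistics (flagged
in the result). One RNG stream is seeded per `slf_fill()` call; slices
are processed in ascending index and voxels in R's native array order,
so a fixed seed reproduces the output bit-exactly across platforms, and
the caller's RNG state is restored afterwards.

## Numerical conventions

* **Initialization** is deterministic: FCM/RFCM centroids start at the
  $(1..K)/(K{+}1)$ masked-intensity quantiles; AR-FCM starts at the
  atlas-weighted means $v_k = \sum_j \pi_{jk} y_j / \sum_j \pi_{jk}$
  when $\gamma > 0$. With $\gamma = 0$ the atlas is inert and the
  quantile initialization applies, which makes `fit_arfcm(gamma = 0)`,
  `fit_rfcm(beta = 0)` and `fit_fcm()` bitwise-identical reductions of
  one engine.
* **Convergence** is declared when the largest centroid change drops
  below `thr`; centroids are sorted ascending on return so class 1/2/3
  always mean CSF/GM/WM on T1 contrast, whatever the internal order the
  optimizer visited (permuting atlas channels permutes nothing after
  sorting).
* **Singularity convention:** a voxel whose combined cost
  $d_{jk}^2 + \text{penalty}_{jk}$ is exactly zero receives one-hot
  membership on the first such class.
* **Ties** in `hard_labels()` and boundary redistribution break toward
  the lower class index.
* **Metrics:** Dice and volumetric similarity are reported ×100; both
  masks empty is perfect agreement for Dice (100) but an error for
  volumetric similarity (its denominator vanishes). HD95 extracts
  surface voxels (a masked voxel with a 6-neighbor outside the mask,
  array borders counting as outside), measures center-to-center
  distances in mm using the header spacing, pools both directed nearest-
  neighbor distance sets and takes the 95th percentile with linear
  interpolation between order statistics (`quantile(type = 7)`) — fixed
  here for bit-reproducibility. The published distance formula prints a
  classical max–min Hausdorff form, but its accompanying text specifies
  the 95th percentile; the percentile variant is implemented. Distances
  are computed by exact chunked nearest-neighbor search, which is
  simple, dependency-free and fast enough at the surface sizes the
  package targets; the test suite checks it against all-pairs
  brute-force references.
* **Statistics** use the population convention (divide by the count, not
  count − 1) for all NAWM and GM reference moments, so degenerate
  two-voxel examples have exact closed forms.

## The phantom generator

`generate_phantom()` builds nested ellipsoids — a WM core inside a GM
ribbon inside a CSF shell, plus a central CSF ventricle — within an
ellipsoidal brain mask, then writes lesions, bias and noise in that
order, all driven by one seed. Defaults: tissue means (0.2, 0.5, 0.8) on
T1 and (0.15, 0.55, 0.45) on FLAIR (CSF suppressed, GM brightest);
lesions are spheres placed rejection-wise fully inside WM with a
one-voxel halo so distinct lesions stay 26-disconnected, hypointense on
T1 at the GM level — deliberately recreating the failure mode where an
atlas-constrained fit without filling mislabels lesioned WM as GM — and
hyperintense on FLAIR (0.9). The bias field is a separable low-frequency
sinusoid product scaled to peak deviation `bias_amplitude`; noise is
additive Gaussian. The atlas is the per-class one-hot ground truth
smoothed with an isotropic Gaussian (default σ = 2 voxels) and
renormalized per voxel.

The canonical validation suite (`default_validation_suite()`) fixes the
study conditions: (a) a clean 48³ phantom, (b) a noisy 48³ phantom at
σ = 0.08, and (c) a lesioned 64³ phantom at σ = 0.05 with five lesions
of radius 2–4 voxels. These sizes keep every suite computation at desk
scale (each full fit takes seconds) while leaving thousands of boundary
voxels per tissue interface.

What the phantom does *not* emulate: anatomical cortical folding,
partial-volume mixing along oblique boundaries (interfaces are hard
label steps blurred only by noise), Rician noise statistics (Gaussian is
used so the fitters' behavior stays analytically predictable),
registration error between atlas and subject, and skull/extra-cerebral
tissue. Passing the suite therefore demonstrates internal correctness
and the claimed orderings under controlled conditions, not clinical
accuracy on real MRI.

## Observed model behavior and limitations

Two properties of the *models* (not implementation artifacts) are worth
stating because the validation suite surfaces them:

* With β = 1 on the normalized scale, the RFCM neighborhood penalty
  (up to 6β per class) dominates squared intensity distances (≤ 1). The
  penalty then acts as a curvature-shrinking prior: isolated noise
  voxels are correctly absorbed, but protruding voxels on curved tissue
  interfaces are relabeled to the majority neighbor class even on a
  noiseless image, and the one-to-three-voxel-thin CSF shell is
  systematically eroded in favor of GM. On the validation phantoms RFCM
  consequently improves WM Dice over FCM under noise while *losing* CSF
  Dice, and does not reproduce the clean phantom exactly (FCM, AR-FCM
  and LFA-FCM do). This is consistent with the boundary sensitivity of
  penalty-term clustering that motivates the atlas-constrained variant
  in the first place.
* The AR-FCM atlas term is additive and voxel-separable, so its
  benefits depend entirely on atlas quality; with the phantom's
  smoothed-ground-truth atlas it is close to an upper bound on what a
  registered population atlas could provide on real data.

Other limitations: no bias-field correction stage exists (the bias
amplitude in the phantom exercises robustness only); atlas-to-subject
registration and skull stripping are out of scope (inputs are assumed
brain-extracted and atlas-aligned); exactly three tissue classes are
supported end-to-end; and the lesion screening is a single global
threshold per volume, not a trained lesion segmenter.
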