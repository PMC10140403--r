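#' Synthetic brain phantom specification
#'
#' Parameters of the seeded T1/FLAIR phantom used for desk-scale
#' validation of the segmentation stack.  The geometry is a set of
#' nested ellipsoids: a WM core wrapped in a GM ribbon wrapped in a CSF
#' shell, plus a central CSF ventricle, all inside an ellipsoidal brain
#' mask.  Optional WM lesions are hypointense on T1 (near the GM level,
#' so an atlas-constrained fit without filling mislabels them GM) and
#' hyperintense on FLAIR.
#'
#' @param shape grid dimensions (3 integers).
#' @param spacing voxel size in mm per axis.
#' @param t1_means per-tissue T1 intensities (CSF, GM, WM), strictly
#'   increasing, normalized units.
#' @param flair_means per-tissue FLAIR intensities (CSF suppressed, GM
#'   brightest, WM intermediate).
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param bias_amplitude peak deviation of the smooth multiplicative
#'   bias field from 1, in \[0, 1).
#' @param lesion_count number of non-overlapping WM lesion spheres.
#' @param lesion_radius_range integer radius range in voxels.
#' @param lesion_t1_intensity,lesion_flair_intensity lesion intensities
#'   written into T1 / FLAIR before bias and noise.
#' @param atlas_smoothing_sigma Gaussian sigma (voxels) applied to the
#'   one-hot ground truth to form the probabilistic atlas.
#' @param seed RNG seed; the bundle is fully determined by it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                         t1_means = c(0.2, 0.5, 0.8),
                         flair_means = c(0.15, 0.55, 0.45),
                         noise_sigma = 0.05, bias_amplitude = 0,
                         lesion_count = 0L, lesion_radius_range = c(2L, 4L),
                         lesion_t1_intensity = 0.5,
                         lesion_flair_intensity = 0.9,
                         atlas_smoothing_sigma = 2, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stopf("shape must be 3 integers >= 8")
  if (any(diff(t1_means) <= 0)) stopf("t1_means must be strictly increasing")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stopf("bias_amplitude must be in [0, 1)")
  if (lesion_count < 0) stopf("lesion_count must be >= 0")
  rr <- as.integer(lesion_radius_range)
  if (length(rr) != 2L || rr[1] < 1L || rr[2] < rr[1])
    stopf("lesion_radius_range must be two integers >= 1, non-decreasing")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 t1_means = t1_means, flair_means = flair_means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_range = rr,
                 lesion_t1_intensity = lesion_t1_intensity,
                 lesion_flair_intensity = lesion_flair_intensity,
                 atlas_smoothing_sigma = atlas_smoothing_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid geometry fractions (of the half-extent per axis).
PHANTOM_GEOM <- list(brain = c(0.92, 0.85, 0.92),
                     csf_inner = 0.84,   # GM outer boundary (fraction of brain radius)
                     gm_inner = 0.66,    # WM outer boundary
                     ventricle = c(0.22, 0.18, 0.26))

#' Generate a synthetic phantom bundle
#'
#' Builds the tissue geometry of [phantom_spec], writes lesion
#' intensities into T1/FLAIR, applies a smooth low-frequency
#' multiplicative bias field and additive Gaussian noise inside the
#' brain mask, and derives the probabilistic atlas as the Gaussian-
#' smoothed one-hot ground truth, renormalized per voxel.
#'
#' @param spec a [phantom_spec].
#' @return a `phantom_bundle`: `t1`, `flair` ([mri_volume]s),
#'   `gt_labels` (integer array), `lesion_gt`, `mask` (logical arrays),
#'   `atlas` ([prob_atlas]), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  g <- PHANTOM_GEOM
  # ribbon thickness feasibility (voxels) on the tightest axis
  half <- d / 2
  shell_vox <- min((1 - g$csf_inner) * g$brain * half,
                   (g$csf_inner - g$gm_inner) * g$brain * half)
  if (shell_vox < 1)
    stopf("geometry infeasible for shape %s: tissue ribbon thinner than 1 voxel",
          paste(d, collapse = "x"))

  ax <- lapply(1:3, function(i) (seq_len(d[i]) - (d[i] + 1) / 2) / (d[i] / 2))
  # normalized ellipsoidal radius of the brain surface, and the ventricle
  e2 <- outer(outer((ax[[1]] / g$brain[1])^2, (ax[[2]] / g$brain[2])^2, `+`),
              (ax[[3]] / g$brain[3])^2, `+`)
  e <- sqrt(e2)
  v2 <- outer(outer((ax[[1]] / g$ventricle[1])^2,
                    (ax[[2]] / g$ventricle[2])^2, `+`),
              (ax[[3]] / g$ventricle[3])^2, `+`)
  mask <- e <= 1
  gt <- array(0L, d)
  gt[mask] <- TISSUE_LABELS["CSF"]
  gt[e <= g$csf_inner] <- TISSUE_LABELS["GM"]
  gt[e <= g$gm_inner] <- TISSUE_LABELS["WM"]
  gt[v2 <= 1 & mask] <- TISSUE_LABELS["CSF"]   # central ventricle

  lesion <- array(FALSE, d)
  t1 <- array(0, d); fl <- array(0, d)
  with_private_seed(spec$seed, {
    if (spec$lesion_count > 0) {
      wm_idx <- which(gt == TISSUE_LABELS["WM"])
      wm_co <- arrayInd(wm_idx, d)
      placed <- 0L
      tries <- 0L
      while (placed < spec$lesion_count) {
        tries <- tries + 1L
        if (tries > 2000L)
          stopf("could not place %d lesions in the WM region", spec$lesion_count)
        r <- if (spec$lesion_radius_range[1] == spec$lesion_radius_range[2])
          spec$lesion_radius_range[1] else
          sample(spec$lesion_radius_range[1]:spec$lesion_radius_range[2], 1L)
        ctr <- wm_co[sample.int(nrow(wm_co), 1L), ]
        # sphere voxels; the +1 halo keeps distinct lesions 26-disconnected
        off <- expand.grid(dx = -(r + 1):(r + 1), dy = -(r + 1):(r + 1),
                           dz = -(r + 1):(r + 1))
        rad2 <- off$dx^2 + off$dy^2 + off$dz^2
        core <- as.matrix(off[rad2 <= r^2, ])
        halo <- as.matrix(off[rad2 <= (r + 1)^2, ])
        cv <- sweep(core, 2, ctr, `+`)
        hv <- sweep(halo, 2, ctr, `+`)
        if (any(hv < 1) || any(sweep(hv, 2, d, `>`))) next
        ci <- cv[, 1] + (cv[, 2] - 1) * d[1] + (cv[, 3] - 1) * d[1] * d[2]
        hi <- hv[, 1] + (hv[, 2] - 1) * d[1] + (hv[, 3] - 1) * d[1] * d[2]
        if (any(gt[ci] != TISSUE_LABELS["WM"])) next
        if (any(lesion[hi])) next
        lesion[ci] <- TRUE
        placed <- placed + 1L
      }
    }
    t1[mask] <- spec$t1_means[gt[mask]]
    fl[mask] <- spec$flair_means[gt[mask]]
    t1[lesion] <- spec$lesion_t1_intensity
    fl[lesion] <- spec$lesion_flair_intensity
    if (spec$bias_amplitude > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      f <- outer(outer(sin(pi * ax[[1]] + ph[1]), sin(pi * ax[[2]] + ph[2])),
                 sin(pi * ax[[3]] + ph[3]))
      f <- f / max(abs(f))
      bias <- 1 + spec$bias_amplitude * f
      t1[mask] <- t1[mask] * bias[mask]
      fl[mask] <- fl[mask] * bias[mask]
    }
    if (spec$noise_sigma > 0) {
      nm <- sum(mask)
      t1[mask] <- t1[mask] + stats::rnorm(nm, 0, spec$noise_sigma)
      fl[mask] <- fl[mask] + stats::rnorm(nm, 0, spec$noise_sigma)
    }
  })

  probs <- array(0, c(d, 3L))
  for (k in 1:3) {
    oh <- array(as.numeric(gt == k), d)
    probs[, , , k] <- if (spec$atlas_smoothing_sigma > 0)
      gaussian_smooth_3d(oh, spec$atlas_smoothing_sigma) else oh
  }
  atlas <- normalize_atlas(probs, mask)
  # outside the mask the prior is meaningless; zero it for tidy files
  for (k in 1:3) {
    pk <- atlas$probs[, , , k]
    pk[!mask] <- 0
    atlas$probs[, , , k] <- pk
  }

  structure(list(t1 = mri_volume(t1, spec$spacing),
                 flair = mri_volume(fl, spec$spacing),
                 gt_labels = gt, lesion_gt = lesion, mask = mask,
                 atlas = atlas, spec = spec),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %s, %d masked voxels, %d lesion voxel(s), seed %d\n",
              paste(dim(x$gt_labels), collapse = "x"), sum(x$mask),
              sum(x$lesion_gt), x$spec$seed))
  invisible(x)
}

#' Canonical validation phantom specifications
#'
#' The three phantoms the validation and acceptance runs use:
#' (a) a clean 48^3 phantom (no noise, no bias, no lesions),
#' (b) a noisy 48^3 phantom (sigma = 0.08),
#' (c) a lesioned 64^3 phantom (sigma = 0.05, 5 lesions of radius 2–4).
#'
#' @param seed RNG seed stored in each spec.
#' @return named list of three [phantom_spec]s (`clean`, `noisy`,
#'   `lesioned`).
#' @export
default_validation_suite <- function(seed = 1L) {
  list(
    clean = phantom_spec(shape = c(48L, 48L, 48L), noise_sigma = 0,
                         bias_amplitude = 0, lesion_count = 0L, seed = seed),
    noisy = phantom_spec(shape = c(48L, 48L, 48L), noise_sigma = 0.08,
                         bias_amplitude = 0, lesion_count = 0L, seed = seed),
    lesioned = phantom_spec(shape = c(64L, 64L, 64L), noise_sigma = 0.05,
                            bias_amplitude = 0, lesion_count = 5L,
                            lesion_radius_range = c(2L, 4L), seed = seed))
}
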