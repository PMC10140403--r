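#' Lesion screening and filling configuration
#'
#' @param alpha FLAIR hyperintensity threshold multiplier: candidate
#'   voxels exceed `mu_GM + alpha * sigma_GM` (dimensionless, > 0).
#' @param min_size minimum 26-connected component size in voxels;
#'   smaller candidate components are discarded.
#' @param overlap_classes coarse-segmentation labels eligible to contain
#'   lesions (default GM and WM; CSF is excluded because MS lesions on
#'   FLAIR are less intense than unsuppressed fluid is on T2 but clearly
#'   brighter than suppressed CSF).
#' @param fill_seed RNG seed for the lesion-filling draws.
#' @return a `lesion_config` list.
#' @export
lesion_config <- function(alpha = 2, min_size = 10L,
                          overlap_classes = c(2L, 3L), fill_seed = 1L) {
  if (alpha <= 0) stopf("alpha must be > 0")
  if (min_size < 1) stopf("min_size must be >= 1")
  structure(list(alpha = alpha, min_size = as.integer(min_size),
                 overlap_classes = as.integer(overlap_classes),
                 fill_seed = as.integer(fill_seed)),
            class = "lesion_config")
}

#' Screen FLAIR hyperintensities for lesion candidates
#'
#' MS lesions are hyperintense on FLAIR relative to gray matter.  Using a
#' coarse T1 segmentation as tissue reference, a voxel is a candidate
#' when its FLAIR intensity exceeds `mu_GM + alpha * sigma_GM`, where the
#' GM statistics are taken over coarse-GM voxels (population standard
#' deviation).  Candidates are intersected with the coarse GM-or-WM
#' region (CSF excluded) and 26-connected components smaller than
#' `min_size` voxels are removed.
#'
#' @param flair normalized FLAIR [mri_volume] or 3-D array.
#' @param coarse_labels integer label array from a prior T1 clustering
#'   pass (1 = CSF, 2 = GM, 3 = WM).
#' @param mask logical brain mask.
#' @param config a [lesion_config].
#' @return logical lesion mask.
#' @export
segment_lesions_flair <- function(flair, coarse_labels, mask = NULL,
                                  config = lesion_config()) {
  fv <- as_volume(flair)
  if (is.null(mask)) mask <- default_brain_mask(fv)
  check_mask(mask, fv)
  check_label_map(coarse_labels)
  check_same_grid(coarse_labels, fv, "coarse_labels/flair")
  gm <- coarse_labels == TISSUE_LABELS["GM"] & mask
  if (!any(gm)) stopf("cannot estimate GM statistics: no GM voxels in coarse segmentation")
  g <- fv$data[gm]
  mu <- mean(g)
  sigma <- sqrt(mean((g - mu)^2))
  cand <- mask & fv$data > mu + config$alpha * sigma
  eligible <- array(coarse_labels %in% config$overlap_classes,
                    dim(coarse_labels))
  cand <- cand & eligible
  if (!any(cand)) return(cand)
  cc <- label_components_26(cand)
  keep <- which(cc$sizes >= config$min_size)
  array(cc$labels %in% keep & cand, dim(cand))
}

#' Per-slice normal-appearing white matter statistics
#'
#' NAWM is the white-matter mask minus lesion voxels.  For one axial
#' slice (third array axis), returns the NAWM mean and population
#' standard deviation.  A slice without NAWM voxels falls back to the
#' volume-global NAWM statistics, flagged in the result.
#'
#' @param t1 [mri_volume] or 3-D array.
#' @param wm_mask logical WM mask.
#' @param lesion_mask logical lesion mask.
#' @param slice_index axial slice number (1-based).
#' @return list with `mu`, `sigma`, `count` (NAWM voxels in the slice)
#'   and `fallback` (TRUE when global statistics were substituted).
#' @export
compute_slice_stats <- function(t1, wm_mask, lesion_mask, slice_index) {
  tv <- as_volume(t1)
  check_same_grid(wm_mask, tv, "wm_mask/t1")
  check_same_grid(lesion_mask, tv, "lesion_mask/t1")
  nz <- dim(tv$data)[3]
  if (slice_index < 1 || slice_index > nz)
    stopf("slice_index %d outside 1..%d", slice_index, nz)
  nawm <- wm_mask & !lesion_mask
  if (!any(nawm)) stopf("no NAWM reference tissue")
  sl <- nawm[, , slice_index]
  if (any(sl)) {
    x <- tv$data[, , slice_index][sl]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    list(mu = mu, sigma = sigma, count = sum(sl), fallback = FALSE)
  } else {
    x <- tv$data[nawm]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    list(mu = mu, sigma = sigma, count = 0L, fallback = TRUE)
  }
}

#' S-Lesion-Filling of T1 lesion voxels
#'
#' Walks the axial slices in ascending order; on each slice containing
#' lesion voxels it computes the NAWM mean and standard deviation
#' ([compute_slice_stats]) and replaces every lesion voxel's intensity by
#' an independent draw from Normal(mu, sigma / 2).  Non-lesion voxels are
#' bit-identical to the input, draws are not clipped, and a fixed seed
#' reproduces the output exactly (one RNG stream per call, voxels filled
#' in array order within each slice).
#'
#' @param t1 [mri_volume] or 3-D array.
#' @param lesion_mask logical lesion mask.
#' @param wm_mask logical WM mask (lesion voxels are excluded
#'   internally).
#' @param seed RNG seed.
#' @return filled [mri_volume].
#' @export
slf_fill <- function(t1, lesion_mask, wm_mask, seed = 1L) {
  tv <- as_volume(t1)
  check_same_grid(lesion_mask, tv, "lesion_mask/t1")
  check_same_grid(wm_mask, tv, "wm_mask/t1")
  out <- tv$data
  if (!any(lesion_mask)) return(mri_volume(out, tv$spacing))
  if (!any(wm_mask & !lesion_mask)) stopf("no NAWM reference tissue")
  slices <- which(apply(lesion_mask, 3, any))
  with_private_seed(seed, {
    for (z in slices) {
      st <- compute_slice_stats(tv, wm_mask, lesion_mask, z)
      sl <- lesion_mask[, , z]
      vals <- stats::rnorm(sum(sl), mean = st$mu, sd = st$sigma / 2)
      plane <- out[, , z]
      plane[sl] <- vals
      out[, , z] <- plane
    }
  })
  mri_volume(out, tv$spacing, validate = FALSE)
}

#' Lesion-filling atlas-constrained segmentation pipeline (LFA-FCM)
#'
#' End-to-end segmentation of a lesioned brain: (1) coarse FCM
#' clustering of the T1 volume into three tissues; (2) FLAIR lesion
#' screening against the coarse GM statistics
#' ([segment_lesions_flair]); (3) S-Lesion-Filling of the T1 lesion
#' voxels from NAWM slice statistics ([slf_fill]); (4) AR-FCM on the
#' filled T1 ([fit_arfcm]); (5) morphological boundary redistribution
#' ([redistribute_boundaries]).  With an empty lesion mask stages 2–3
#' are no-ops and the result equals a direct AR-FCM run.
#'
#' @param t1,flair normalized [mri_volume]s on one grid.
#' @param atlas statistical [prob_atlas].
#' @param mask logical brain mask; defaults to positive T1 voxels.
#' @param cluster_config [cluster_config] for the AR-FCM stage.
#' @param lesion_config [lesion_config] for screening and filling.
#' @param morph_atlas morphological [prob_atlas]; defaults to `atlas`.
#' @param coarse_config [cluster_config] for the coarse FCM pass.
#' @return an object of class `lfafcm_result`: `labels` (final label
#'   map), `lesions` (lesion mask), `fit` (the AR-FCM `fcm_fit`),
#'   `filled` (filled T1), `coarse_labels`.
#' @export
run_lfa_fcm <- function(t1, flair, atlas, mask = NULL,
                        cluster_config = default_config("lfafcm"),
                        lesion_config = lfafcm::lesion_config(),
                        morph_atlas = NULL,
                        coarse_config = default_config("fcm")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("%s: %s", name, conditionMessage(e)))
  }
  tv <- as_volume(t1)
  fv <- as_volume(flair)
  if (is.null(mask)) mask <- default_brain_mask(tv)
  stage("segment_lesions_flair", check_same_grid(fv, tv, "grid"))
  check_mask(mask, tv)

  coarse <- stage("coarse_fcm", fit_fcm(tv, mask, coarse_config))
  coarse_labels <- hard_labels(coarse)
  lesions <- stage("segment_lesions_flair",
                   segment_lesions_flair(fv, coarse_labels, mask,
                                         lesion_config))
  wm <- coarse_labels == TISSUE_LABELS["WM"]
  filled <- stage("slf_fill",
                  if (any(lesions))
                    slf_fill(tv, lesions, wm, lesion_config$fill_seed)
                  else tv)
  fit <- stage("fit_arfcm", fit_arfcm(filled, mask, atlas, cluster_config))
  labels <- stage("redistribute_boundaries",
                  redistribute_boundaries(hard_labels(fit), fit,
                                          morph_atlas %||% atlas, mask))
  structure(list(labels = labels, lesions = lesions, fit = fit,
                 filled = filled, coarse_labels = coarse_labels),
            class = "lfafcm_result")
}

#' @export
print.lfafcm_result <- function(x, ...) {
  cat(sprintf("<lfafcm_result> %s grid, %d lesion voxel(s)\n",
              paste(dim(x$labels), collapse = "x"), sum(x$lesions)))
  print(x$fit)
  invisible(x)
}
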