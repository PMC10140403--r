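#' Intensity volume container
#'
#' A 3-D scalar image plus its voxel spacing in millimetres.  The third
#' array axis is the axial (slice) axis by convention; the lesion-filling
#' routines iterate over it.
#'
#' @param data 3-D numeric array of finite values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param validate check finiteness (disable only to construct
#'   deliberately invalid volumes, e.g. for writer tests).
#' @return an object of class `mri_volume` with elements `data` and
#'   `spacing`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), validate = TRUE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stopf("expected 3-D data, got %d-D", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive finite values")
  if (validate) {
    bad <- sum(!is.finite(data))
    if (bad > 0)
      stopf("volume contains %d non-finite voxel(s)", bad)
  }
  structure(list(data = data, spacing = spacing), class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

# Coerce an mri_volume or bare 3-D array to mri_volume.
as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "mri_volume")) return(x)
  mri_volume(x, spacing)
}

#' Default brain mask: strictly positive voxels
#'
#' The clustering routines assume brain-extracted inputs with zeroed
#' background, so the default mask keeps every voxel with intensity > 0.
#'
#' @param volume an [mri_volume] or 3-D array.
#' @return logical 3-D array.
#' @export
default_brain_mask <- function(volume) {
  v <- as_volume(volume)
  v$data > 0
}

check_mask <- function(mask, volume = NULL, require_nonempty = TRUE) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stopf("mask must be a 3-D logical array")
  if (!is.null(volume)) check_same_grid(mask, volume, "mask/volume")
  if (require_nonempty && !any(mask))
    stopf("brain mask is empty")
  invisible(TRUE)
}

# Tissue label coding used throughout: 0 = background, 1 = CSF,
# 2 = GM, 3 = WM.
TISSUE_LABELS <- c(CSF = 1L, GM = 2L, WM = 3L)

check_label_map <- function(labels, K = 3L) {
  if (length(dim(labels)) != 3L)
    stopf("label map must be a 3-D array")
  u <- unique(as.integer(labels))
  if (any(!(u %in% 0:K)))
    stopf("label map contains labels outside {0..%d}: %s", K,
          paste(setdiff(u, 0:K), collapse = ", "))
  invisible(TRUE)
}

#' Probabilistic tissue atlas container
#'
#' Per-voxel tissue priors aligned to the subject grid: a 4-D array with
#' one channel per tissue class (CSF, GM, WM), each probability in
#' \[0, 1\], rows summing to 1 inside the brain mask.
#'
#' @param probs 4-D numeric array, third spatial axis axial, 4th axis the
#'   K = 3 tissue channels.
#' @return object of class `prob_atlas`.
#' @export
prob_atlas <- function(probs) {
  probs <- as.array(probs)
  if (length(dim(probs)) != 4L)
    stopf("atlas must be 4-D (x, y, z, class)")
  if (any(!is.finite(probs)) || any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stopf("atlas probabilities must be finite and in [0, 1]")
  structure(list(probs = probs, K = dim(probs)[4]), class = "prob_atlas")
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> %s, %d tissue channels\n",
              paste(dim(x$probs)[1:3], collapse = "x"), x$K))
  invisible(x)
}

# Matrix of atlas priors for masked voxels: n_masked x K.
atlas_matrix <- function(atlas, mask) {
  check_same_grid(array(0, dim(atlas$probs)[1:3]), mask, "atlas/mask")
  idx <- which(mask)
  K <- atlas$K
  nvox <- prod(dim(mask))
  out <- matrix(0, length(idx), K)
  for (k in seq_len(K))
    out[, k] <- atlas$probs[idx + (k - 1) * nvox]
  out
}
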