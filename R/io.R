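#' Read a 3-D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file, validates that it is three-dimensional
#' with finite voxel values, and attaches the header voxel spacing.
#'
#' @param path file path to a NIfTI-1 image.
#' @return an [mri_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L)
    stopf("expected 3-D image, got %d-D (%s)", length(d), path)
  bad <- sum(!is.finite(im))
  if (bad > 0)
    stopf("volume contains %d non-finite voxel(s): %s", bad, path)
  sp <- RNifti::pixdim(im)[1:3]
  mri_volume(array(as.numeric(im), d), sp)
}

#' Write a 3-D volume as NIfTI
#'
#' @param volume an [mri_volume] or 3-D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing voxel spacing, used when `volume` is a bare array.
#' @param datatype NIfTI on-disk datatype; the `"double"` default
#'   round-trips finite values bit-exactly.
#' @param raw write the array as-is without finiteness validation (for
#'   constructing deliberately corrupt files in tests).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL, datatype = "double",
                         raw = FALSE) {
  if (inherits(volume, "mri_volume")) {
    arr <- volume$data
    sp <- spacing %||% volume$spacing
  } else {
    arr <- as.array(volume)
    sp <- spacing %||% c(1, 1, 1)
  }
  if (!raw && any(!is.finite(arr)))
    stopf("refusing to write %d non-finite voxel(s); use raw = TRUE",
          sum(!is.finite(arr)))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- sp[seq_len(min(3L, length(dim(arr))))]
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @param mask logical array to write as an 8-bit mask image.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  write_volume(array(as.integer(mask), dim(mask)), path, spacing,
               datatype = "uint8")
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  v$data != 0
}

#' @rdname write_volume
#' @param labels integer tissue label array (0..3) to write.
#' @export
write_labels <- function(labels, path, spacing = c(1, 1, 1)) {
  check_label_map(labels)
  write_volume(array(as.integer(labels), dim(labels)), path, spacing,
               datatype = "int16")
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  v <- read_volume(path)
  lab <- array(as.integer(round(v$data)), dim(v$data))
  check_label_map(lab)
  lab
}

#' Load a probabilistic tissue atlas
#'
#' Reads a 4-D NIfTI with one probability channel per tissue class
#' (CSF, GM, WM), checks alignment with the subject grid, and
#' renormalizes each voxel's priors to sum to one inside the brain mask.
#' Voxels whose stored channel sum is below `1e-6` receive the
#' uninformative prior (1/3, 1/3, 1/3).
#'
#' @param path 4-D NIfTI path with exactly 3 channels.
#' @param mask logical brain mask on the subject grid.
#' @return a [prob_atlas].
#' @export
load_atlas <- function(path, mask) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L)
    stopf("atlas must be 4-D, got %d-D (%s)", length(d), path)
  if (d[4] != 3L)
    stopf("atlas must have 3 tissue channels, got %d", d[4])
  if (!identical(as.integer(d[1:3]), as.integer(dim(mask))))
    stopf("atlas grid %s does not match mask grid %s",
          paste(d[1:3], collapse = "x"), paste(dim(mask), collapse = "x"))
  probs <- array(as.numeric(im), d)
  normalize_atlas(probs, mask)
}

# Renormalize 4-D prior array inside the mask; uniform fallback where the
# stored sum is (near) zero.  Outside the mask priors are left as stored.
normalize_atlas <- function(probs, mask) {
  probs[probs < 0] <- 0
  K <- dim(probs)[4]
  nvox <- prod(dim(probs)[1:3])
  idx <- which(mask)
  m <- matrix(0, length(idx), K)
  for (k in seq_len(K)) m[, k] <- probs[idx + (k - 1) * nvox]
  s <- rowSums(m)
  degenerate <- s < 1e-6
  m[degenerate, ] <- 1 / K
  m[!degenerate, ] <- m[!degenerate, , drop = FALSE] / s[!degenerate]
  for (k in seq_len(K)) probs[idx + (k - 1) * nvox] <- m[, k]
  prob_atlas(probs)
}

#' @rdname load_atlas
#' @param atlas a [prob_atlas] to write.
#' @param spacing voxel spacing in mm.
#' @export
write_atlas <- function(atlas, path, spacing = c(1, 1, 1)) {
  im <- RNifti::asNifti(atlas$probs)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' Normalize intensities to the unit interval
#'
#' Clips masked intensities to their 1st–99th percentile range and maps
#' that range affinely onto \[0, 1\]; voxels outside the mask are set to
#' zero.  All clustering parameters (notably the atlas penalty weight and
#' the convergence threshold) are interpreted on this normalized scale.
#'
#' @param volume an [mri_volume] or 3-D array.
#' @param mask logical brain mask; defaults to positive voxels.
#' @param probs clip percentiles (lower, upper).
#' @return an [mri_volume] with masked values in \[0, 1\].
#' @export
normalize_intensities <- function(volume, mask = NULL,
                                  probs = c(0.01, 0.99)) {
  v <- as_volume(volume)
  if (is.null(mask)) mask <- default_brain_mask(v)
  check_mask(mask, v)
  x <- v$data[mask]
  q <- stats::quantile(x, probs, names = FALSE, type = 7)
  if (diff(q) <= 0)
    stopf("degenerate intensity range: percentiles %g and %g coincide",
          probs[1], probs[2])
  x <- pmin(pmax(x, q[1]), q[2])
  x <- (x - q[1]) / (q[2] - q[1])
  out <- array(0, dim(v$data))
  out[mask] <- x
  mri_volume(out, v$spacing)
}
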