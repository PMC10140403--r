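# Shared fixture builders (all generated in code; nothing on disk).

# Flat-interface slab phantom: three axial slabs CSF/GM/WM with the
# given intensities.  Every tissue interface is planar, so no voxel has
# a minority same-class 6-neighborhood.
slab_phantom <- function(d = c(12L, 12L, 12L),
                         means = c(0.2, 0.5, 0.8)) {
  gt <- array(0L, d)
  thirds <- round(d[3] * c(1, 2) / 3)
  gt[, , 1:thirds[1]] <- 1L
  gt[, , (thirds[1] + 1):thirds[2]] <- 2L
  gt[, , (thirds[2] + 1):d[3]] <- 3L
  vol <- array(means[gt], d)
  list(t1 = mri_volume(vol), gt = gt, mask = array(TRUE, d))
}

# One-hot atlas from a label map.
onehot_atlas <- function(labels, K = 3L) {
  d <- dim(labels)
  probs <- array(0, c(d, K))
  for (k in seq_len(K)) probs[, , , k] <- as.numeric(labels == k)
  prob_atlas(probs)
}
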