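#' Dice similarity coefficient (percent)
#'
#' `100 * 2|SEG intersect GT| / (|SEG| + |GT|)`.  Two empty masks agree
#' perfectly by convention and score 100.
#'
#' @param seg,gt logical 3-D masks on one grid.
#' @return score in \[0, 100\].
#' @export
dice_score <- function(seg, gt) {
  check_same_grid(seg, gt, "seg/gt")
  ns <- sum(seg); ng <- sum(gt)
  if (ns + ng == 0) return(100)
  100 * 2 * sum(seg & gt) / (ns + ng)
}

#' Volumetric similarity (percent)
#'
#' `100 * (1 - ||GT| - |SEG|| / (|GT| + |SEG|))` with volumes as voxel
#' counts; insensitive to overlap, it scores the agreement of total
#' volumes only.
#'
#' @inheritParams dice_score
#' @return score in \[0, 100\].
#' @export
volumetric_similarity <- function(seg, gt) {
  check_same_grid(seg, gt, "seg/gt")
  ns <- sum(seg); ng <- sum(gt)
  if (ns + ng == 0) stopf("undefined volume ratio: both masks empty")
  100 * (1 - abs(ng - ns) / (ng + ns))
}

# Surface voxels: masked voxels with at least one 6-neighbor outside the
# mask (array borders count as outside).  Returns mm coordinates.
surface_coords <- function(mask, spacing) {
  nbr <- neighbor_index_6(mask)
  n <- nrow(nbr)
  surf <- rowSums(nbr == n + 1L) > 0
  co <- arrayInd(which(mask), dim(mask))[surf, , drop = FALSE]
  sweep(co, 2, spacing, `*`)
}

# For each row of A, the distance to the nearest row of B, chunked to
# bound memory.
min_dists <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  bb <- rowSums(B^2)
  out <- numeric(n)
  chunk <- max(1L, floor(2e7 / m))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    a <- A[i:j, , drop = FALSE]
    D <- rowSums(a^2) - 2 * a %*% t(B)
    D <- sweep(D, 2, bb, `+`)
    best <- max.col(-D, ties.method = "first")
    out[i:j] <- sqrt(pmax(0, D[cbind(seq_len(nrow(D)), best)]))
    i <- j + 1L
  }
  out
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Extracts the surface voxels of each mask (6-connectivity), computes
#' every seg-surface voxel's distance to the nearest gt-surface voxel
#' and vice versa (voxel centers, millimetres), pools the two directed
#' sets and returns their 95th percentile (linear interpolation between
#' order statistics, [stats::quantile] type 7).
#'
#' @inheritParams dice_score
#' @param spacing voxel size in mm per axis.
#' @return distance in mm.
#' @export
hd95 <- function(seg, gt, spacing = c(1, 1, 1)) {
  check_same_grid(seg, gt, "seg/gt")
  if (!any(seg) || !any(gt)) stopf("HD undefined for empty mask")
  S <- surface_coords(seg, spacing)
  G <- surface_coords(gt, spacing)
  d <- c(min_dists(S, G), min_dists(G, S))
  stats::quantile(d, 0.95, names = FALSE, type = 7)
}

#' Per-tissue segmentation metrics
#'
#' Binarizes each tissue class (1 = CSF, 2 = GM, 3 = WM; background
#' excluded) and applies [dice_score], [volumetric_similarity] and
#' [hd95].  A class absent from the gold standard is reported as `NA`;
#' HD95 is `NA` whenever either binary mask is empty.
#'
#' @param seg,gt integer 3-D label arrays with labels in 0..3.
#' @param spacing voxel size in mm per axis.
#' @param metrics which metrics to compute; the surface-distance HD95 is
#'   by far the most expensive on large noisy segmentations and can be
#'   dropped when only overlap/volume scores are needed.
#' @return data.frame with columns `class`, `dsc`, `vs`, `hd95`
#'   (requested metrics only).
#' @export
evaluate_segmentation <- function(seg, gt, spacing = c(1, 1, 1),
                                  metrics = c("dsc", "vs", "hd95")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  check_label_map(seg)
  check_label_map(gt)
  check_same_grid(seg, gt, "seg/gt")
  out <- data.frame(class = names(TISSUE_LABELS),
                    dsc = NA_real_, vs = NA_real_, hd95 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(TISSUE_LABELS)) {
    k <- TISSUE_LABELS[i]
    s <- seg == k; g <- gt == k
    if (!any(g)) next
    if ("dsc" %in% metrics) out$dsc[i] <- dice_score(s, g)
    if ("vs" %in% metrics) out$vs[i] <- volumetric_similarity(s, g)
    if ("hd95" %in% metrics && any(s)) out$hd95[i] <- hd95(s, g, spacing)
  }
  out[, c("class", metrics), drop = FALSE]
}
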