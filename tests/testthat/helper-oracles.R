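# Independent brute-force reference implementations used to validate the
# package's metric and clustering code paths.  Deliberately written with
# naive loops and none of the package's internal helpers.

oracle_dsc <- function(seg, gt) {
  s <- which(seg); g <- which(gt)
  if (length(s) + length(g) == 0) return(100)
  100 * 2 * length(intersect(s, g)) / (length(s) + length(g))
}

oracle_vs <- function(seg, gt) {
  ns <- length(which(seg)); ng <- length(which(gt))
  100 * (1 - abs(ng - ns) / (ng + ns))
}

# Surface voxels by explicit neighbor inspection.
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    surf <- FALSE
    for (r in 1:6) {
      p <- nb[r, ]
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) { surf <- TRUE; break }
    }
    if (surf) out <- rbind(out, c(i, j, k))
  }
  out
}

# All-pairs symmetric 95th-percentile surface distance.
oracle_hd95 <- function(seg, gt, spacing = c(1, 1, 1)) {
  S <- sweep(oracle_surface(seg), 2, spacing, `*`)
  G <- sweep(oracle_surface(gt), 2, spacing, `*`)
  dmat <- matrix(0, nrow(S), nrow(G))
  for (a in seq_len(nrow(S))) for (b in seq_len(nrow(G)))
    dmat[a, b] <- sqrt(sum((S[a, ] - G[b, ])^2))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(pooled, 0.95, type = 7))
}

# Plain alternate-minimization FCM on a numeric vector (no spatial
# machinery, no centroid sorting, explicit loops).
oracle_fcm_1d <- function(y, v, q = 2, iters = 100) {
  K <- length(v)
  u <- matrix(0, length(y), K)
  for (it in seq_len(iters)) {
    for (j in seq_along(y)) {
      d <- abs(y[j] - v)
      if (any(d == 0)) {
        u[j, ] <- 0; u[j, which(d == 0)[1]] <- 1
      } else {
        w <- d^(-2 / (q - 1))
        u[j, ] <- w / sum(w)
      }
    }
    for (k in seq_len(K)) v[k] <- sum(u[, k]^q * y) / sum(u[, k]^q)
  }
  list(u = u, v = v)
}

# Per-voxel max scan with lower-index tie break.
oracle_argmax_labels <- function(u, mask) {
  lab <- array(0L, dim(mask))
  idx <- which(mask)
  for (r in seq_along(idx)) {
    row <- u[r, ]
    best <- 1L
    for (k in seq_along(row)) if (row[k] > row[best]) best <- k
    lab[idx[r]] <- best
  }
  lab
}

# Random nonempty mask pair on a small grid.
random_mask_pair <- function(seed, dmin = 4L, dmax = 8L, p = 0.35) {
  set.seed(seed)
  d <- sample(dmin:dmax, 3L, replace = TRUE)
  repeat {
    a <- array(runif(prod(d)) < p, d)
    b <- array(runif(prod(d)) < p, d)
    if (any(a) && any(b)) return(list(seg = a, gt = b))
  }
}
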