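#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a private RNG stream
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state so that
#' seeded package internals never perturb user-level random sequences.
#' @noRd
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

check_same_grid <- function(a, b, what = "inputs") {
  da <- if (is.list(a)) dim(a$data) else dim(a)
  db <- if (is.list(b)) dim(b$data) else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stopf("%s: grid mismatch (%s vs %s)", what,
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Separable 3-D Gaussian smoothing (zero-padded)
#'
#' Convolves a 3-D array with an isotropic Gaussian kernel, axis by axis.
#' Values beyond the array edge are treated as zero; callers that need
#' mass preservation at edges should renormalize afterwards (the atlas
#' builder does).
#'
#' @param x 3-D numeric array.
#' @param sigma kernel standard deviation in voxels; 0 returns `x`.
#' @return smoothed array of the same dimensions.
#' @noRd
gaussian_smooth_3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  conv_axis1 <- function(m, n1) {
    # m: n1 x rest matrix; zero-pad, filter each column, crop
    pad <- matrix(0, r, ncol(m))
    mp <- rbind(pad, m, pad)
    f <- stats::filter(mp, k, sides = 2)
    matrix(f[(r + 1):(r + n1), ], nrow = n1)
  }
  # axis 1
  x <- array(conv_axis1(matrix(x, d[1]), d[1]), d)
  # axis 2
  xp <- aperm(x, c(2, 1, 3))
  xp <- array(conv_axis1(matrix(xp, d[2]), d[2]), d[c(2, 1, 3)])
  x <- aperm(xp, c(2, 1, 3))
  # axis 3
  xp <- aperm(x, c(3, 1, 2))
  xp <- array(conv_axis1(matrix(xp, d[3]), d[3]), d[c(3, 1, 2)])
  aperm(xp, c(2, 3, 1))
}

# The 26-neighborhood offsets, one representative per symmetric pair.
half_offsets_26 <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  keep <- o$dz > 0 | (o$dz == 0 & (o$dy > 0 | (o$dy == 0 & o$dx > 0)))
  as.matrix(o[keep, ])
}

#' Label 26-connected components of a 3-D logical array
#'
#' @param mask logical 3-D array.
#' @return list with `labels` (integer array, 0 = background), `n`
#'   components, and `sizes` (voxel count per component).
#' @noRd
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L)
    return(list(labels = lab, n = 0L, sizes = integer(0)))
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  edges <- vector("list", 13L)
  offs <- half_offsets_26()
  for (i in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[i, ], nrow(co), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    j <- pos[nb[ok, , drop = FALSE]]
    src <- which(ok)[j > 0]
    if (length(src)) edges[[i]] <- cbind(src, j[j > 0])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el))
    g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  lab[idx] <- as.integer(comp$membership)
  list(labels = lab, n = comp$no, sizes = as.integer(comp$csize))
}

#' Six-neighbor row index matrix for masked voxels
#'
#' For each masked voxel (row), the row indices of its 6-connected masked
#' neighbors; absent neighbors (outside the grid or the mask) point at a
#' sentinel row `n_masked + 1` so callers can append a zero row to value
#' matrices and use plain matrix indexing.
#' @noRd
neighbor_index_6 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  pos <- array(n + 1L, d)  # sentinel
  pos[idx] <- seq_len(n)
  co <- arrayInd(idx, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nbr <- matrix(n + 1L, n, 6L)
  for (i in 1:6) {
    nb <- co + matrix(offs[i, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbr[ok, i] <- pos[nb[ok, , drop = FALSE]]
  }
  nbr
}
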