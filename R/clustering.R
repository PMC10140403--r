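#' Clustering configuration
#'
#' Collects the parameters of the fuzzy C-means family.  Defaults per
#' method (see [default_config]):
#'
#' | method  | q | beta | gamma | w | n   | thr   |
#' |---------|---|------|-------|---|-----|-------|
#' | fcm     | 2 | 0    | 0     | 1 | 500 | 0.001 |
#' | rfcm    | 2 | 1    | 0     | 1 | 500 | 0.001 |
#' | arfcm   | 2 | 0    | 0.025 | 1 | 200 | 0.001 |
#' | lfafcm  | 2 | 0    | 0.025 | 1 | 200 | 0.001 |
#'
#' @param q fuzziness exponent, > 1 (dimensionless).
#' @param beta spatial penalty weight (>= 0), couples each voxel's
#'   membership to its 6-connected neighbors.
#' @param gamma atlas penalty weight (>= 0) on the normalized intensity
#'   scale.
#' @param w atlas penalty exponent (> 0) applied to (1 - prior).
#' @param n maximum number of iterations.
#' @param thr convergence threshold on the maximum centroid change, in
#'   normalized intensity units.
#' @param K number of tissue classes.
#' @param init centroid initialization: `"quantile"` places centroids at
#'   the (1..K)/(K+1) masked-intensity quantiles, `"atlas"` at
#'   atlas-weighted intensity means, `"auto"` picks `"atlas"` for the
#'   atlas-constrained fitter when `gamma > 0` and `"quantile"` otherwise.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(q = 2, beta = 0, gamma = 0, w = 1, n = 100,
                           thr = 1e-3, K = 3L,
                           init = c("auto", "quantile", "atlas")) {
  init <- match.arg(init)
  if (!is.numeric(q) || q <= 1) stopf("q must be > 1")
  if (beta < 0 || gamma < 0) stopf("beta and gamma must be >= 0")
  if (w <= 0) stopf("w must be > 0")
  if (n < 1) stopf("n must be >= 1")
  if (thr <= 0) stopf("thr must be > 0")
  K <- as.integer(K)
  if (K < 1) stopf("K must be >= 1")
  structure(list(q = q, beta = beta, gamma = gamma, w = w,
                 n = as.integer(n), thr = thr, K = K, init = init),
            class = "cluster_config")
}

#' @rdname cluster_config
#' @param method one of `"fcm"`, `"rfcm"`, `"arfcm"`, `"lfafcm"`.
#' @export
default_config <- function(method = c("fcm", "rfcm", "arfcm", "lfafcm")) {
  method <- match.arg(method)
  switch(method,
    fcm    = cluster_config(q = 2, beta = 0, gamma = 0,     w = 1, n = 500, thr = 1e-3),
    rfcm   = cluster_config(q = 2, beta = 1, gamma = 0,     w = 1, n = 500, thr = 1e-3),
    arfcm  = cluster_config(q = 2, beta = 0, gamma = 0.025, w = 1, n = 200, thr = 1e-3),
    lfafcm = cluster_config(q = 2, beta = 0, gamma = 0.025, w = 1, n = 200, thr = 1e-3))
}

# Deterministic quantile initialization of K centroids.
init_quantile <- function(y, K) {
  v <- stats::quantile(y, (1:K) / (K + 1), names = FALSE, type = 7)
  if (anyDuplicated(v))
    v <- seq(min(y), max(y), length.out = K)
  v
}

# Membership update: u_jk proportional to a_jk^(-1/(q-1)), where
# a_jk = d_jk^2 + penalties.  Rows with a zero entry become one-hot on
# the first zero (the exact-centroid singularity convention).
membership_from_a <- function(a, q) {
  e <- -1 / (q - 1)
  zr <- a <= 0
  anyz <- rowSums(zr) > 0
  aw <- a
  aw[anyz, ] <- 1  # placeholder, overwritten below
  u <- aw^e
  u <- u / rowSums(u)
  if (any(anyz)) {
    K <- ncol(a)
    first0 <- max.col(zr[anyz, , drop = FALSE], ties.method = "first")
    oh <- matrix(0, sum(anyz), K)
    oh[cbind(seq_len(sum(anyz)), first0)] <- 1
    u[anyz, ] <- oh
  }
  u
}

# Core alternating-minimization engine shared by the three fitters.
#
# y            masked intensity vector (length N)
# v0           initial centroids (length K, any order)
# fixed_pen    N x K matrix added to the squared distances (atlas term
#              gamma * (1 - prior)^w), or NULL
# nbr          N x 6 neighbor index matrix (sentinel row N + 1) when
#              beta > 0, else NULL
fcm_engine <- function(y, v0, config, fixed_pen = NULL, nbr = NULL) {
  q <- config$q; beta <- config$beta
  K <- length(v0)
  N <- length(y)
  v <- as.numeric(v0)
  u <- NULL
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  spatial <- !is.null(nbr) && beta > 0

  spatial_pen <- function(u) {
    # beta * sum over 6-neighbors of the other-class memberships^q
    uq <- rbind(u^q, rep(0, K))   # sentinel zero row
    S <- matrix(0, N, K)
    for (k in seq_len(K)) {
      col <- uq[, k]
      S[, k] <- rowSums(matrix(col[nbr], N, 6L))
    }
    Stot <- rowSums(S)
    beta * (Stot - S)
  }

  objective <- function(u, v) {
    uq <- u^q
    d2 <- (matrix(y, N, K) - matrix(v, N, K, byrow = TRUE))^2
    J <- sum(uq * d2)
    if (!is.null(fixed_pen)) J <- J + sum(uq * fixed_pen)
    if (spatial) J <- J + 0.5 * sum(uq * spatial_pen(u))
    J
  }

  # state 0: memberships from the initial centroids, spatial term off
  # (there is no previous membership field to penalize against yet)
  a0 <- (matrix(y, N, K) - matrix(v, N, K, byrow = TRUE))^2
  if (!is.null(fixed_pen)) a0 <- a0 + fixed_pen
  u <- membership_from_a(a0, q)
  J_curr <- objective(u, v)

  for (iter in seq_len(config$n)) {
    d2 <- (matrix(y, N, K) - matrix(v, N, K, byrow = TRUE))^2
    a <- d2
    if (!is.null(fixed_pen)) a <- a + fixed_pen
    if (spatial) a <- a + spatial_pen(u)
    u_cand <- membership_from_a(a, q)
    if (spatial) {
      # The spatial penalty couples memberships across voxels, so the
      # simultaneous update evaluated at the previous memberships is not
      # guaranteed to descend; accept the step only if it does, backing
      # off toward the current memberships when needed (on spatially
      # coherent images the full step is virtually always accepted).
      t <- 1
      repeat {
        u_t <- if (t == 1) u_cand else (1 - t) * u + t * u_cand
        if (objective(u_t, v) <= J_curr + 1e-12 * max(1, abs(J_curr))) {
          u <- u_t
          break
        }
        t <- t / 2
        if (t < 1 / 16) break   # no acceptable membership step; keep u
      }
    } else {
      # without the neighborhood term the update exactly minimizes the
      # objective in u for fixed v
      u <- u_cand
    }
    uq <- u^q
    den <- colSums(uq)
    v_new <- ifelse(den > 0, colSums(uq * y) / den, v)
    J_curr <- objective(u, v_new)
    trace <- c(trace, J_curr)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < config$thr) { converged <- TRUE; break }
  }

  ord <- order(v)
  list(u = u[, ord, drop = FALSE], v = v[ord], trace = trace,
       iterations = iter, converged = converged)
}

fit_common <- function(volume, mask, config, fixed_pen = NULL,
                       use_nbr = FALSE, v0 = NULL, method, call) {
  vol <- as_volume(volume)
  if (is.null(mask)) mask <- default_brain_mask(vol)
  check_mask(mask, vol)
  y <- vol$data[mask]
  if (length(unique(y)) < config$K)
    stopf("underdetermined clustering: %d classes but only %d distinct masked intensities",
          config$K, length(unique(y)))
  if (is.null(v0)) v0 <- init_quantile(y, config$K)
  nbr <- if (use_nbr && config$beta > 0) neighbor_index_6(mask) else NULL
  res <- fcm_engine(y, v0, config, fixed_pen = fixed_pen, nbr = nbr)
  structure(list(membership = res$u, centroids = res$v,
                 objective_trace = res$trace,
                 iterations_used = res$iterations,
                 converged = res$converged,
                 method = method, config = config,
                 mask = mask, dim = dim(vol$data),
                 spacing = vol$spacing, call = call),
            class = "fcm_fit")
}

#' Fuzzy C-means tissue segmentation
#'
#' Fits the classical fuzzy C-means model to the masked intensities by
#' alternating the membership update
#' \eqn{u_{jk} \propto d_{jk}^{-2/(q-1)}} (with
#' \eqn{d_{jk} = |y_j - v_k|}) and the centroid update
#' \eqn{v_k = \sum_j u_{jk}^q y_j / \sum_j u_{jk}^q} until the largest
#' centroid change drops below `thr` or `n` iterations elapse.  A voxel
#' lying exactly on a centroid receives one-hot membership for that class.
#' Centroids are sorted ascending on return, so on T1-weighted images
#' class 1 = CSF, 2 = GM, 3 = WM.
#'
#' @param volume an [mri_volume] (or 3-D array) with intensities
#'   normalized to \[0, 1\]; see [normalize_intensities].
#' @param mask logical brain mask; defaults to positive voxels.
#' @param config a [cluster_config] with `beta = gamma = 0`.
#' @return an object of class `fcm_fit`: masked-voxel membership matrix,
#'   sorted centroids, per-iteration objective trace, iteration count and
#'   convergence flag.
#' @seealso [fit_rfcm], [fit_arfcm], [hard_labels]
#' @export
fit_fcm <- function(volume, mask = NULL, config = default_config("fcm")) {
  if (config$beta != 0 || config$gamma != 0)
    stopf("fit_fcm requires beta = gamma = 0 (got beta=%g, gamma=%g)",
          config$beta, config$gamma)
  fit_common(volume, mask, config, method = "fcm", call = match.call())
}

#' Robust fuzzy C-means with a spatial penalty
#'
#' Adds to the FCM energy a Markov-random-field-like neighborhood
#' penalty,
#' \deqn{J = \sum_j \sum_k u_{jk}^q d_{jk}^2 + \frac{\beta}{2} \sum_j
#'   \sum_k u_{jk}^q \sum_{l \in N_j} \sum_{m \ne k} u_{lm}^q,}
#' where \eqn{N_j} are the 6-connected neighbors of voxel j inside the
#' mask.  The membership update becomes
#' \eqn{u_{jk} \propto (d_{jk}^2 + \beta \sum_{l \in N_j} \sum_{m \ne k}
#' u_{lm}^q)^{-1/(q-1)}}, evaluated with the previous iteration's
#' neighbor memberships.  With `beta = 0` this reduces exactly to
#' [fit_fcm].
#'
#' @inheritParams fit_fcm
#' @param config a [cluster_config]; `beta` is the spatial weight
#'   (default 1).
#' @return an `fcm_fit` object.
#' @export
fit_rfcm <- function(volume, mask = NULL, config = default_config("rfcm")) {
  fit_common(volume, mask, config, use_nbr = TRUE, method = "rfcm",
             call = match.call())
}

#' Atlas-constrained robust fuzzy C-means (AR-FCM)
#'
#' Couples fuzzy clustering to a statistical probability atlas by the
#' additive constraint term
#' \deqn{J = \sum_j \sum_k u_{jk}^q d_{jk}^2 + \gamma \sum_j \sum_k
#'   u_{jk}^q (1 - \pi_{jk})^w,}
#' where \eqn{\pi_{jk}} is the atlas prior of class k at voxel j.  The
#' membership update is
#' \eqn{u_{jk} \propto (d_{jk}^2 + \gamma (1 - \pi_{jk})^w)^{-1/(q-1)}};
#' the centroid update is unchanged from FCM.  Because the penalty does
#' not involve the memberships of other voxels, each iteration exactly
#' minimizes the objective in `u` then `v`, so the objective trace is
#' monotone non-increasing.
#'
#' When `gamma > 0` (and `init = "auto"`) centroids are initialized at
#' the atlas-weighted intensity means
#' \eqn{v_k = \sum_j \pi_{jk} y_j / \sum_j \pi_{jk}}; with `gamma = 0`
#' the atlas is inert and the default quantile initialization applies,
#' making the fit identical to [fit_fcm].
#'
#' @inheritParams fit_fcm
#' @param atlas a [prob_atlas] aligned to the subject grid.
#' @param config a [cluster_config]; `gamma` (default 0.025) weighs the
#'   atlas term and `w` (default 1) is its exponent, both on the
#'   normalized intensity scale.
#' @return an `fcm_fit` object.
#' @export
fit_arfcm <- function(volume, mask = NULL, atlas,
                      config = default_config("arfcm")) {
  vol <- as_volume(volume)
  if (is.null(mask)) mask <- default_brain_mask(vol)
  check_mask(mask, vol)
  if (!inherits(atlas, "prob_atlas")) stopf("atlas must be a prob_atlas")
  if (!identical(as.integer(dim(atlas$probs)[1:3]), as.integer(dim(vol$data))))
    stopf("atlas grid %s does not match volume grid %s",
          paste(dim(atlas$probs)[1:3], collapse = "x"),
          paste(dim(vol$data), collapse = "x"))
  if (atlas$K != config$K)
    stopf("atlas has %d channels but config$K = %d", atlas$K, config$K)
  pim <- atlas_matrix(atlas, mask)
  fixed_pen <- config$gamma * (1 - pim)^config$w
  v0 <- NULL
  use_atlas_init <- switch(config$init,
                           atlas = TRUE, quantile = FALSE,
                           auto = config$gamma > 0)
  if (use_atlas_init) {
    y <- vol$data[mask]
    den <- colSums(pim)
    v0 <- ifelse(den > 0, colSums(pim * y) / den,
                 init_quantile(y, config$K))
  }
  fit_common(vol, mask, config, fixed_pen = fixed_pen, v0 = v0,
             method = "arfcm", call = match.call())
}

#' Maximum-membership labeling
#'
#' Defuzzifies a membership field: each masked voxel receives the class
#' of its largest membership, coded 1 = CSF, 2 = GM, 3 = WM (centroids
#' ascending), background 0.  Ties break toward the lower class index.
#'
#' @param x an `fcm_fit`, or a masked-voxel membership matrix.
#' @param mask logical mask matching the membership rows (unused when `x`
#'   is a fit).
#' @return integer 3-D label array.
#' @export
hard_labels <- function(x, mask = NULL) {
  if (inherits(x, "fcm_fit")) {
    u <- x$membership; mask <- x$mask
  } else {
    u <- as.matrix(x)
    if (is.null(mask)) stopf("mask required when x is a membership matrix")
    if (nrow(u) != sum(mask))
      stopf("membership rows (%d) do not match masked voxels (%d)",
            nrow(u), sum(mask))
  }
  lab <- array(0L, dim(mask))
  lab[mask] <- max.col(u, ties.method = "first")
  lab
}

#' Morphological boundary redistribution
#'
#' Post-processing against partial-volume effects: voxels on tissue
#' boundaries (masked voxels with at least one 6-neighbor carrying a
#' different nonzero label) are relabeled to
#' \eqn{\arg\max_k u_{jk} \, m_{jk}}, the class maximizing the product of
#' the fuzzy membership and the morphological-atlas probability.
#' Non-boundary voxels are untouched.
#'
#' @param labels integer 3-D label array (0..3).
#' @param membership an `fcm_fit` or masked-voxel membership matrix.
#' @param morph_atlas a [prob_atlas] of morphological label
#'   probabilities; the statistical atlas is a valid stand-in.
#' @param mask logical brain mask.
#' @return relabeled integer array.
#' @export
redistribute_boundaries <- function(labels, membership, morph_atlas,
                                    mask = NULL) {
  if (inherits(membership, "fcm_fit")) {
    if (is.null(mask)) mask <- membership$mask
    u <- membership$membership
  } else u <- as.matrix(membership)
  check_label_map(labels)
  check_mask(mask, require_nonempty = TRUE)
  check_same_grid(labels, mask, "labels/mask")
  check_same_grid(array(0, dim(morph_atlas$probs)[1:3]), mask,
                  "morph_atlas/mask")
  if (nrow(u) != sum(mask))
    stopf("membership rows (%d) do not match masked voxels (%d)",
          nrow(u), sum(mask))
  nbr <- neighbor_index_6(mask)
  labm <- c(as.integer(labels[mask]), NA_integer_)   # sentinel
  nlab <- matrix(labm[nbr], nrow(nbr), 6L)
  own <- labm[seq_len(nrow(nbr))]
  boundary <- rowSums(!is.na(nlab) & nlab != 0 & nlab != own, na.rm = TRUE) > 0
  if (!any(boundary)) return(labels)
  m <- atlas_matrix(morph_atlas, mask)
  newlab <- max.col(u[boundary, , drop = FALSE] * m[boundary, , drop = FALSE],
                    ties.method = "first")
  out <- labels
  midx <- which(mask)
  out[midx[boundary]] <- newlab
  out
}
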