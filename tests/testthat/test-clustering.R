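test_that("FCM matches an independent alternate-minimization oracle", {
  y <- c(0, 0, 0, 1, 1, 1)
  v <- mri_volume(array(y, c(6, 1, 1)))
  mask <- array(TRUE, c(6, 1, 1))
  fit <- fit_fcm(v, mask, cluster_config(q = 2, K = 2, n = 100, thr = 1e-8))
  ref <- oracle_fcm_1d(y, v = c(0.25, 0.75), q = 2)
  expect_equal(fit$centroids, sort(ref$v), tolerance = 1e-6)
  expect_lt(max(abs(fit$membership - ref$u)), 1e-6)
  # memberships one-hot at the exact-centroid singularity
  expect_true(all(abs(fit$membership - round(fit$membership)) < 1e-6))
})

test_that("K = 1 on a constant image converges immediately to the constant", {
  d <- c(4, 4, 4)
  fit <- fit_fcm(mri_volume(array(0.7, d)), array(TRUE, d),
                 cluster_config(K = 1, n = 10))
  expect_equal(fit$centroids, 0.7)
  expect_true(all(fit$membership == 1))
  expect_equal(fit$iterations_used, 1L)
  expect_true(fit$converged)
})

test_that("clustering more classes than distinct intensities errors", {
  d <- c(4, 4, 2)
  v <- mri_volume(array(rep(c(0.2, 0.8), each = 16), d))
  expect_error(fit_fcm(v, array(TRUE, d), cluster_config(K = 3)),
               "underdetermined clustering")
})

test_that("membership rows sum to one for every fitter", {
  set.seed(11)
  d <- c(10, 10, 10)
  v <- mri_volume(array(runif(prod(d)), d))
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), prod(d))[seq_len(prod(d))]
  mask <- array(mask, d)
  atlas <- onehot_atlas(array(sample(1:3, prod(d), TRUE), d))
  for (fit in list(fit_fcm(v, mask),
                   fit_rfcm(v, mask),
                   fit_arfcm(v, mask, atlas)))
    expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
})

test_that("the reduction chain arfcm(gamma=0) = rfcm(beta=0) = fcm is exact", {
  for (s in 1:5) {
    set.seed(s)
    d <- c(8, 8, 8)
    v <- mri_volume(array(runif(prod(d)), d))
    mask <- array(TRUE, d)
    atlas <- prob_atlas(array(runif(prod(d) * 3, 0.1, 1), c(d, 3)))
    cfg <- function(...) cluster_config(n = 40, thr = 1e-5, ...)
    f1 <- fit_fcm(v, mask, cfg())
    f2 <- fit_rfcm(v, mask, cfg(beta = 0))
    f3 <- fit_arfcm(v, mask, atlas, cfg(gamma = 0))
    expect_lt(max(abs(f1$membership - f2$membership)), 1e-10)
    expect_lt(max(abs(f1$membership - f3$membership)), 1e-10)
    expect_lt(max(abs(f1$centroids - f3$centroids)), 1e-10)
  }
})

test_that("objective traces never increase, including on random inputs", {
  for (s in 1:20) {
    set.seed(s)
    d <- c(9, 9, 9)
    v <- mri_volume(array(runif(prod(d)), d))
    mask <- array(TRUE, d)
    probs <- array(runif(prod(d) * 3), c(d, 3))
    atlas <- prob_atlas(probs / rep(apply(probs, 1:3, sum), 3))
    for (fit in list(fit_fcm(v, mask),
                     fit_rfcm(v, mask),
                     fit_arfcm(v, mask, atlas))) {
      tr <- fit$objective_trace
      if (length(tr) > 1)
        expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])),
                    label = sprintf("%s trace monotone (seed %d)",
                                    fit$method, s))
    }
  }
})

test_that("RFCM relabels an isolated noise voxel to its neighborhood", {
  d <- c(8, 8, 8)
  gt <- array(1L, d); gt[, , 5:8] <- 2L
  vol <- array(c(0.2, 0.8)[gt], d)
  vol[4, 4, 2] <- 0.8            # lone bright voxel deep in the dark region
  v <- mri_volume(vol)
  mask <- array(TRUE, d)
  ffcm <- fit_fcm(v, mask, cluster_config(K = 2, n = 100))
  frf <- fit_rfcm(v, mask, cluster_config(K = 2, beta = 1, n = 100))
  expect_equal(hard_labels(ffcm)[4, 4, 2], 2L)   # FCM keeps the outlier
  expect_equal(hard_labels(frf)[4, 4, 2], 1L)    # RFCM smooths it away
  # everything else is unchanged by the penalty
  keep <- array(TRUE, d); keep[4, 4, 2] <- FALSE
  expect_equal(hard_labels(frf)[keep], gt[keep])
})

test_that("a dominant atlas penalty forces the atlas labeling", {
  set.seed(3)
  d <- c(8, 8, 8)
  lab <- array(sample(1:3, prod(d), TRUE), d)
  # class-ordered intensities with noise heavy enough that plain FCM
  # would mislabel many voxels; the atlas term must override it
  v <- mri_volume(array(c(0.2, 0.5, 0.8)[lab] + rnorm(prod(d), 0, 0.15), d),
                  validate = TRUE)
  mask <- array(TRUE, d)
  atlas <- onehot_atlas(lab)
  fit <- fit_arfcm(v, mask, atlas,
                   cluster_config(gamma = 1e6, w = 1, n = 50))
  expect_equal(hard_labels(fit)[mask], lab[mask])
})

test_that("permuting atlas channel order leaves the sorted labeling alone", {
  set.seed(5)
  b <- generate_phantom(phantom_spec(shape = c(16, 16, 16), noise_sigma = 0.03,
                                     seed = 5))
  fit1 <- fit_arfcm(b$t1, b$mask, b$atlas)
  perm <- prob_atlas(b$atlas$probs[, , , c(3, 1, 2)])
  fit2 <- fit_arfcm(b$t1, b$mask, perm)
  expect_equal(hard_labels(fit1), hard_labels(fit2))
})

test_that("noiseless separated phantoms are recovered exactly", {
  # flat interfaces: all three fitters, including the spatial penalty
  sl <- slab_phantom()
  atlas <- onehot_atlas(sl$gt)
  for (fit in list(fit_fcm(sl$t1, sl$mask),
                   fit_rfcm(sl$t1, sl$mask),
                   fit_arfcm(sl$t1, sl$mask, atlas)))
    expect_equal(hard_labels(fit), sl$gt,
                 label = paste(fit$method, "exact recovery"))
  # curved geometry: the pure-intensity and atlas fitters stay exact
  b <- generate_phantom(default_validation_suite(seed = 2)$clean)
  expect_equal(hard_labels(fit_fcm(b$t1, b$mask))[b$mask], b$gt_labels[b$mask])
  expect_equal(hard_labels(fit_arfcm(b$t1, b$mask, b$atlas))[b$mask],
               b$gt_labels[b$mask])
})

test_that("RFCM beats FCM on white matter under heavy noise", {
  b <- generate_phantom(default_validation_suite(seed = 4)$noisy)
  dsc <- function(fit) evaluate_segmentation(hard_labels(fit), b$gt_labels,
                                             metrics = "dsc")$dsc
  expect_gt(dsc(fit_rfcm(b$t1, b$mask))[3], dsc(fit_fcm(b$t1, b$mask))[3])
})

test_that("hard_labels matches a per-voxel max scan and breaks ties low", {
  # stated tie rule
  u <- rbind(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5), c(1 / 3, 1 / 3, 1 / 3))
  mask <- array(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), c(2, 2, 2))
  lab <- hard_labels(u, mask)
  expect_equal(lab[mask], c(1L, 3L, 1L))
  expect_true(all(lab[!mask] == 0L))
  # seeded random membership vs brute-force oracle
  set.seed(9)
  d <- c(6, 6, 6)
  m2 <- array(runif(prod(d)) < 0.7, d)
  um <- matrix(runif(sum(m2) * 3), ncol = 3)
  um <- um / rowSums(um)
  expect_identical(hard_labels(um, m2), oracle_argmax_labels(um, m2))
})

test_that("one-hot membership reproduces its own labeling", {
  d <- c(5, 5, 5)
  mask <- array(TRUE, d)
  lab <- array(sample(1:3, prod(d), TRUE), d)
  u <- matrix(0, prod(d), 3)
  u[cbind(seq_len(prod(d)), lab[mask])] <- 1
  expect_identical(hard_labels(u, mask), lab)
})

test_that("boundary redistribution follows the membership-prior product", {
  d <- c(6, 6, 6)
  mask <- array(TRUE, d)
  # two-region labeling: boundary voxels are the interface planes
  lab <- array(2L, d); lab[, , 1:3] <- 3L
  n <- sum(mask)
  u <- matrix(0, n, 3)
  u[cbind(seq_len(n), lab[mask])] <- 1
  # hand example at one boundary voxel: u (0.1, 0.45, 0.45),
  # prior (0.1, 0.2, 0.7) -> WM wins on the product
  probs <- array(0, c(d, 3))
  probs[, , , 1] <- 0.1; probs[, , , 2] <- 0.2; probs[, , , 3] <- 0.7
  atlas <- prob_atlas(probs)
  target <- which(mask)
  vox <- which(arrayInd(target, d)[, 3] == 4)[1]   # a GM boundary voxel
  u[vox, ] <- c(0.1, 0.45, 0.45)
  out <- redistribute_boundaries(lab, u, atlas, mask)
  expect_equal(out[target[vox]], 3L)

  # uniform region: no boundary voxels, exact no-op
  uni <- array(2L, d)
  expect_identical(redistribute_boundaries(uni, u, atlas, mask), uni)

  # uniform morphological prior cancels: redistribution = plain argmax
  flat <- prob_atlas(array(1 / 3, c(d, 3)))
  set.seed(2)
  u2 <- matrix(runif(n * 3), ncol = 3); u2 <- u2 / rowSums(u2)
  lab2 <- hard_labels(u2, mask)
  expect_identical(redistribute_boundaries(lab2, u2, flat, mask), lab2)
})

test_that("fit objects expose the modelling-idiom methods", {
  sl <- slab_phantom()
  fit <- fit_fcm(sl$t1, sl$mask)
  expect_named(coef(fit), c("CSF", "GM", "WM"))
  expect_equal(unname(coef(fit)), c(0.2, 0.5, 0.8), tolerance = 1e-6)
  expect_output(print(fit), "fcm_fit")
  expect_output(print(summary(fit)), "centroids")
  fm <- fitted(fit)
  expect_equal(dim(fm), c(dim(sl$t1$data), 3L))
  expect_lt(max(abs(apply(fm, 1:3, sum)[sl$mask] - 1)), 1e-9)
})
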