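#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> method: %s, K = %d\n", x$method, x$config$K))
  cat(sprintf("  centroids: %s\n",
              paste(format(x$centroids, digits = 4), collapse = ", ")))
  cat(sprintf("  %d/%d iterations, %s (thr = %g)\n", x$iterations_used,
              x$config$n, if (x$converged) "converged" else "not converged",
              x$config$thr))
  invisible(x)
}

#' @export
summary.fcm_fit <- function(object, ...) {
  lab <- hard_labels(object)
  counts <- tabulate(lab[object$mask], nbins = object$config$K)
  structure(list(method = object$method, config = object$config,
                 centroids = object$centroids,
                 iterations_used = object$iterations_used,
                 converged = object$converged,
                 objective_first = object$objective_trace[1],
                 objective_last = utils::tail(object$objective_trace, 1),
                 class_voxels = counts,
                 n_masked = sum(object$mask)),
            class = "summary.fcm_fit")
}

#' @export
print.summary.fcm_fit <- function(x, ...) {
  cat(sprintf("Fuzzy C-means fit (%s), K = %d, %d masked voxels\n",
              x$method, x$config$K, x$n_masked))
  cat(sprintf("  centroids : %s\n",
              paste(format(x$centroids, digits = 4), collapse = ", ")))
  cat(sprintf("  objective : %.6g -> %.6g over %d iterations (%s)\n",
              x$objective_first, x$objective_last, x$iterations_used,
              if (x$converged) "converged" else "cap reached"))
  tn <- if (x$config$K == 3) names(TISSUE_LABELS) else
    paste0("class", seq_len(x$config$K))
  cat("  hard-label voxel counts:\n")
  for (k in seq_len(x$config$K))
    cat(sprintf("    %-5s %d\n", tn[k], x$class_voxels[k]))
  invisible(x)
}

#' @export
coef.fcm_fit <- function(object, ...) {
  v <- object$centroids
  names(v) <- if (object$config$K == 3) names(TISSUE_LABELS) else
    paste0("class", seq_along(v))
  v
}

#' Membership field as a 4-D array
#'
#' @param object an `fcm_fit`.
#' @param ... unused.
#' @return 4-D array (x, y, z, class) of memberships; zero outside the
#'   mask.
#' @export
fitted.fcm_fit <- function(object, ...) {
  d <- object$dim
  K <- object$config$K
  out <- array(0, c(d, K))
  idx <- which(object$mask)
  nvox <- prod(d)
  for (k in seq_len(K))
    out[idx + (k - 1) * nvox] <- object$membership[, k]
  out
}

#' Plot the objective trace of a fit
#'
#' @param x an `fcm_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.fcm_fit <- function(x, ...) {
  graphics::plot(seq_along(x$objective_trace), x$objective_trace,
                 type = "b", pch = 16, cex = 0.6,
                 xlab = "iteration", ylab = "objective J",
                 main = sprintf("%s energy minimization", x$method), ...)
  invisible(x)
}
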