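#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the points to their
#' centroid — the size measure removed by full Procrustes scaling.
#'
#' @param points An `k x 2` matrix (or a `hip_landmarks` object).
#' @return A positive scalar (same units as the coordinates).
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(points) {
  if (inherits(points, "hip_landmarks")) points <- points$points
  stopifnot(nrow(points) >= 2)
  centred <- sweep(points, 2, colMeans(points))
  s <- sqrt(sum(centred^2))
  if (s < 1e-12) stop("degenerate shape: all points identical")
  s
}

#' Optimal rotation aligning one centred shape onto another
#'
#' Closed-form least-squares rotation (reflections excluded, determinant
#' +1) from the SVD of the 2 x 2 cross-covariance between the shape and
#' the reference. Both inputs must already be centred.
#'
#' @param shape,reference Centred `k x 2` coordinate matrices.
#' @return A `2 x 2` rotation matrix `R` such that `shape %*% R` is as
#'   close as possible to `reference` in summed squared distance.
#' @export
optimal_rotation <- function(shape, reference) {
  stopifnot(nrow(shape) == nrow(reference))
  if (max(abs(colMeans(shape))) > 1e-6 || max(abs(colMeans(reference))) > 1e-6) {
    stop("optimal_rotation expects centred shapes")
  }
  m <- crossprod(shape, reference)
  if (sqrt(sum(m^2)) < 1e-12) {
    warning("zero cross-covariance: returning identity rotation")
    return(diag(2))
  }
  sv <- svd(m)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes alignment of a set of configurations
#'
#' Iterative superimposition removing position, scale and orientation:
#' every shape is centred and scaled to unit centroid size, rotated onto
#' the current consensus, and the consensus is recomputed as the
#' coordinate-wise mean re-normalised to unit centroid size (fixing the
#' scale gauge). The consensus is initialised from the first shape;
#' iteration stops when the root-mean-square consensus change drops below
#' `tol`. Reflections are never used; pool left hips with [mirror_left()]
#' before alignment.
#'
#' @param shapes A list of `k x 2` matrices or `hip_landmarks` objects
#'   (at least 2, equal point counts), or an `n x 2k` matrix of flattened
#'   shapes.
#' @param tol Convergence tolerance on the RMS consensus change.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `gpa_alignment`: list with `aligned`
#'   (`n x 2k` matrix of flattened aligned coordinates, rows named by hip
#'   id when available), `consensus` (length `2k`), `centroid_sizes`,
#'   `iterations`, `converged`, and `rss` (per-iteration summed squared
#'   Procrustes residuals).
#' @export
generalized_procrustes <- function(shapes, tol = 1e-8, max_iter = 100) {
  mats <- shapes_as_matrices(shapes)
  n <- length(mats)
  if (n < 2) stop("need at least 2 shapes for Procrustes alignment")
  k <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == k)) {
    stop("all shapes must have the same number of points")
  }

  sizes <- vapply(mats, centroid_size, numeric(1))
  unitized <- lapply(mats, function(p) {
    centred <- sweep(p, 2, colMeans(p))
    centred / sqrt(sum(centred^2))
  })

  consensus <- unitized[[1]]
  converged <- FALSE
  iterations <- 0L
  rss_trace <- numeric(0)
  aligned <- unitized
  for (it in seq_len(max_iter)) {
    iterations <- it
    aligned <- lapply(unitized, function(p) p %*% optimal_rotation(p, consensus))
    rss_trace <- c(
      rss_trace,
      sum(vapply(aligned, function(p) sum((p - consensus)^2), numeric(1)))
    )
    new_consensus <- Reduce(`+`, aligned) / n
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Procrustes alignment did not converge in ", max_iter,
            " iterations (last RMS change above ", tol, ")")
  }
  ## final rotation pass against the converged consensus
  aligned <- lapply(unitized, function(p) p %*% optimal_rotation(p, consensus))

  mat <- t(vapply(aligned, flatten_points, numeric(2 * k)))
  rownames(mat) <- names(mats)
  structure(
    list(
      aligned = mat,
      consensus = flatten_points(consensus),
      centroid_sizes = stats::setNames(sizes, names(mats)),
      iterations = iterations,
      converged = converged,
      rss = rss_trace
    ),
    class = "gpa_alignment"
  )
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat("<gpa_alignment> ", nrow(x$aligned), " shapes, ",
      ncol(x$aligned) / 2, " points; ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

shapes_as_matrices <- function(shapes) {
  if (is.matrix(shapes)) {
    shapes <- lapply(seq_len(nrow(shapes)), function(i) {
      unflatten_points(shapes[i, ])
    })
  }
  lapply(shapes, function(s) {
    if (inherits(s, "hip_landmarks")) s$points else as.matrix(s)
  })
}

#' Mirror a left-hip configuration into the right-hip frame
#'
#' Negates the x coordinate of every point so left and right hips can be
#' pooled into one per-sex shape model. Must be applied before Procrustes
#' alignment; applying it to a right hip is an error (mirroring twice
#' would silently flip chirality).
#'
#' @param config A `hip_landmarks` object with `side == "left"`.
#' @return The mirrored configuration, with `side` relabelled
#'   `"right_mirrored"`.
#' @export
mirror_left <- function(config) {
  stopifnot(inherits(config, "hip_landmarks"))
  if (!identical(config$side, "left")) {
    stop("mirror_left applies only to left hips (got side = '",
         config$side, "')")
  }
  config$points <- mirror_points(config$points)
  config$side <- "right_mirrored"
  config
}

#' @rdname mirror_left
#' @param points A `k x 2` coordinate matrix.
#' @return `mirror_points()`: the matrix with `x` negated (an involution
#'   that preserves centroid size).
#' @export
mirror_points <- function(points) {
  points[, 1] <- -points[, 1]
  points
}
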