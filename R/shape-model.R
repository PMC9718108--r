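#' Fit a PCA shape model to aligned configurations
#'
#' Principal-component decomposition of Procrustes-aligned landmark
#' coordinates: the mean shape plus orthonormal modes of variation sorted
#' by descending eigenvalue. Scores are the projections of each centred
#' shape onto the modes; standardized scores are scaled per mode to mean 0
#' and SD 1 (n - 1 denominator), so one unit of a standardized score is one
#' SD of that shape mode — the unit in which all downstream associations
#' are expressed. Mode signs are fixed by making each mode's
#' largest-magnitude loading positive.
#'
#' @param aligned A `gpa_alignment` from [generalized_procrustes()], or an
#'   `n x 2k` matrix of flattened aligned shapes.
#' @param sex Optional stratum label stored in the model.
#' @return An object of class `shape_model`: `consensus` (length 2k),
#'   `modes` (`2k x r` orthonormal columns), `eigenvalues` (descending),
#'   `variance_fraction`, `scores` (`n x r`), `standardized_scores`,
#'   `score_sds`, `n_shapes` and `sex`. Rank `r` is capped at
#'   `min(n - 1, 2k - 4)`.
#' @export
fit_shape_model <- function(aligned, sex = NA_character_) {
  mat <- if (inherits(aligned, "gpa_alignment")) aligned$aligned else as.matrix(aligned)
  n <- nrow(mat)
  if (n < 3) stop("need at least 3 shapes to fit a shape model (got ", n, ")")
  p <- ncol(mat)

  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  rank_cap <- min(n - 1, p - 4)
  keep <- which(pc$sdev > 1e-12)
  keep <- keep[keep <= rank_cap]

  modes <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  ## sign convention: largest-|loading| entry of each mode positive
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) {
      modes[, j] <- -modes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eigenvalues <- pc$sdev[keep]^2
  total_var <- sum(pc$sdev^2)
  score_sds <- pc$sdev[keep]

  colnames(modes) <- colnames(scores) <- paste0("mode", seq_along(keep))
  standardized <- sweep(scores, 2, score_sds, "/")

  structure(
    list(
      consensus = colMeans(mat),
      modes = modes,
      eigenvalues = eigenvalues,
      variance_fraction = eigenvalues / total_var,
      total_variance = total_var,
      scores = scores,
      standardized_scores = standardized,
      score_sds = score_sds,
      n_shapes = n,
      sex = sex
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat("<shape_model>", if (!is.na(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  ", x$n_shapes, " shapes, ", length(x$eigenvalues), " modes; first ",
      min(3, length(x$eigenvalues)), " explain ",
      sprintf("%.1f%%", 100 * sum(utils::head(x$variance_fraction, 3))),
      " of variance\n", sep = "")
  invisible(x)
}

#' Select shape modes by variance explained
#'
#' Returns the indices of the modes whose (unrounded) fraction of total
#' shape variation is at least `threshold`, preserving eigenvalue order.
#' The default 0.01 keeps every mode explaining at least 1.00% of total
#' variation — the inclusion rule used to limit multiple testing.
#'
#' @param model A [fit_shape_model()] result.
#' @param threshold Minimum variance fraction (default 0.01).
#' @return An integer vector of mode indices (possibly empty).
#' @export
select_modes <- function(model, threshold = 0.01) {
  stopifnot(inherits(model, "shape_model"), threshold >= 0, threshold < 1)
  which(model$variance_fraction >= threshold)
}

#' Shape at k standard deviations along a mode
#'
#' The consensus displaced by `k_sd` in-sample score SDs along one mode —
#' the standard visualisation of what a shape mode does (e.g. mean shape
#' at -3, 0, +3 SD).
#'
#' @param model A [fit_shape_model()] result.
#' @param mode_index Mode number (1-based).
#' @param k_sd Signed number of score SDs.
#' @return A `k x 2` matrix of landmark coordinates.
#' @export
mode_shape_at <- function(model, mode_index, k_sd) {
  stopifnot(inherits(model, "shape_model"))
  if (mode_index < 1 || mode_index > ncol(model$modes)) {
    stop("mode index out of range: ", mode_index, " (model has ",
         ncol(model$modes), " modes)")
  }
  flat <- model$consensus +
    k_sd * model$score_sds[mode_index] * model$modes[, mode_index]
  unflatten_points(flat)
}

#' Project shapes onto a fitted model's modes
#'
#' Raw scores are inner products of the centred shape with each mode;
#' [standardize_scores()] scales raw scores by the in-sample per-mode SD
#' (mean 0, SD 1 over the training set), the unit of downstream analysis.
#'
#' @param model A [fit_shape_model()] result.
#' @param shape A flattened shape vector (length 2k), a `k x 2` matrix, or
#'   an `n x 2k` matrix of flattened shapes.
#' @return `project()`: raw scores (vector, or `n x r` matrix).
#' @export
project <- function(model, shape) {
  stopifnot(inherits(model, "shape_model"))
  if (is.matrix(shape) && ncol(shape) == 2) shape <- flatten_points(shape)
  if (is.matrix(shape)) {
    if (ncol(shape) != length(model$consensus)) {
      stop("dimension mismatch: shapes have ", ncol(shape),
           " coordinates, model expects ", length(model$consensus))
    }
    centred <- sweep(shape, 2, model$consensus)
    return(centred %*% model$modes)
  }
  if (length(shape) != length(model$consensus)) {
    stop("dimension mismatch: shape has ", length(shape),
         " coordinates, model expects ", length(model$consensus))
  }
  drop(crossprod(model$modes, shape - model$consensus))
}

#' @rdname project
#' @param scores Raw scores from [project()] (defaults to the training
#'   scores).
#' @return `standardize_scores()`: scores divided per mode by the
#'   in-sample SD.
#' @export
standardize_scores <- function(model, scores = model$scores) {
  stopifnot(inherits(model, "shape_model"))
  if (is.matrix(scores)) {
    sweep(scores, 2, model$score_sds, "/")
  } else {
    scores / model$score_sds
  }
}

#' Reconstruct a shape from its mode scores
#'
#' @param model A [fit_shape_model()] result.
#' @param scores Raw scores (length up to the model rank).
#' @return A flattened shape vector `consensus + modes %*% scores`.
#' @export
reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "shape_model"))
  r <- length(scores)
  model$consensus + drop(model$modes[, seq_len(r), drop = FALSE] %*% scores)
}

#' Per-mode variance-explained table
#'
#' Percentages of total shape variation per mode, to one decimal, with
#' cumulative percentages computed on the unrounded fractions and rounded
#' only for display (so the cumulative column is internally consistent
#' even when the rounded per-mode values are not).
#'
#' @param model A [fit_shape_model()] result.
#' @return A data.frame with columns `mode`, `pct_variance`,
#'   `cum_pct_variance`.
#' @export
variance_table <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  frac <- model$variance_fraction
  data.frame(
    mode = seq_along(frac),
    pct_variance = round(100 * frac, 1),
    cum_pct_variance = round(100 * cumsum(frac), 1)
  )
}
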