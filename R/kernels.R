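#' Kernel specification for one feature group
#'
#' Each feature group (M = per-VOI means, S = per-VOI sds, A = pair
#' asymmetries) is handled by its own kernel; the combined machine uses the
#' weighted sum of the three. The published assignment is linear for M,
#' second-order polynomial for S and Gaussian for A, but any assignment can
#' be configured (all six permutations of the ablation grid are runnable).
#'
#' @param group `"M"`, `"S"` or `"A"`.
#' @param kind `"linear"` (`x . y`), `"polynomial2"` (`(x . y + 1)^2`) or
#'   `"gaussian"` (`exp(-||x - y||^2 / (2 sigma^2))`).
#' @param sigma Gaussian bandwidth (> 0). `NULL` defers to the median
#'   heuristic at training time (median pairwise distance of the group's
#'   training vectors).
#' @param weight Kernel weight beta (> 0).
#' @param scale Trace normalizer: the raw kernel is divided by `scale` so
#'   every group kernel has unit mean self-similarity on the training set
#'   and the weights beta are comparable across groups. `NULL` defers to
#'   training time (mean kernel diagonal); 1 disables normalization.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(group, kind = c("linear", "polynomial2", "gaussian"),
                        sigma = NULL, weight = 1, scale = NULL) {
  kind <- match.arg(kind)
  if (!is.null(sigma) && sigma <= 0) abort("`sigma` must be positive.")
  if (!is.null(scale) && scale <= 0) abort("`scale` must be positive.")
  if (weight <= 0) abort("Kernel weight beta must be positive.")
  structure(list(group = group, kind = kind, sigma = sigma, weight = weight,
                 scale = scale),
            class = "kernel_spec")
}

#' Default kernel assignment for the three feature groups
#'
#' @param kinds Named character vector mapping group to kernel kind.
#' @param weights Named numeric vector of kernel weights beta.
#' @param sigma Gaussian bandwidth passed to any `"gaussian"` entry.
#' @return Named list of three [kernel_spec()] objects.
#' @export
default_kernel_specs <- function(kinds = c(M = "linear", S = "polynomial2",
                                           A = "gaussian"),
                                 weights = c(M = 1, S = 1, A = 1),
                                 sigma = NULL) {
  specs <- lapply(c(M = "M", S = "S", A = "A"), function(g)
    kernel_spec(g, kinds[[g]],
                sigma = if (kinds[[g]] == "gaussian") sigma else NULL,
                weight = weights[[g]]))
  specs
}

#' Kernel value between two vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,y Numeric vectors of equal length from the spec's group.
#' @return The scalar kernel value.
#' @export
kernel_value <- function(spec, x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  switch(spec$kind,
         linear = sum(x * y),
         polynomial2 = (sum(x * y) + 1)^2,
         gaussian = {
           if (is.null(spec$sigma)) abort("Gaussian kernel needs `sigma`.")
           exp(-sum((x - y)^2) / (2 * spec$sigma^2))
         })
}

# Kernel matrix between the rows of X and Y (Y = NULL -> X vs X).
kernel_matrix <- function(spec, X, Y = NULL) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  K <- switch(spec$kind,
              linear = tcrossprod(X, Y),
              polynomial2 = (tcrossprod(X, Y) + 1)^2,
              gaussian = {
                if (is.null(spec$sigma)) abort("Gaussian kernel needs `sigma`.")
                d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
                exp(-pmax(d2, 0) / (2 * spec$sigma^2))
              })
  if (!is.null(spec$scale)) K / spec$scale else K
}

# Raw-kernel mean self-similarity of the rows of X (trace normalizer).
kernel_mean_diag <- function(spec, X) {
  X <- as.matrix(X)
  d <- switch(spec$kind,
              linear = rowSums(X^2),
              polynomial2 = (rowSums(X^2) + 1)^2,
              gaussian = rep(1, nrow(X)))
  m <- mean(d)
  if (!is.finite(m) || m <= 0) 1 else m
}

# Resolve deferred kernel parameters (gaussian sigma via the median
# heuristic, trace normalizer via the mean kernel diagonal) on training
# blocks (internal).
resolve_specs <- function(specs, blocks) {
  for (g in names(specs)) {
    if (specs[[g]]$kind == "gaussian" && is.null(specs[[g]]$sigma))
      specs[[g]]$sigma <- median_heuristic_sigma(blocks[[g]])
    if (is.null(specs[[g]]$scale))
      specs[[g]]$scale <- kernel_mean_diag(specs[[g]], blocks[[g]])
  }
  specs
}

#' Combined multi-kernel Gram matrix
#'
#' Entry (i, j) is the beta-weighted sum over the feature groups of the
#' group kernel between case i's and case j's group vectors. With every
#' beta > 0 the result is symmetric positive semidefinite, since each
#' summand is a PSD kernel.
#'
#' @param specs Named list of [kernel_spec()] (one per present group).
#' @param blocks_x Named list of numeric matrices (cases x features), one
#'   per group; all groups named in `specs` must be present.
#' @param blocks_y Optional second list (for train-vs-test rectangles);
#'   `NULL` = `blocks_x`.
#' @return The combined Gram matrix.
#' @export
combined_gram <- function(specs, blocks_x, blocks_y = NULL) {
  gs <- names(specs)
  miss <- setdiff(gs, names(blocks_x))
  if (length(miss))
    abort(paste0("Missing feature block(s): ", paste(miss, collapse = ", "), "."))
  G <- NULL
  for (g in gs) {
    Kg <- specs[[g]]$weight *
      kernel_matrix(specs[[g]], blocks_x[[g]],
                    if (is.null(blocks_y)) NULL else blocks_y[[g]])
    G <- if (is.null(G)) Kg else G + Kg
  }
  G
}

#' Median-heuristic Gaussian bandwidth
#'
#' The median Euclidean distance between distinct rows of `X`; a standard
#' scale-adaptive, deterministic default for the Gaussian kernel. Falls back
#' to 1 when the median distance is zero (all rows identical).
#'
#' @param X Numeric matrix of training vectors.
#' @return A positive scalar bandwidth.
#' @export
median_heuristic_sigma <- function(X) {
  d <- as.vector(stats::dist(as.matrix(X)))
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) 1 else m
}
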