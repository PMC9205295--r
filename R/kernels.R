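#' Kernel configuration
#'
#' Describes one of the seven supported kernel functions and its
#' hyperparameters. Defaults follow the package-wide convention:
#' `gamma = 1/p` (resolved against the marker count at computation time
#' when left `NULL`), `degree = 3`, `coef0 = 0`, arc-cosine depth 1.
#'
#' @param name one of `"linear"`, `"polynomial"`, `"sigmoid"`,
#'   `"gaussian"`, `"exponential"`, `"arc_cosine"`.
#' @param gamma positive bandwidth/scale multiplier, or `NULL` for `1/p`.
#' @param degree positive integer polynomial degree.
#' @param coef0 additive constant for polynomial/sigmoid kernels.
#' @param arc_depth depth L >= 1 of the arc-cosine kernel (number of
#'   recursive applications of the depth-1 angular transform; mimics an
#'   L-layer infinite-width network). Only meaningful for `arc_cosine`.
#' @return an object of class `kernel_config`.
#' @export
kernel_config <- function(name = c("linear", "polynomial", "sigmoid",
                                   "gaussian", "exponential", "arc_cosine"),
                          gamma = NULL, degree = 3L, coef0 = 0,
                          arc_depth = 1L) {
  name <- match.arg(name)
  if (!is.null(gamma)) {
    if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
      stop("'gamma' must be a single positive number")
    }
  }
  degree <- as.integer(degree)
  if (degree < 1) stop("'degree' must be a positive integer")
  arc_depth <- as.integer(arc_depth)
  if (arc_depth < 1) stop("'arc_depth' must be >= 1")
  structure(list(name = name, gamma = gamma, degree = degree,
                 coef0 = coef0, arc_depth = arc_depth),
            class = "kernel_config")
}

#' Compute a (cross-)kernel matrix between two sets of lines
#'
#' Evaluates the configured kernel between every line of `A` and every
#' line of `B`. Both matrices must share the same markers and, for kernels
#' that assume it, the same centering/scaling constants (use
#' [center_scale()] and [apply_scaling()]).
#'
#' Formulas, with x, z marker rows and p the marker count:
#' \itemize{
#'   \item linear: `x.z / p` (the genomic relationship kernel `XX'/p`)
#'   \item polynomial: `(gamma x.z + coef0)^degree`
#'   \item sigmoid: `tanh(gamma x.z + coef0)`
#'   \item gaussian: `exp(-gamma ||x - z||^2 / s)`
#'   \item exponential: `exp(-gamma ||x - z|| / sqrt(s))`
#'   \item arc-cosine depth 1:
#'     `(1/pi) ||x|| ||z|| (sin t + (pi - t) cos t)`, `t = acos(x.z / (||x|| ||z||))`;
#'     depth L applies the same angular transform recursively to the
#'     depth L-1 self- and cross-kernel values.
#' }
#'
#' For the Gaussian/exponential kernels the squared distances are divided
#' by `s`, the median nonzero pairwise squared distance of the reference
#' set `A` (the median heuristic), so that `gamma` stays dimensionless
#' across marker densities. Pass `scale_const = 1` for the raw form, or an
#' explicit `s` (e.g. the constant of an anchor/reference set) to keep a
#' cross-kernel on the same scale as a self-kernel.
#'
#' @param A,B numeric matrices (lines x markers) with line-id row names;
#'   `B` defaults to `A` (self-kernel).
#' @param config a [kernel_config()].
#' @param scale_const optional distance normalization constant `s`.
#' @return the `nrow(A) x nrow(B)` kernel matrix with line-id dimnames and
#'   attribute `kernel_config` (the config with `gamma` and `scale_const`
#'   resolved). Self-kernels are exactly symmetrized.
#' @export
compute_kernel <- function(A, B = NULL, config = kernel_config("linear"),
                           scale_const = NULL) {
  self <- is.null(B)
  A <- as_marker_matrix(A, min_rows = 1L)
  B <- if (self) A else as_marker_matrix(B, min_rows = 1L)
  if (ncol(A) != ncol(B)) {
    stop("marker count mismatch: A has ", ncol(A), " markers, B has ", ncol(B))
  }
  p <- ncol(A)
  gamma <- if (is.null(config$gamma)) 1 / p else config$gamma
  if (gamma <= 0) stop("'gamma' must be positive")

  K <- switch(config$name,
    linear = tcrossprod(A, B) / p,
    polynomial = (gamma * tcrossprod(A, B) + config$coef0)^config$degree,
    sigmoid = tanh(gamma * tcrossprod(A, B) + config$coef0),
    gaussian = ,
    exponential = {
      d2 <- pairwise_sqdist(A, B)
      if (is.null(scale_const)) scale_const <- median_sqdist(A)
      if (config$name == "gaussian") {
        exp(-gamma * d2 / scale_const)
      } else {
        exp(-gamma * sqrt(d2) / sqrt(scale_const))
      }
    },
    arc_cosine = arc_cosine_kernel(A, B, config$arc_depth)
  )
  if (self && nrow(K) == ncol(K)) K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(A), rownames(B))
  cfg <- config
  cfg$gamma <- gamma
  cfg$scale_const <- scale_const
  attr(K, "kernel_config") <- cfg
  K
}

# Pairwise squared Euclidean distances, clamped at 0 against cancellation.
pairwise_sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Median heuristic bandwidth: median of the nonzero pairwise squared
# distances of the set itself. Degenerates to 1 when all lines coincide.
median_sqdist <- function(A) {
  d2 <- as.numeric(stats::dist(A))^2
  d2 <- d2[d2 > 0]
  if (length(d2) == 0) {
    warning("all lines identical; using raw (s = 1) distance scale")
    return(1)
  }
  stats::median(d2)
}

# Arc-cosine kernel of depth L. The depth-1 self-kernel equals ||x||^2, so
# the diagonal terms of the recursion are invariant across depths and only
# the cross terms need updating. Zero-norm rows yield value 0.
arc_cosine_kernel <- function(A, B, depth) {
  kaa <- rowSums(A^2)
  kbb <- rowSums(B^2)
  kab <- tcrossprod(A, B)
  for (l in seq_len(depth)) {
    kab <- arc_cosine_step(kaa, kbb, kab)
  }
  kab
}

# One application of the angular transform to self/cross kernel values.
arc_cosine_step <- function(kaa, kbb, kab) {
  nn <- sqrt(outer(pmax(kaa, 0), pmax(kbb, 0)))
  cos_t <- ifelse(nn > 0, kab / nn, 0)
  cos_t <- pmin(1, pmax(-1, cos_t))
  theta <- acos(cos_t)
  (1 / pi) * nn * (sin(theta) + (pi - theta) * cos_t)
}

#' Symmetric positive-semidefinite square root of a kernel matrix
#'
#' Eigendecomposes a symmetric kernel, clamps eigenvalues below
#' `tol * lambda_max` (including all negatives, as arise for the sigmoid
#' kernel which is not PSD in general) to zero, and returns
#' `V diag(sqrt(lambda+)) V'`. The result `R` satisfies `R %*% R = K+`
#' where `K+` is `K` with the clamped spectrum.
#'
#' @param K square symmetric numeric matrix.
#' @param tol relative eigenvalue clamping threshold.
#' @return the symmetric PSD square root, same dimnames as `K`.
#' @export
kernel_sqrt <- function(K, tol = 1e-10) {
  K <- check_symmetric(K)
  eg <- eigen(K, symmetric = TRUE)
  lam <- eg$values
  lam_max <- max(lam, 0)
  clamped <- lam < tol * lam_max
  neg_mass <- sum(abs(lam[lam < 0]))
  tr <- sum(abs(lam))
  if (tr > 0 && neg_mass / tr > 0.01) {
    warning(sprintf(
      "clamped negative eigenvalue mass is %.1f%% of the spectrum; ",
      100 * neg_mass / tr),
      "the kernel is far from positive semidefinite")
  }
  lam[clamped] <- 0
  R <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(K)
  R
}

check_symmetric <- function(K, tol = 1e-8) {
  if (is.data.frame(K)) K <- as.matrix(K)
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("kernel must be a square matrix")
  }
  scale <- max(abs(K), 1e-300)
  if (max(abs(K - t(K))) > tol * scale) {
    stop("kernel is not symmetric within tolerance")
  }
  (K + t(K)) / 2
}

#' Line incidence matrix
#'
#' Builds the N x n 0/1 matrix mapping observations (e.g. line-environment
#' records) to the n lines indexing a kernel. Each row has exactly one 1.
#'
#' @param line_ids character vector of length N: the line of each observation.
#' @param levels the n line identifiers, in kernel order.
#' @return the incidence matrix with `line_ids` rownames, `levels` colnames.
#' @export
line_incidence <- function(line_ids, levels) {
  line_ids <- as.character(line_ids)
  unknown <- setdiff(unique(line_ids), levels)
  if (length(unknown) > 0) {
    stop("line ids absent from the kernel: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  Z <- matrix(0, nrow = length(line_ids), ncol = length(levels),
              dimnames = list(line_ids, levels))
  Z[cbind(seq_along(line_ids), match(line_ids, levels))] <- 1
  Z
}

#' Kernel-square-root design matrix
#'
#' The mechanism that turns any supervised learner into a kernel machine:
#' the observation-to-line incidence matrix is post-multiplied by the
#' symmetric square root of the kernel, yielding an N x n feature matrix
#' whose ridge fit is equivalent to the kernel mixed model.
#'
#' @param K square symmetric kernel over n lines (line-id dimnames).
#' @param Z either an N x n incidence matrix or a character vector of line
#'   ids (converted with [line_incidence()] against `rownames(K)`).
#'   Defaults to the identity (one observation per line).
#' @return the N x n design matrix `Z %*% kernel_sqrt(K)`.
#' @export
design_from_kernel <- function(K, Z = NULL) {
  K <- check_symmetric(K)
  R <- kernel_sqrt(K)
  if (is.null(Z)) return(R)
  if (is.character(Z) || is.factor(Z)) {
    Z <- line_incidence(as.character(Z), rownames(K))
  }
  if (ncol(Z) != nrow(K)) {
    stop("incidence has ", ncol(Z), " columns but the kernel indexes ",
         nrow(K), " lines")
  }
  Z %*% R
}
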