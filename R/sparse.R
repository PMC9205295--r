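#' Sparse-kernel (Nystrom) specification
#'
#' The compression level is the fraction of lines NOT used as anchors:
#' `lines_proportion = 1 - compression_level` and the anchor count is
#' `m = ceiling(lines_proportion * n)`. Higher compression means fewer
#' design columns and cheaper training.
#'
#' @param compression_level real in `[0, 1)`.
#' @param seed integer seed driving anchor subsampling.
#' @param eig_tol relative eigenvalue cutoff used when (pseudo-)inverting
#'   the anchor kernel; eigenvalues below `eig_tol * lambda_max` are
#'   discarded, which replaces a literal inverse and keeps rank-deficient
#'   anchor sets usable.
#' @return an object of class `sparse_spec`.
#' @export
sparse_spec <- function(compression_level = 0, seed = 1L, eig_tol = 1e-10) {
  if (!is.numeric(compression_level) || length(compression_level) != 1 ||
      compression_level < 0 || compression_level >= 1) {
    stop("'compression_level' must be in [0, 1)")
  }
  structure(list(compression_level = compression_level,
                 seed = as.integer(seed), eig_tol = eig_tol),
            class = "sparse_spec")
}

#' Select anchor lines for a sparse kernel
#'
#' Draws `m = ceiling((1 - compression_level) * n)` distinct line
#' identifiers uniformly without replacement, deterministically for a
#' fixed seed. Internally a full seeded permutation is drawn and its first
#' `m` elements taken, so for one seed the anchor sets at decreasing
#' compression levels are nested — the structure needed to study how the
#' approximation error shrinks as anchors are added.
#'
#' @param line_ids character vector of n line identifiers.
#' @param spec a [sparse_spec()].
#' @return `m` selected identifiers (all of `line_ids`, in original order,
#'   when `compression_level = 0`).
#' @export
select_anchor_lines <- function(line_ids, spec) {
  line_ids <- as.character(line_ids)
  n <- length(line_ids)
  if (n < 2) stop("need at least 2 lines")
  m <- ceiling((1 - spec$compression_level) * n)
  if (m < 2) stop("compression too aggressive: fewer than 2 anchor lines")
  if (spec$compression_level == 0) return(line_ids)
  perm <- with_seed(spec$seed, sample.int(n))
  line_ids[perm[seq_len(m)]]
}

#' Build the sparse (compressed) kernel design matrix
#'
#' Implements the Nystrom construction: select m anchor lines, compute the
#' anchor self-kernel `K_mm` and the cross-kernel `K_nm` between all n
#' lines and the anchors, eigendecompose `K_mm = U S U'`, truncate the
#' spectrum at `eig_tol * lambda_max`, and return the n x r design matrix
#' `P = K_nm U S^(-1/2)`. `P %*% t(P)` is the rank-`<= m` approximation
#' `Q = K_nm K_mm^-1 K_nm'` of the dense kernel, and `P` can be handed to
#' any learner as a feature matrix with only r columns.
#'
#' For distance-based kernels the normalization constant s is computed
#' once from the full line set, so `K_mm` and `K_nm` are exact slices of
#' the dense kernel and the approximation converges to it as m grows.
#'
#' @param X centered/scaled marker matrix over all n lines (a plain
#'   dosage matrix is centered/scaled automatically), or `NULL` when a
#'   precomputed dense kernel `K` is supplied.
#' @param config a [kernel_config()].
#' @param spec a [sparse_spec()].
#' @param K optional precomputed dense n x n kernel with line-id dimnames;
#'   when given, `K_mm` and `K_nm` are sliced from it instead of
#'   recomputed.
#' @return an object of class `sparse_design`: list with `P` (n x r,
#'   line-id rownames), `anchor_ids`, `eigenvalues` (the r retained
#'   eigenvalues, descending), `spec` and `config`.
#' @export
sparse_design <- function(X, config = kernel_config("linear"),
                          spec = sparse_spec(), K = NULL) {
  if (is.null(K)) {
    X <- as_marker_matrix(X)
    if (is.null(attr(X, "scale"))) X <- center_scale(X)
    ids <- rownames(X)
    anchors <- select_anchor_lines(ids, spec)
    s <- if (config$name %in% c("gaussian", "exponential")) {
      median_sqdist(X)
    } else NULL
    Knm <- compute_kernel(X, X[anchors, , drop = FALSE], config,
                          scale_const = s)
  } else {
    K <- check_symmetric(K)
    ids <- rownames(K) %||% paste0("L", seq_len(nrow(K)))
    rownames(K) <- colnames(K) <- ids
    anchors <- select_anchor_lines(ids, spec)
    Knm <- K[, anchors, drop = FALSE]
    config <- attr(K, "kernel_config") %||% config
  }
  Kmm <- Knm[match(anchors, ids), , drop = FALSE]
  Kmm <- (Kmm + t(Kmm)) / 2
  eg <- eigen(Kmm, symmetric = TRUE)
  lam_max <- max(eg$values, 0)
  keep <- eg$values > spec$eig_tol * lam_max
  if (!any(keep)) {
    stop("anchor kernel is numerically singular: no eigenvalue above ",
         "the truncation threshold")
  }
  U <- eg$vectors[, keep, drop = FALSE]
  S <- eg$values[keep]
  P <- Knm %*% U %*% diag(1 / sqrt(S), nrow = length(S))
  rownames(P) <- ids
  colnames(P) <- paste0("pc", seq_along(S))
  structure(list(P = P, anchor_ids = anchors, eigenvalues = S,
                 spec = spec, config = config),
            class = "sparse_design")
}

#' Reconstruct the approximated kernel from a sparse design
#'
#' Returns `Q = P %*% t(P)`, the Nystrom approximation
#' `K_nm K_mm^-1 K_nm'` of the dense kernel: symmetric, positive
#' semidefinite by construction, of rank at most m. With zero compression
#' and a full-rank kernel, `Q` equals the dense kernel.
#'
#' @param D a [sparse_design()].
#' @return the n x n approximated kernel matrix.
#' @export
reconstruct_kernel <- function(D) {
  stopifnot(inherits(D, "sparse_design"))
  Q <- tcrossprod(D$P)
  Q <- (Q + t(Q)) / 2
  attr(Q, "kernel_config") <- D$config
  Q
}

#' Serialize / load a sparse design
#'
#' `write_sparse_design()` writes `P` as a CSV (line-id first column) plus
#' a JSON sidecar (`<path>.json`) with anchor ids, spec and retained
#' eigenvalues; `read_sparse_design()` restores the object.
#'
#' @param D a [sparse_design()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); the restored `sparse_design`
#'   (reader).
#' @export
write_sparse_design <- function(D, path) {
  stopifnot(inherits(D, "sparse_design"))
  df <- data.frame(Line = rownames(D$P), D$P, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(anchor_ids = D$anchor_ids,
               eigenvalues = D$eigenvalues,
               spec = unclass(D$spec),
               config = unclass(D$config))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sparse_design
#' @export
read_sparse_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  P <- as.matrix(df[, -1, drop = FALSE])
  rownames(P) <- df[[1]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(sparse_spec, meta$spec[c("compression_level", "seed",
                                           "eig_tol")])
  cfg_fields <- meta$config[intersect(names(meta$config),
                                      c("name", "gamma", "degree", "coef0",
                                        "arc_depth"))]
  config <- do.call(kernel_config, cfg_fields)
  config$scale_const <- meta$config$scale_const
  structure(list(P = P, anchor_ids = meta$anchor_ids,
                 eigenvalues = meta$eigenvalues, spec = spec,
                 config = config),
            class = "sparse_design")
}
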