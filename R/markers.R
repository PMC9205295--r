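#' Center and scale a marker matrix
#'
#' Transforms a lines x markers dosage matrix so that every retained column
#' has mean 0 and unit sample (n - 1) standard deviation, the form all
#' kernels here expect. Monomorphic (zero-variance) columns carry no
#' information for prediction and are dropped; their names are recorded.
#' The centering/scaling constants are kept as attributes so that marker
#' profiles of new lines can be put on the identical scale with
#' [apply_scaling()].
#'
#' Applying `center_scale()` to an already centered/scaled matrix is a
#' no-op up to floating point, since the column means are then 0 and the
#' standard deviations 1.
#'
#' @param X numeric matrix (lines x markers). Row names are taken as line
#'   identifiers; when absent, `L1 ... Ln` are assigned.
#' @return the transformed matrix, with attributes `center`, `scale`
#'   (named constants of the retained columns) and `dropped` (names of
#'   removed zero-variance columns).
#' @examples
#' X <- matrix(c(0, 1, 2, 0, 0, 0), nrow = 3,
#'             dimnames = list(NULL, c("m1", "m2")))
#' Xs <- center_scale(X)  # m2 is monomorphic and dropped
#' attr(Xs, "dropped")
#' @export
center_scale <- function(X) {
  X <- as_marker_matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 1e-12
  if (!any(keep)) {
    stop("no informative markers: every column has zero variance")
  }
  dropped <- colnames(X)[!keep]
  Xs <- sweep(X[, keep, drop = FALSE], 2, mu[keep], "-")
  Xs <- sweep(Xs, 2, sdv[keep], "/")
  attr(Xs, "center") <- mu[keep]
  attr(Xs, "scale") <- sdv[keep]
  attr(Xs, "dropped") <- dropped
  Xs
}

#' Apply stored centering/scaling constants to new lines
#'
#' @param X_new numeric matrix of new lines (same marker columns as the
#'   matrix `reference` was derived from; extra columns are dropped).
#' @param reference a matrix returned by [center_scale()].
#' @return `X_new` restricted to the reference's retained markers and
#'   transformed with the reference constants.
#' @export
apply_scaling <- function(X_new, reference) {
  ctr <- attr(reference, "center")
  scl <- attr(reference, "scale")
  if (is.null(ctr) || is.null(scl)) {
    stop("'reference' does not carry centering/scaling constants; ",
         "use a matrix returned by center_scale()")
  }
  X_new <- as_marker_matrix(X_new, min_rows = 1L)
  missing_cols <- setdiff(names(ctr), colnames(X_new))
  if (length(missing_cols) > 0) {
    stop("markers absent from new data: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  X_new <- X_new[, names(ctr), drop = FALSE]
  Xs <- sweep(X_new, 2, ctr, "-")
  sweep(Xs, 2, scl, "/")
}

# Validate a marker matrix: numeric, finite, >= min_rows lines, >= 1 marker.
as_marker_matrix <- function(X, min_rows = 2L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("marker matrix must be a numeric matrix")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("marker matrix contains missing or non-finite entries")
  }
  if (nrow(X) < min_rows) {
    stop("marker matrix needs at least ", min_rows, " lines")
  }
  if (ncol(X) < 1) stop("marker matrix needs at least one marker")
  if (is.null(rownames(X))) rownames(X) <- paste0("L", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("M", seq_len(ncol(X)))
  X
}
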