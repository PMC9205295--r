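#' Regression metrics
#'
#' Standard genomic-prediction regression losses between observed and
#' predicted values: mean squared error, its root, mean absolute error,
#' and the mean arctangent absolute percentage error
#' `MAAPE = mean(atan(|(y - yhat) / y|))`, a bounded (`[0, pi/2]`)
#' analogue of MAPE that stays finite near zero-valued observations. A
#' case with `y = 0` and `yhat != 0` contributes the limit `pi/2`; the
#' number of such cases is attached as attribute `n_zero_observed`.
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @return a single numeric value.
#' @export
mse <- function(observed, predicted) {
  check_regression_pair(observed, predicted)
  mean((observed - predicted)^2)
}

#' @rdname mse
#' @export
rmse <- function(observed, predicted) sqrt(mse(observed, predicted))

#' @rdname mse
#' @export
mae <- function(observed, predicted) {
  check_regression_pair(observed, predicted)
  mean(abs(observed - predicted))
}

#' @rdname mse
#' @export
maape <- function(observed, predicted) {
  check_regression_pair(observed, predicted)
  err <- abs(observed - predicted)
  zero_y <- observed == 0
  ratio <- ifelse(zero_y, ifelse(err == 0, 0, Inf), abs(err / observed))
  out <- mean(atan(ratio))
  attr(out, "n_zero_observed") <- sum(zero_y & err > 0)
  out
}

#' Normalized root mean squared error
#'
#' RMSE divided by a scale of the observed values: their sample standard
#' deviation (default; a mean-predictor then scores `sqrt((n-1)/n)`),
#' mean, range, or interquartile range.
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @param type one of `"sd"`, `"mean"`, `"range"`, `"iqr"`.
#' @return a single numeric value.
#' @export
nrmse <- function(observed, predicted, type = c("sd", "mean", "range", "iqr")) {
  type <- match.arg(type)
  check_regression_pair(observed, predicted)
  norm <- switch(type,
    sd = stats::sd(observed),
    mean = mean(observed),
    range = diff(range(observed)),
    iqr = stats::IQR(observed)
  )
  if (is.na(norm) || norm == 0) {
    stop("zero or undefined '", type, "' normalizer for NRMSE")
  }
  rmse(observed, predicted) / norm
}

check_regression_pair <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' lengths differ")
  }
  if (length(observed) == 0) stop("empty input")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite values in input")
  }
  invisible(TRUE)
}

#' Confusion matrix
#'
#' Counts of observed (rows) against predicted (columns) class labels
#' over the union of observed levels. A predicted label outside the level
#' set is an error.
#'
#' @param observed,predicted label vectors of equal length.
#' @param levels optional explicit level set (order kept).
#' @return an L x L integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(observed, predicted, levels = NULL) {
  observed <- as.character(observed)
  predicted <- as.character(predicted)
  if (length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' lengths differ")
  }
  if (is.null(levels)) levels <- sort(unique(observed))
  bad <- setdiff(unique(predicted), levels)
  if (length(bad) > 0) {
    stop("predicted labels outside the level set: ",
         paste(bad, collapse = ", "))
  }
  cm <- table(factor(observed, levels = levels),
              factor(predicted, levels = levels))
  cm <- unclass(cm)
  dimnames(cm) <- list(observed = levels, predicted = levels)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

cm_of <- function(observed, predicted, levels = NULL) {
  if (inherits(observed, "confusion_matrix") && missing(predicted)) {
    return(observed)
  }
  confusion_matrix(observed, predicted, levels)
}

#' Classification metrics
#'
#' Standard label-based metrics. For binary problems the first level of
#' the level set is the positive class (override with `positive`); for
#' more than two classes, sensitivity/specificity/precision/recall/F1 are
#' macro-averaged one-vs-rest. `kappa_coeff` is Cohen's kappa with the
#' marginal-product chance expectation and `mcc` the multiclass Matthews
#' correlation (covariance form).
#'
#' @param observed,predicted label vectors of equal length.
#' @param levels optional explicit level set.
#' @param positive positive-class label for binary problems (default:
#'   first level).
#' @return a single numeric value.
#' @export
accuracy <- function(observed, predicted, levels = NULL) {
  cm <- cm_of(observed, predicted, levels)
  sum(diag(cm)) / sum(cm)
}

per_class_rates <- function(cm) {
  tot <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- tot - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

macro_or_positive <- function(cm, positive, rate_fn) {
  rates <- per_class_rates(cm)
  vals <- rate_fn(rates)
  if (nrow(cm) == 2) {
    pos <- positive %||% rownames(cm)[1]
    if (!pos %in% rownames(cm)) stop("unknown positive class: ", pos)
    return(unname(vals[pos]))
  }
  mean(vals, na.rm = TRUE)
}

#' @rdname accuracy
#' @export
sensitivity <- function(observed, predicted, levels = NULL, positive = NULL) {
  cm <- cm_of(observed, predicted, levels)
  macro_or_positive(cm, positive, function(r) r$tp / (r$tp + r$fn))
}

#' @rdname accuracy
#' @export
recall <- sensitivity

#' @rdname accuracy
#' @export
specificity <- function(observed, predicted, levels = NULL, positive = NULL) {
  cm <- cm_of(observed, predicted, levels)
  macro_or_positive(cm, positive, function(r) r$tn / (r$tn + r$fp))
}

#' @rdname accuracy
#' @export
precision <- function(observed, predicted, levels = NULL, positive = NULL) {
  cm <- cm_of(observed, predicted, levels)
  macro_or_positive(cm, positive, function(r) r$tp / (r$tp + r$fp))
}

#' @rdname accuracy
#' @export
f1_score <- function(observed, predicted, levels = NULL, positive = NULL) {
  cm <- cm_of(observed, predicted, levels)
  macro_or_positive(cm, positive, function(r) {
    2 * r$tp / (2 * r$tp + r$fp + r$fn)
  })
}

#' @rdname accuracy
#' @export
kappa_coeff <- function(observed, predicted, levels = NULL) {
  cm <- cm_of(observed, predicted, levels)
  tot <- sum(cm)
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' @rdname accuracy
#' @export
mcc <- function(observed, predicted, levels = NULL) {
  cm <- cm_of(observed, predicted, levels)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Probability-based classification metrics
#'
#' `brier_score` is the mean squared distance between the predicted
#' probability vectors and the one-hot encoding of the truth (for a
#' binary problem a bare probability vector of the positive class may be
#' given, yielding the classical `mean((p - y)^2)`). `roc_auc` uses the
#' rank (Mann-Whitney) formulation with midrank tie handling; `pr_auc` is
#' the average-precision form with tie groups processed atomically.
#' Multiclass versions are macro-averaged one-vs-rest over the
#' probability-matrix columns.
#'
#' @param observed label vector.
#' @param probabilities numeric matrix (rows = cases, columns named by
#'   class, each row summing to 1 within 1e-6) or, for binary problems, a
#'   vector of positive-class probabilities.
#' @param positive positive-class label used when `probabilities` is a
#'   vector (default: first level).
#' @return a single numeric value.
#' @export
brier_score <- function(observed, probabilities, positive = NULL) {
  observed <- as.character(observed)
  if (is.matrix(probabilities) || is.data.frame(probabilities)) {
    P <- check_prob_matrix(probabilities, observed)
    onehot <- outer(observed, colnames(P), "==") * 1
    return(mean(rowSums((P - onehot)^2)))
  }
  p <- check_prob_vector(probabilities, length(observed))
  pos <- positive %||% sort(unique(observed))[1]
  mean((p - (observed == pos))^2)
}

#' @rdname brier_score
#' @export
roc_auc <- function(observed, probabilities, positive = NULL) {
  observed <- as.character(observed)
  if (is.matrix(probabilities) || is.data.frame(probabilities)) {
    P <- check_prob_matrix(probabilities, observed)
    if (ncol(P) == 2) {
      pos <- positive %||% sort(unique(observed))[1]
      return(binary_roc_auc(observed == pos, P[, pos]))
    }
    aucs <- vapply(colnames(P), function(cl) {
      binary_roc_auc(observed == cl, P[, cl])
    }, numeric(1))
    return(mean(aucs, na.rm = TRUE))
  }
  p <- check_prob_vector(probabilities, length(observed))
  pos <- positive %||% sort(unique(observed))[1]
  binary_roc_auc(observed == pos, p)
}

binary_roc_auc <- function(is_pos, score) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname brier_score
#' @export
pr_auc <- function(observed, probabilities, positive = NULL) {
  observed <- as.character(observed)
  if (is.matrix(probabilities) || is.data.frame(probabilities)) {
    P <- check_prob_matrix(probabilities, observed)
    if (ncol(P) == 2) {
      pos <- positive %||% sort(unique(observed))[1]
      return(binary_pr_auc(observed == pos, P[, pos]))
    }
    aucs <- vapply(colnames(P), function(cl) {
      binary_pr_auc(observed == cl, P[, cl])
    }, numeric(1))
    return(mean(aucs, na.rm = TRUE))
  }
  p <- check_prob_vector(probabilities, length(observed))
  pos <- positive %||% sort(unique(observed))[1]
  binary_pr_auc(observed == pos, p)
}

# Average precision with ties processed as atomic groups (deterministic).
binary_pr_auc <- function(is_pos, score) {
  n1 <- sum(is_pos)
  if (n1 == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  is_pos <- is_pos[ord]
  score <- score[ord]
  groups <- cumsum(!duplicated(score))
  tp_g <- tapply(as.numeric(is_pos), groups, sum)
  n_g <- tapply(rep(1, length(groups)), groups, sum)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  sum(prec * tp_g) / n1
}

check_prob_matrix <- function(P, observed) {
  P <- as.matrix(P)
  if (nrow(P) != length(observed)) {
    stop("probability matrix rows must match the number of cases")
  }
  if (is.null(colnames(P))) {
    stop("probability matrix needs class-labelled columns")
  }
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("probabilities outside [0, 1]")
  }
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 (within 1e-6)")
  }
  missing_lv <- setdiff(unique(observed), colnames(P))
  if (length(missing_lv) > 0) {
    stop("no probability column for class: ",
         paste(missing_lv, collapse = ", "))
  }
  P
}

check_prob_vector <- function(p, n) {
  p <- as.numeric(p)
  if (length(p) != n) stop("probability vector length mismatch")
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("probabilities outside [0, 1]")
  }
  p
}

#' Full regression metric report
#'
#' Evaluates the complete regression metric set in one pass: MSE, RMSE,
#' the four NRMSE normalizations, MAE and MAAPE. Values equal the
#' individual metric calls exactly.
#'
#' @param observed,predicted numeric vectors.
#' @return a named list of class `metric_report`; `$nrmse` is itself a
#'   named vector over the four normalization types.
#' @export
numeric_summary <- function(observed, predicted) {
  structure(list(
    mse = mse(observed, predicted),
    rmse = rmse(observed, predicted),
    nrmse = c(sd = nrmse(observed, predicted, "sd"),
              mean = nrmse(observed, predicted, "mean"),
              range = nrmse(observed, predicted, "range"),
              iqr = nrmse(observed, predicted, "iqr")),
    mae = mae(observed, predicted),
    maape = as.numeric(maape(observed, predicted))
  ), class = "metric_report")
}

#' Full classification metric report
#'
#' Evaluates the complete classification metric set in one pass; the
#' probability-based members (Brier, ROC-AUC, PR-AUC) are `NA` when no
#' probabilities are supplied. The confusion matrix is attached as
#' attribute `confusion`.
#'
#' @param observed,predicted label vectors.
#' @param probabilities optional probability matrix (see [brier_score()]).
#' @param positive positive-class label for binary problems.
#' @return a named list of class `metric_report`.
#' @export
categorical_summary <- function(observed, predicted, probabilities = NULL,
                                positive = NULL) {
  lv <- sort(unique(as.character(observed)))
  cm <- confusion_matrix(observed, predicted, lv)
  rep_ <- list(
    accuracy = accuracy(cm),
    sensitivity = sensitivity(cm, positive = positive),
    specificity = specificity(cm, positive = positive),
    precision = precision(cm, positive = positive),
    recall = recall(cm, positive = positive),
    f1 = f1_score(cm, positive = positive),
    kappa = kappa_coeff(cm),
    mcc = mcc(cm),
    brier = NA_real_, roc_auc = NA_real_, pr_auc = NA_real_
  )
  if (!is.null(probabilities)) {
    rep_$brier <- brier_score(observed, probabilities, positive)
    rep_$roc_auc <- roc_auc(observed, probabilities, positive)
    rep_$pr_auc <- pr_auc(observed, probabilities, positive)
  }
  structure(rep_, class = "metric_report", confusion = cm)
}
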