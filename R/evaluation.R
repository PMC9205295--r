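#' Run the outer benchmarking protocol
#'
#' For each random partition and each model: tune on the training rows
#' only (inner CV), fit, predict the test rows, and append long-format
#' prediction records. No test row ever reaches tuning or fitting; the
#' whole run is deterministic under fixed seeds.
#'
#' @param pheno data frame with columns `Line`, `Env` and one trait
#'   column (the first remaining column is used).
#' @param features per-line feature source: a matrix with line-id row
#'   names (markers, kernel square root, or a [sparse_design()]'s `P`), a
#'   [sparse_design()], or a symmetric kernel matrix (required by
#'   `"bayesian_gblup"`, which consumes the kernel directly).
#' @param models character vector of model names (see [fit()]), or a
#'   named list `list(name = list(hyperparams = ..., space = ...))`.
#' @param partitions list of `$train`/`$test` observation-index sets from
#'   [make_random_partitions()]; by default 5 seeded 80/20 splits
#'   stratified by environment.
#' @param tune optional [tune_config()] applied to models with a `space`.
#' @param seed master seed (partitions and stochastic learners).
#' @return a `prediction_table` data frame with columns `model`, `fold`,
#'   `env`, `line`, `observed`, `predicted`.
#' @export
run_benchmark <- function(pheno, features, models = "bayesian_gblup",
                          partitions = NULL, tune = NULL, seed = NULL) {
  stopifnot(is.data.frame(pheno))
  need <- c("Line", "Env")
  if (!all(need %in% names(pheno))) {
    stop("'pheno' must have columns Line and Env")
  }
  trait <- setdiff(names(pheno), need)[1]
  if (is.na(trait)) stop("'pheno' has no trait column")
  y_all <- pheno[[trait]]
  lines <- as.character(pheno$Line)
  envs <- as.character(pheno$Env)

  if (inherits(features, "sparse_design")) features <- features$P
  features <- as.matrix(features)
  is_kernel <- nrow(features) == ncol(features) &&
    !is.null(rownames(features)) && !is.null(colnames(features)) &&
    identical(rownames(features), colnames(features)) &&
    max(abs(features - t(features))) < 1e-8 * max(abs(features), 1e-300)
  if (is.null(rownames(features))) {
    stop("'features' needs line-id row names")
  }
  missing_lines <- setdiff(unique(lines), rownames(features))
  if (length(missing_lines) > 0) {
    stop("lines absent from features: ",
         paste(utils::head(missing_lines, 10), collapse = ", "))
  }

  if (is.null(partitions)) {
    partitions <- make_random_partitions(nrow(pheno), 0.2, 5L,
                                         seed = seed, strata = envs)
  }
  if (is.character(models)) {
    models <- stats::setNames(rep(list(list()), length(models)), models)
  }

  rows <- list()
  for (model_name in names(models)) {
    mspec <- models[[model_name]]
    kernel_mode <- model_name == "bayesian_gblup"
    if (kernel_mode && !is_kernel) {
      stop("bayesian_gblup requires a symmetric kernel as 'features'")
    }
    for (f in seq_along(partitions)) {
      tr <- partitions[[f]]$train
      te <- partitions[[f]]$test
      if (length(intersect(tr, te)) > 0) stop("overlapping partition")
      fseed <- child_seed(seed, f)
      if (kernel_mode) {
        K_tr <- features[lines[tr], lines[tr], drop = FALSE]
        m <- fit_gblup(K_tr, y_all[tr], seed = fseed)
        K_cross <- features[lines[te], lines[tr], drop = FALSE]
        pred <- stats::predict(m, K_new = K_cross)
      } else {
        X_tr <- features[lines[tr], , drop = FALSE]
        m <- fit(model_name, X_tr, y_all[tr],
                 hyperparams = mspec$hyperparams %||% list(),
                 space = mspec$space, tune = tune, seed = fseed)
        pred <- stats::predict(m, features[lines[te], , drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = model_name, fold = f, env = envs[te], line = lines[te],
        observed = y_all[te],
        predicted = if (is.list(pred)) pred$class else pred,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Summarize prediction performance per environment and globally
#'
#' For every (model, environment, fold) cell the full metric set is
#' computed; per environment the mean and standard error (`sd /
#' sqrt(folds)`) over folds are reported. The `Global` rows pool all
#' environments within each fold before computing the metrics, then
#' average over folds — the across-environment protocol of multi-
#' environment genomic-prediction benchmarks. Cells too small for a
#' metric (e.g. sd-normalized NRMSE on fewer than 2 records) yield `NA`
#' with a warning.
#'
#' @param preds a `prediction_table` (columns `fold`, `env`, `line`,
#'   `observed`, `predicted`, optionally `model`).
#' @param response_type `"continuous"` or `"categorical"`; inferred from
#'   `observed` when `NULL`.
#' @param global_from_env_means if `TRUE`, the Global mean is the average
#'   of environment means instead of the pooled-per-fold computation
#'   (non-default alternative).
#' @return a `summary_table` data frame with columns `model`, `metric`,
#'   `env` (including `"Global"`), `mean`, `se`.
#' @export
summaries <- function(preds, response_type = NULL,
                      global_from_env_means = FALSE) {
  stopifnot(is.data.frame(preds), nrow(preds) > 0)
  if (!all(c("fold", "env", "observed", "predicted") %in% names(preds))) {
    stop("'preds' must have columns fold, env, observed, predicted")
  }
  if (!"model" %in% names(preds)) preds$model <- "model"
  response_type <- response_type %||%
    if (is.numeric(preds$observed)) "continuous" else "categorical"

  cell_metrics <- function(obs, pred) {
    if (response_type == "continuous") {
      nr <- tryCatch(nrmse(obs, pred, "sd"), error = function(e) {
        warning("NRMSE undefined in a cell (", conditionMessage(e), ")",
                call. = FALSE)
        NA_real_
      })
      c(MAAPE = as.numeric(maape(obs, pred)), MAE = mae(obs, pred),
        MSE = mse(obs, pred), NRMSE = nr, RMSE = rmse(obs, pred))
    } else {
      lv <- sort(unique(as.character(obs)))
      cmx <- confusion_matrix(obs, pred, lv)
      c(accuracy = accuracy(cmx), kappa = kappa_coeff(cmx),
        sensitivity = sensitivity(cmx), specificity = specificity(cmx),
        f1 = f1_score(cmx))
    }
  }

  out <- list()
  for (mod in unique(preds$model)) {
    pm <- preds[preds$model == mod, , drop = FALSE]
    folds <- sort(unique(pm$fold))
    env_levels <- c(sort(unique(pm$env)), "Global")
    for (ev in env_levels) {
      per_fold <- lapply(folds, function(f) {
        cell <- if (ev == "Global") {
          pm[pm$fold == f, , drop = FALSE]
        } else {
          pm[pm$fold == f & pm$env == ev, , drop = FALSE]
        }
        if (nrow(cell) == 0) return(NULL)
        cell_metrics(cell$observed, cell$predicted)
      })
      per_fold <- per_fold[!vapply(per_fold, is.null, logical(1))]
      if (length(per_fold) == 0) next
      M <- do.call(rbind, per_fold)
      if (ev == "Global" && global_from_env_means) {
        env_rows <- out[vapply(out, function(r) r$env != "Global" &&
                                 r$model == mod, logical(1))]
        for (metric in colnames(M)) {
          vals <- vapply(env_rows[vapply(env_rows, function(r) {
            r$metric == metric
          }, logical(1))], function(r) r$mean, numeric(1))
          out[[length(out) + 1L]] <- data.frame(
            model = mod, metric = metric, env = "Global",
            mean = mean(vals), se = NA_real_)
        }
        next
      }
      for (metric in colnames(M)) {
        v <- M[, metric]
        out[[length(out) + 1L]] <- data.frame(
          model = mod, metric = metric, env = ev,
          mean = mean(v, na.rm = TRUE),
          se = if (sum(!is.na(v)) >= 2) {
            stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
          } else NA_real_)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("summary_table", "data.frame")
  res
}

#' Percent outperformance between two mean squared errors
#'
#' The relative-MSE comparison used when ranking models:
#' `100 * (mse_reference - mse_better) / mse_reference`, truncated toward
#' zero at two decimals (the convention of the standard worked examples,
#' where e.g. 3.058% is reported as 3.05%). Positive values mean the
#' second model beats the reference.
#'
#' @param mse_reference positive reference (e.g. the weaker model's MSE).
#' @param mse_better the comparison model's MSE.
#' @return percentage, truncated to 2 decimals.
#' @examples
#' percent_outperformance(0.5951, 0.5769) # 3.05
#' @export
percent_outperformance <- function(mse_reference, mse_better) {
  if (!is.numeric(mse_reference) || any(mse_reference <= 0)) {
    stop("'mse_reference' must be positive")
  }
  pct <- 100 * (mse_reference - mse_better) / mse_reference
  # round at a far finer precision first so that values which are exact
  # in decimal (e.g. 18.77) are not pushed below the truncation boundary
  # by floating point
  trunc(round(pct * 100, 6)) / 100
}
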