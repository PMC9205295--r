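#' Infer the response type
#'
#' Character, factor or logical responses with exactly two distinct
#' levels are binary, with more than two categorical; numeric responses
#' are continuous. Non-negative integer-valued numeric responses (counts)
#' are treated as continuous with a warning.
#'
#' @param y response vector, non-empty, no missing values.
#' @return an object of class `response_spec` with fields `type` and
#'   `levels`.
#' @export
infer_response_type <- function(y) {
  if (length(y) == 0) stop("empty response")
  if (anyNA(y)) stop("missing values in response")
  if (is.character(y) || is.factor(y) || is.logical(y)) {
    lv <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(as.character(y)))
    if (length(lv) < 2) stop("constant response")
    type <- if (length(lv) == 2) "binary" else "categorical"
    return(structure(list(type = type, levels = lv),
                     class = "response_spec"))
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("constant response")
  if (all(y >= 0) && all(y == round(y))) {
    warning("response looks like counts; fitting a continuous model")
  }
  structure(list(type = "continuous", levels = NULL),
            class = "response_spec")
}

#' Default hyperparameters per model
#'
#' The package-wide defaults of the six model families, in the
#' genomic-prediction naming convention (`trees_number`, `node_size`,
#' ...). The delegated back-ends receive these through an explicit
#' translation table (see [fit()]).
#'
#' @param model_name one of `"boosted_machine"`, `"linear_model"`,
#'   `"svm"`, `"random_forest"`, `"bayesian_brr"`, `"bayesian_gblup"`.
#' @return named list of defaults.
#' @export
model_defaults <- function(model_name) {
  switch(model_name,
    boosted_machine = list(trees_number = 500L, max_depth = 1L,
                           node_size = 10L, shrinkage = 0.1,
                           sampled_records_proportion = 0.5),
    linear_model = list(alpha = 1, lambda = NULL),
    svm = list(kernel = "linear", degree = 3L, gamma = NULL,
               coef0 = 0, cost = 1),
    random_forest = list(trees_number = 500L, node_size = 5L,
                         node_depth = NULL, sampled_x_vars_number = NULL),
    bayesian_brr = list(iterations = 1500L, burn_in = 500L),
    bayesian_gblup = list(iterations = 1500L, burn_in = 500L),
    stop("unknown model: '", model_name, "'")
  )
}

supported_models <- c("boosted_machine", "linear_model", "svm",
                      "random_forest", "bayesian_brr", "bayesian_gblup")

#' Fit a supervised model with a unified interface
#'
#' One entry point over the six model families: gradient boosted trees
#' (xgboost back-end), penalized generalized linear models (glmnet),
#' support vector machines (e1071), random forest (randomForest), and the
#' package's own Gibbs samplers [fit_brr()] and [fit_gblup()]. The
#' response type is inferred automatically, defaults follow
#' [model_defaults()], and a hyperparameter space plus [tune_config()]
#' triggers nested-CV tuning (grid search or Bayesian optimization) on
#' the training data before the final fit.
#'
#' Back-end translation (the tested surface): `trees_number` -> xgboost
#' `nrounds` / randomForest `ntree`; `node_size` -> `min_child_weight` /
#' `nodesize`; `shrinkage` -> `eta`; `sampled_records_proportion` ->
#' `subsample`; `sampled_x_vars_number` -> `mtry`; `node_depth` ->
#' `maxnodes = 2^node_depth`; `alpha`/`lambda`, `cost`/`gamma`/`degree`/
#' `coef0` keep their names. `gamma = NULL` resolves to `1/ncol(x)`;
#' `lambda = NULL` is selected by seeded internal 5-fold `cv.glmnet`.
#'
#' @param model_name one of the six model names.
#' @param x numeric design matrix (markers, kernel square root, sparse
#'   design `P`); for `"bayesian_gblup"`, a symmetric kernel over the
#'   training observations.
#' @param y response vector, length `nrow(x)`.
#' @param hyperparams named list of overrides of the defaults.
#' @param space optional hyperparameter space: named list of discrete
#'   value vectors (grid) or `c(lower, upper)` bounds (bayes).
#' @param tune a [tune_config()]; required with `space`.
#' @param seed integer seed (folds, stochastic back-ends).
#' @return an object of class `skm_fit` carrying the resolved
#'   hyperparameters, the `response_spec`, the back-end fit and, when
#'   tuned, the `tune_result`.
#' @export
fit <- function(model_name, x, y, hyperparams = list(), space = NULL,
                tune = NULL, seed = NULL) {
  model_name <- match.arg(model_name, supported_models)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  rspec <- infer_response_type(y)
  if (rspec$type != "continuous") {
    y <- factor(as.character(y), levels = rspec$levels)
    if (model_name %in% c("bayesian_brr", "bayesian_gblup")) {
      stop(model_name, " supports continuous responses only")
    }
  } else {
    y <- as.numeric(y)
  }
  params <- utils::modifyList(model_defaults(model_name), hyperparams,
                              keep.null = TRUE)

  tuned <- NULL
  if (!is.null(space)) {
    tune <- tune %||% tune_config("grid", seed = seed)
    loss_fn <- resolve_loss(tune$loss, rspec)
    fit_eval <- function(cand, train_idx, val_idx) {
      pars <- utils::modifyList(params, cand, keep.null = TRUE)
      backend <- fit_backend(model_name, x[train_idx, , drop = FALSE],
                             y[train_idx], pars, rspec, seed = tune$seed)
      m <- structure(list(model_name = model_name, params = pars,
                          response = rspec, backend = backend,
                          x_names = colnames(x)),
                     class = "skm_fit")
      pred <- stats::predict(m, x[val_idx, , drop = FALSE])
      loss_fn(y[val_idx], pred)
    }
    if (tune$strategy == "grid") {
      lapply(space, function(v) {
        if (length(v) < 2) {
          stop("grid search needs at least two candidate values for ",
               "at least one hyperparameter")
        }
      })
      tuned <- grid_search(fit_eval, space, n = nrow(x), config = tune)
    } else {
      int_pars <- names(space)[vapply(space, function(b) {
        all(b == round(b))
      }, logical(1))]
      folds <- make_kfolds(nrow(x), tune$inner_folds, tune$seed)
      objective <- function(pars) {
        ls <- vapply(seq_along(folds), function(f) {
          val <- folds[[f]]
          fit_eval(pars, setdiff(seq_len(nrow(x)), val), val)
        }, numeric(1))
        mean(ls)
      }
      tuned <- bayes_opt(objective, space, config = tune,
                         integer_params = int_pars)
    }
    params <- utils::modifyList(params, tuned$best, keep.null = TRUE)
  }

  backend <- fit_backend(model_name, x, y, params, rspec, seed = seed)
  structure(list(model_name = model_name, params = params,
                 response = rspec, backend = backend,
                 x_names = colnames(x), n_train = nrow(x),
                 y_train_mean = if (rspec$type == "continuous") mean(y) else NULL,
                 tune_result = tuned),
            class = "skm_fit")
}

resolve_loss <- function(loss, rspec) {
  loss <- loss %||% if (rspec$type == "continuous") "mse" else "log_loss"
  switch(loss,
    mse = function(obs, pred) mse(obs, pred_values(pred)),
    log_loss = function(obs, pred) {
      P <- pred$probabilities
      eps <- 1e-12
      -mean(log(pmax(P[cbind(seq_along(obs), match(as.character(obs),
                                                   colnames(P)))], eps)))
    },
    accuracy = function(obs, pred) {
      1 - accuracy(as.character(obs), as.character(pred$class))
    },
    stop("unknown tuning loss: ", loss)
  )
}

pred_values <- function(pred) if (is.list(pred)) pred$class else pred

# glmnet needs >= 2 columns; pad degenerate designs with a zero column,
# which gets a zero coefficient and leaves predictions unchanged.
pad_x <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

fit_backend <- function(model_name, x, y, params, rspec, seed = NULL) {
  classification <- rspec$type != "continuous"
  switch(model_name,
    random_forest = with_seed(seed, {
      args <- list(x = x, y = y,
                   ntree = params$trees_number,
                   nodesize = params$node_size)
      if (!is.null(params$sampled_x_vars_number)) {
        args$mtry <- params$sampled_x_vars_number
      }
      if (!is.null(params$node_depth)) {
        args$maxnodes <- 2^params$node_depth
      }
      do.call(randomForest::randomForest, args)
    }),
    svm = {
      gamma <- params$gamma %||% (1 / ncol(x))
      e1071::svm(x = x, y = y, kernel = params$kernel,
                 degree = params$degree, gamma = gamma,
                 coef0 = params$coef0, cost = params$cost,
                 probability = classification)
    },
    linear_model = with_seed(seed, {
      xp <- pad_x(x)
      if (all(apply(xp, 2, stats::sd) < 1e-12)) {
        # no informative predictor at all: intercept-only behavior
        if (classification) {
          tab <- table(y) / length(y)
          return(list(intercept_only = TRUE, class_probs = tab))
        }
        return(list(intercept_only = TRUE, mu = mean(y)))
      }
      family <- switch(rspec$type, continuous = "gaussian",
                       binary = "binomial", categorical = "multinomial")
      if (is.null(params$lambda)) {
        foldid <- integer(nrow(xp))
        folds <- make_kfolds(nrow(xp), min(5L, nrow(xp)), seed)
        for (f in seq_along(folds)) foldid[folds[[f]]] <- f
        cv <- glmnet::cv.glmnet(xp, y, alpha = params$alpha,
                                family = family, foldid = foldid)
        list(fit = cv$glmnet.fit, lambda = cv$lambda.min, family = family)
      } else {
        m <- glmnet::glmnet(xp, y, alpha = params$alpha, family = family,
                            lambda = params$lambda)
        list(fit = m, lambda = params$lambda, family = family)
      }
    }),
    boosted_machine = with_seed(seed, {
      xgboost::xgboost(x = x, y = y,
                       nrounds = params$trees_number,
                       max_depth = params$max_depth,
                       learning_rate = params$shrinkage,
                       min_child_weight = params$node_size,
                       subsample = params$sampled_records_proportion,
                       nthreads = 1, verbosity = 0,
                       seed = (seed %||% 0L))
    }),
    bayesian_brr = fit_brr(x, y, iterations = params$iterations,
                           burn_in = params$burn_in, seed = seed),
    bayesian_gblup = fit_gblup(x, y, iterations = params$iterations,
                               burn_in = params$burn_in, seed = seed)
  )
}

#' Predict from a unified fit
#'
#' Continuous models return a numeric vector. Classification models
#' return a list with `$class` (labels) and `$probabilities` (row-
#' normalized matrix, one column per class). An empty `x_new` yields an
#' empty prediction set.
#'
#' @param object an [fit()] result.
#' @param x_new design matrix, column-compatible with training (for
#'   `"bayesian_gblup"`, the cross-kernel rows of new observations
#'   against the training observations).
#' @param ... unused.
#' @export
predict.skm_fit <- function(object, x_new, ...) {
  x_new <- as.matrix(x_new)
  classification <- object$response$type != "continuous"
  if (nrow(x_new) == 0) {
    if (classification) {
      return(list(class = character(0),
                  probabilities = matrix(numeric(0), 0,
                                         length(object$response$levels),
                                         dimnames = list(NULL, object$response$levels))))
    }
    return(numeric(0))
  }
  if (!is.null(object$x_names) && !is.null(colnames(x_new)) &&
      object$model_name != "bayesian_gblup") {
    missing_cols <- setdiff(object$x_names, colnames(x_new))
    if (length(missing_cols) > 0) {
      stop("columns missing from x_new: ",
           paste(utils::head(missing_cols, 5), collapse = ", "))
    }
    x_new <- x_new[, object$x_names, drop = FALSE]
  }
  b <- object$backend
  lv <- object$response$levels
  out <- switch(object$model_name,
    random_forest = {
      if (classification) {
        P <- stats::predict(b, x_new, type = "prob")[, lv, drop = FALSE]
        list(class = as.character(stats::predict(b, x_new)),
             probabilities = P)
      } else {
        as.numeric(stats::predict(b, x_new))
      }
    },
    svm = {
      pr <- stats::predict(b, x_new, probability = classification)
      if (classification) {
        P <- attr(pr, "probabilities")[, lv, drop = FALSE]
        list(class = as.character(pr), probabilities = P)
      } else {
        as.numeric(pr)
      }
    },
    linear_model = {
      xp <- pad_x(x_new)
      if (isTRUE(b$intercept_only)) {
        if (classification) {
          P <- matrix(rep(as.numeric(b$class_probs), each = nrow(xp)),
                      nrow(xp), dimnames = list(NULL, names(b$class_probs)))
          return(list(class = rep(names(which.max(b$class_probs)),
                                  nrow(xp)),
                      probabilities = P))
        }
        return(rep(b$mu, nrow(xp)))
      }
      if (object$response$type == "continuous") {
        as.numeric(stats::predict(b$fit, xp, s = b$lambda))
      } else if (object$response$type == "binary") {
        p2 <- as.numeric(stats::predict(b$fit, xp, s = b$lambda,
                                        type = "response"))
        P <- cbind(1 - p2, p2)
        colnames(P) <- lv
        list(class = lv[(p2 > 0.5) + 1L], probabilities = P)
      } else {
        P <- stats::predict(b$fit, xp, s = b$lambda, type = "response")[, , 1]
        P <- P[, lv, drop = FALSE]
        list(class = lv[max.col(P, ties.method = "first")],
             probabilities = P)
      }
    },
    boosted_machine = {
      pr <- stats::predict(b, x_new)
      if (object$response$type == "binary") {
        # the returned probability refers to the second factor level
        P <- cbind(1 - pr, pr)
        colnames(P) <- lv
        list(class = lv[(pr > 0.5) + 1L], probabilities = P)
      } else if (object$response$type == "categorical") {
        P <- pr[, lv, drop = FALSE]
        list(class = lv[max.col(P, ties.method = "first")],
             probabilities = P)
      } else {
        as.numeric(pr)
      }
    },
    bayesian_brr = stats::predict(b, x_new),
    bayesian_gblup = stats::predict(b, K_new = x_new)
  )
  out
}
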