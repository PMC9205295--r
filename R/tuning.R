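#' Tuning configuration
#'
#' Controls hyperparameter selection under inner k-fold cross-validation.
#' Grid search exhaustively evaluates the Cartesian product of discrete
#' candidate values; Bayesian optimization evaluates `initial_points`
#' space-filling points and then `bayes_iterations` rounds of
#' Gaussian-process-guided search (10 by default).
#'
#' @param strategy `"grid"` or `"bayes"`.
#' @param inner_folds inner cross-validation folds (default 5).
#' @param bayes_iterations Bayesian-optimization rounds after the initial
#'   design (default 10).
#' @param initial_points initial space-filling evaluations (default 5).
#' @param seed integer seed for folds and proposals.
#' @param loss loss name: `"mse"` (continuous, default) or `"log_loss"` /
#'   `"accuracy"` for classification.
#' @return an object of class `tune_config`.
#' @export
tune_config <- function(strategy = c("grid", "bayes"), inner_folds = 5L,
                        bayes_iterations = 10L, initial_points = 5L,
                        seed = NULL, loss = NULL) {
  strategy <- match.arg(strategy)
  inner_folds <- as.integer(inner_folds)
  if (inner_folds < 2) stop("'inner_folds' must be >= 2")
  bayes_iterations <- as.integer(bayes_iterations)
  if (bayes_iterations < 1) stop("'bayes_iterations' must be >= 1")
  structure(list(strategy = strategy, inner_folds = inner_folds,
                 bayes_iterations = bayes_iterations,
                 initial_points = as.integer(initial_points),
                 seed = seed, loss = loss),
            class = "tune_config")
}

#' Seeded k-fold assignment
#'
#' Partitions `1:n` into k folds of sizes differing by at most one, after
#' a seeded shuffle.
#'
#' @param n number of cases.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed.
#' @return a list of k disjoint index vectors covering `1:n`.
#' @export
make_kfolds <- function(n, k, seed = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2) stop("'k' must be >= 2")
  if (k > n) stop("'k' cannot exceed n")
  perm <- with_seed(seed, sample.int(n))
  unname(split(perm, rep(seq_len(k), length.out = n)))
}

#' Seeded random train/test partitions
#'
#' Generates `reps` independent splits with `round(testing_proportion*n)`
#' test cases each (the outer loop of the benchmarking protocol; 5
#' repetitions of an 80/20 split by default). With `strata`, the test
#' cases are drawn per stratum (e.g. per environment) so every stratum is
#' represented in every test set.
#'
#' @param n number of cases.
#' @param testing_proportion fraction in (0, 1) held out per repetition.
#' @param reps number of random partitions.
#' @param seed integer seed.
#' @param strata optional length-n factor for stratified splits.
#' @return a list of `reps` lists with disjoint, exhaustive `$train` and
#'   `$test` index vectors.
#' @export
make_random_partitions <- function(n, testing_proportion = 0.2, reps = 5L,
                                   seed = NULL, strata = NULL) {
  if (testing_proportion <= 0 || testing_proportion >= 1) {
    stop("'testing_proportion' must be in (0, 1)")
  }
  n <- as.integer(n)
  if (!is.null(strata) && length(strata) != n) {
    stop("'strata' must have length n")
  }
  with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      if (is.null(strata)) {
        test <- sort(sample.int(n, round(testing_proportion * n)))
      } else {
        idx_by <- split(seq_len(n), strata)
        test <- sort(unlist(lapply(idx_by, function(ix) {
          size <- max(1L, round(testing_proportion * length(ix)))
          sample(ix, size)
        }), use.names = FALSE))
      }
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}

#' Exhaustive grid search under inner cross-validation
#'
#' Evaluates every combination of the discrete hyperparameter grid: for
#' each combination, `fit_eval` is called once per inner fold with the
#' training and validation index sets, and the mean validation loss over
#' folds is recorded. The selected combination minimizes the mean loss;
#' exact ties go to the first combination in enumeration order.
#'
#' @param fit_eval `function(params, train_idx, val_idx) -> loss`, where
#'   `params` is a named list (one value per hyperparameter).
#' @param space named list of candidate-value vectors.
#' @param n number of training cases to fold.
#' @param config a [tune_config()].
#' @return an object of class `tune_result`: `$trace` (one row per
#'   combination with `loss` and `loss_sd`), `$best` (named list) and
#'   `$best_loss`.
#' @export
grid_search <- function(fit_eval, space, n, config = tune_config("grid")) {
  if (length(space) == 0 || any(lengths(space) == 0)) {
    stop("empty hyperparameter space")
  }
  combos <- expand.grid(space, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  folds <- make_kfolds(n, config$inner_folds, config$seed)
  losses <- matrix(NA_real_, nrow(combos), length(folds))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      train <- setdiff(seq_len(n), val)
      losses[i, f] <- fit_eval(params, train, val)
    }
  }
  trace <- cbind(combos,
                 loss = rowMeans(losses),
                 loss_sd = apply(losses, 1, stats::sd))
  best_i <- which.min(trace$loss)
  structure(list(trace = trace,
                 best = as.list(combos[best_i, , drop = FALSE]),
                 best_loss = trace$loss[best_i]),
            class = "tune_result")
}

#' Bayesian optimization of a bounded objective
#'
#' Minimizes a black-box loss over a box-bounded numeric space: evaluates
#' a seeded Latin-hypercube initial design, then repeatedly fits a
#' Gaussian-process surrogate (Matern-5/2 correlation, profiled variance,
#' lengthscale chosen by marginal likelihood) and evaluates the point
#' maximizing expected improvement over a large candidate set. Integer
#' dimensions are optimized on the continuous relaxation and rounded at
#' evaluation time.
#'
#' @param objective `function(params) -> loss`, `params` a named list.
#' @param bounds named list of `c(lower, upper)` pairs.
#' @param config a [tune_config()] (uses `initial_points`,
#'   `bayes_iterations`, `seed`).
#' @param integer_params names of dimensions rounded to integers.
#' @return an object of class `tune_result` with the full evaluation
#'   trace in evaluation order.
#' @export
bayes_opt <- function(objective, bounds, config = tune_config("bayes"),
                      integer_params = character(0)) {
  d <- length(bounds)
  if (d == 0) stop("empty hyperparameter space")
  nm <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("each bound must satisfy lower < upper")

  to_params <- function(u) {
    x <- lo + u * (hi - lo)
    p <- as.list(x)
    names(p) <- nm
    for (ip in integer_params) p[[ip]] <- round(p[[ip]])
    p
  }
  eval_point <- function(u) {
    p <- to_params(u)
    val <- objective(p)
    if (!is.finite(val)) {
      stop("non-finite objective value at combination: ",
           paste(sprintf("%s = %g", nm, unlist(p)), collapse = ", "))
    }
    val
  }

  with_seed(config$seed, {
    n0 <- max(config$initial_points, 2L)
    U <- lhs::randomLHS(n0, d)
    y <- apply(U, 1, eval_point)
    for (iter in seq_len(config$bayes_iterations)) {
      jitter <- matrix(rep(U[which.min(y), ], each = 20) +
                         stats::rnorm(20 * d, sd = 0.05), ncol = d)
      cand <- rbind(lhs::randomLHS(500 * d, d),
                    pmin(pmax(jitter, 0), 1))
      u_next <- gp_ei_argmax(U, y, cand)
      y <- c(y, eval_point(u_next))
      U <- rbind(U, u_next)
    }
    trace <- as.data.frame(sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+"))
    names(trace) <- nm
    for (ip in integer_params) trace[[ip]] <- round(trace[[ip]])
    trace$loss <- y
    best_i <- which.min(y)
    structure(list(trace = trace,
                   best = to_params(U[best_i, ]),
                   best_loss = y[best_i]),
              class = "tune_result")
  })
}

# Matern-5/2 correlation matrix between unit-cube point sets.
matern52 <- function(A, B, ls) {
  r <- sqrt(pmax(pairwise_sqdist(
    as_marker_matrix(A, min_rows = 1L),
    as_marker_matrix(B, min_rows = 1L)), 0)) / ls
  (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

# Fit a zero-mean GP on standardized losses (lengthscale by profiled
# marginal likelihood over a grid) and return the candidate maximizing
# expected improvement.
gp_ei_argmax <- function(U, y, cand) {
  n <- length(y)
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) {
    # constant objective so far: pure exploration
    return(cand[sample.int(nrow(cand), 1), ])
  }
  ys <- (y - mu_y) / sd_y
  nugget <- 1e-6
  best <- NULL
  for (ls in c(0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2)) {
    C <- matern52(U, U, ls) + diag(nugget, n)
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) next
    alpha <- backsolve(R, backsolve(R, ys, transpose = TRUE))
    s2 <- sum(ys * alpha) / n
    ll <- -0.5 * n * log(max(s2, 1e-12)) - sum(log(diag(R)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ls = ls, R = R, alpha = alpha, s2 = s2)
    }
  }
  if (is.null(best)) return(cand[sample.int(nrow(cand), 1), ])
  Kc <- matern52(cand, U, best$ls)
  mu_c <- Kc %*% best$alpha
  Vh <- backsolve(best$R, t(Kc), transpose = TRUE)
  var_c <- pmax(best$s2 * (1 + nugget - colSums(Vh^2)), 1e-12)
  sd_c <- sqrt(var_c)
  y_best <- min(ys)
  imp <- y_best - mu_c
  z <- imp / sd_c
  ei <- imp * stats::pnorm(z) + sd_c * stats::dnorm(z)
  cand[which.max(ei), ]
}
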