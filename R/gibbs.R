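#' Bayesian ridge regression by Gibbs sampling
#'
#' Fits `y = mu 1 + X beta + e` with `beta ~ N(0, sigma2_b I)` and
#' conjugate scaled-inverse-chi-square priors on both variance components
#' (`df_prior` degrees of freedom; scales chosen so that markers and
#' residual each explain `r2` resp. `1 - r2` of `var(y)` a priori, the
#' usual genomic-prediction convention).
#'
#' The sampler is exact but runs in the singular-value basis of `X`:
#' with `X = U D V'` of rank r, the r coordinates `a = V' beta` have a
#' diagonal conditional posterior and are drawn jointly in O(r) per
#' iteration; the null-space contribution to `beta' beta` (needed by the
#' `sigma2_b` update when p > r) is drawn as `sigma2_b * chi2(p - r)`
#' without forming the null-space basis. This makes dense-marker problems
#' (p in the thousands) tractable in plain R.
#'
#' @param X numeric design matrix (N x p), e.g. centered/scaled markers, a
#'   kernel square root, or a sparse design `P`.
#' @param y numeric response.
#' @param iterations,burn_in,thin MCMC controls; retained draws are
#'   `(iterations - burn_in) / thin`.
#' @param seed integer seed for exact chain replay; `NULL` uses the
#'   current RNG stream.
#' @param df_prior,r2 prior degrees of freedom and a-priori proportion of
#'   variance attributed to the markers.
#' @return an object of class `c("brr_fit", "mixed_model_fit")`: posterior
#'   means `mu`, `effects` (p marker effects), `sigma2_b`, `sigma2_e`,
#'   plus the retained variance-component draws in `$samples`.
#' @export
fit_brr <- function(X, y, iterations = 1500L, burn_in = 500L, thin = 1L,
                    seed = NULL, df_prior = 5, r2 = 0.5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- length(y)
  if (nrow(X) != N) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (iterations <= burn_in) stop("'iterations' must exceed 'burn_in'")
  p <- ncol(X)

  sv <- svd(X)
  dtol <- max(sv$d) * 1e-10
  r <- sum(sv$d > dtol)
  if (r == 0) {
    # no signal columns at all: intercept-only posterior
    sv$u <- matrix(0, N, 1); sv$d <- 0; sv$v <- matrix(0, p, 1); r <- 0
  }
  U <- sv$u[, seq_len(max(r, 1)), drop = FALSE]
  d <- sv$d[seq_len(max(r, 1))]
  V <- sv$v[, seq_len(max(r, 1)), drop = FALSE]

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  msx <- sum(apply(X, 2, stats::var))
  if (!is.finite(msx) || msx <= 0) msx <- 1
  S_e <- vy * (1 - r2) * (df_prior + 2) / df_prior
  S_b <- vy * r2 * (df_prior + 2) / df_prior / msx

  n_keep <- floor((iterations - burn_in) / thin)
  out <- with_seed(seed, {
    mu <- mean(y)
    sigma2_e <- vy * (1 - r2)
    sigma2_b <- vy * r2 / msx
    a <- rep(0, max(r, 1))
    a_sum <- rep(0, max(r, 1))
    mu_sum <- 0
    chain <- matrix(NA_real_, n_keep, 3,
                    dimnames = list(NULL, c("mu", "sigma2_b", "sigma2_e")))
    kept <- 0L
    for (it in seq_len(iterations)) {
      if (r > 0) {
        k <- sigma2_e / sigma2_b
        Uty <- crossprod(U, y - mu)[, 1]
        prec <- d^2 + k
        a <- stats::rnorm(r, mean = d * Uty / prec,
                          sd = sqrt(sigma2_e / prec))
        g <- U %*% (d * a)
      } else {
        g <- matrix(0, N, 1)
      }
      mu <- stats::rnorm(1, mean(y - g), sqrt(sigma2_e / N))
      ss_b <- sum(a^2)
      if (p > r) ss_b <- ss_b + sigma2_b * stats::rchisq(1, p - r)
      sigma2_b <- (ss_b + df_prior * S_b) / stats::rchisq(1, p + df_prior)
      resid <- y - mu - g
      sigma2_e <- (sum(resid^2) + df_prior * S_e) /
        stats::rchisq(1, N + df_prior)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        kept <- kept + 1L
        a_sum <- a_sum + a
        mu_sum <- mu_sum + mu
        chain[kept, ] <- c(mu, sigma2_b, sigma2_e)
      }
    }
    list(a_bar = a_sum / kept, mu_bar = mu_sum / kept,
         chain = as.data.frame(chain))
  })

  beta <- if (r > 0) as.numeric(V %*% out$a_bar) else rep(0, p)
  names(beta) <- colnames(X)
  structure(list(mu = out$mu_bar, effects = beta,
                 sigma2_b = mean(out$chain$sigma2_b),
                 sigma2_e = mean(out$chain$sigma2_e),
                 samples = out$chain,
                 iterations = iterations, burn_in = burn_in, thin = thin),
            class = c("brr_fit", "mixed_model_fit"))
}

#' @export
predict.brr_fit <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0) return(numeric(0))
  if (ncol(X_new) != length(object$effects)) {
    stop("X_new has ", ncol(X_new), " columns; the model was trained on ",
         length(object$effects))
  }
  as.numeric(object$mu + X_new %*% object$effects)
}

#' Bayesian GBLUP by Gibbs sampling
#'
#' Fits the kernel mixed model `y = mu 1 + Z u + e` with line effects
#' `u ~ N(0, sigma2_u K)` and independent residuals, via the
#' eigen-reparameterization `u = Gamma delta` where `K = Gamma Lambda
#' Gamma'` (spectrum clamped at `tol * lambda_max`) and the `delta_j` are
#' independent a priori. When the incidence is balanced (`Z'Z`
#' proportional to the identity — e.g. every line phenotyped once, or once
#' per environment) the conditional posterior of `delta` is diagonal and
#' each sweep costs O(n); otherwise a joint draw via Cholesky of the r x r
#' precision is used. Priors as in [fit_brr()].
#'
#' @param K symmetric kernel matrix over n lines (line-id dimnames).
#' @param y numeric response of length N.
#' @param Z observation-to-line mapping: an N x n incidence matrix, a
#'   character/factor vector of line ids, or `NULL` for the identity
#'   (requires N = n).
#' @param iterations,burn_in,thin,seed,df_prior,r2 as in [fit_brr()].
#' @param tol relative eigenvalue clamping threshold for `K`.
#' @return an object of class `c("gblup_fit", "mixed_model_fit")`:
#'   posterior means `mu`, `effects` (n line effects, named), `sigma2_u`,
#'   `sigma2_e`, posterior-mean heritability `h2`, and variance-component
#'   draws in `$samples`. Predictions for an observation are `mu +
#'   u[line]`; for lines outside `K` supply a cross-kernel to
#'   [predict.gblup_fit()].
#' @export
fit_gblup <- function(K, y, Z = NULL, iterations = 1500L, burn_in = 500L,
                      thin = 1L, seed = NULL, df_prior = 5, r2 = 0.5,
                      tol = 1e-10) {
  K <- check_symmetric(K)
  n <- nrow(K)
  ids <- rownames(K) %||% paste0("L", seq_len(n))
  y <- as.numeric(y)
  N <- length(y)
  if (is.null(Z)) {
    if (N != n) stop("length(y) must equal nrow(K) when Z is NULL")
    Zm <- NULL # identity
  } else if (is.character(Z) || is.factor(Z)) {
    Zm <- line_incidence(as.character(Z), ids)
  } else {
    Zm <- as.matrix(Z)
    if (ncol(Zm) != n) stop("Z column count must equal nrow(K)")
    if (nrow(Zm) != N) stop("nrow(Z) must equal length(y)")
  }
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (iterations <= burn_in) stop("'iterations' must exceed 'burn_in'")

  eg <- eigen(K, symmetric = TRUE)
  lam_max <- max(eg$values, 0)
  if (lam_max <= 0) stop("kernel has no positive eigenvalue")
  keep <- eg$values > tol * lam_max
  Gam <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  r <- length(lam)

  W <- if (is.null(Zm)) Gam else Zm %*% Gam
  WtW <- crossprod(W)
  off <- WtW - diag(diag(WtW), r)
  diagonal_path <- max(abs(off)) < 1e-8 * max(diag(WtW))
  wdiag <- diag(WtW)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  mean_diag_k <- mean(diag(K))
  if (mean_diag_k <= 0) mean_diag_k <- 1
  S_e <- vy * (1 - r2) * (df_prior + 2) / df_prior
  S_u <- vy * r2 * (df_prior + 2) / df_prior / mean_diag_k

  n_keep <- floor((iterations - burn_in) / thin)
  out <- with_seed(seed, {
    mu <- mean(y)
    sigma2_e <- vy * (1 - r2)
    sigma2_u <- vy * r2 / mean_diag_k
    delta_sum <- rep(0, r)
    mu_sum <- 0
    h2_sum <- 0
    chain <- matrix(NA_real_, n_keep, 3,
                    dimnames = list(NULL, c("mu", "sigma2_u", "sigma2_e")))
    kept <- 0L
    delta <- rep(0, r)
    for (it in seq_len(iterations)) {
      Wty <- crossprod(W, y - mu)[, 1]
      if (diagonal_path) {
        prec <- wdiag / sigma2_e + 1 / (sigma2_u * lam)
        delta <- stats::rnorm(r, mean = (Wty / sigma2_e) / prec,
                              sd = sqrt(1 / prec))
      } else {
        M <- WtW / sigma2_e + diag(1 / (sigma2_u * lam), r)
        R <- chol(M)
        mean_d <- backsolve(R, backsolve(R, Wty / sigma2_e,
                                         transpose = TRUE))
        delta <- mean_d + backsolve(R, stats::rnorm(r))
      }
      fitted <- W %*% delta
      mu <- stats::rnorm(1, mean(y - fitted), sqrt(sigma2_e / N))
      sigma2_u <- (sum(delta^2 / lam) + df_prior * S_u) /
        stats::rchisq(1, r + df_prior)
      resid <- y - mu - fitted
      sigma2_e <- (sum(resid^2) + df_prior * S_e) /
        stats::rchisq(1, N + df_prior)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        kept <- kept + 1L
        delta_sum <- delta_sum + delta
        mu_sum <- mu_sum + mu
        # genetic variance at the observation level is sigma2_u * K_ii,
        # so heritability must account for the kernel's diagonal scale
        h2_sum <- h2_sum + sigma2_u * mean_diag_k /
          (sigma2_u * mean_diag_k + sigma2_e)
        chain[kept, ] <- c(mu, sigma2_u, sigma2_e)
      }
    }
    list(delta_bar = delta_sum / kept, mu_bar = mu_sum / kept,
         h2 = h2_sum / kept, chain = as.data.frame(chain))
  })

  u <- as.numeric(Gam %*% out$delta_bar)
  names(u) <- ids
  # alpha = K^+ u: enables prediction for new lines via a cross-kernel
  alpha <- as.numeric(Gam %*% (out$delta_bar / lam))
  structure(list(mu = out$mu_bar, effects = u,
                 sigma2_u = mean(out$chain$sigma2_u),
                 sigma2_e = mean(out$chain$sigma2_e),
                 h2 = out$h2, alpha = alpha, line_ids = ids,
                 samples = out$chain,
                 iterations = iterations, burn_in = burn_in, thin = thin),
            class = c("gblup_fit", "mixed_model_fit"))
}

#' Predict from a fitted GBLUP model
#'
#' @param object a [fit_gblup()] result.
#' @param line_ids character vector of line ids present in the training
#'   kernel; predictions are `mu + u[line]`.
#' @param K_new cross-kernel (new lines x training lines, columns in
#'   training-kernel order) for lines not in the training kernel;
#'   predictions are `mu + K_new %*% K^+ u`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.gblup_fit <- function(object, line_ids = NULL, K_new = NULL, ...) {
  if (!is.null(K_new)) {
    K_new <- as.matrix(K_new)
    if (nrow(K_new) == 0) return(numeric(0))
    if (ncol(K_new) != length(object$alpha)) {
      stop("K_new must have one column per training line (",
           length(object$alpha), ")")
    }
    return(as.numeric(object$mu + K_new %*% object$alpha))
  }
  if (is.null(line_ids)) return(object$mu + object$effects)
  line_ids <- as.character(line_ids)
  if (length(line_ids) == 0) return(numeric(0))
  unknown <- setdiff(unique(line_ids), object$line_ids)
  if (length(unknown) > 0) {
    stop("lines absent from the training kernel: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         "; supply K_new for new lines")
  }
  as.numeric(object$mu + object$effects[line_ids])
}
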