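#' Simulation configuration
#'
#' Study conditions for the synthetic genomic data: biallelic SNP dosages
#' under Hardy-Weinberg sampling (no linkage disequilibrium), additive
#' (optionally epistatic) genetic effects with a target heritability, and
#' replication of every line across environments with environment main
#' effects only (no genotype-by-environment interaction). Defaults
#' emulate, at desk scale, multi-environment cereal trials: a few hundred
#' lines, several hundred markers, four environments.
#'
#' The genetic variance is `sigma2_u = h2` and the residual variance
#' `sigma2_e = sigma2_u (1 - h2) / h2 = 1 - h2`, so line-level phenotypic
#' variance within an environment is 1 and `h2 = sigma2_u / (sigma2_u +
#' sigma2_e)` holds by construction.
#'
#' @param n_lines number of lines (default 200).
#' @param p_markers number of SNP markers (default 500).
#' @param maf_range minor-allele-frequency range, within (0, 0.5]
#'   (default `c(0.05, 0.5)` — markers below 5% MAF are typically
#'   filtered out of real panels).
#' @param h2 target narrow-sense heritability in `[0, 1]` (default 0.5).
#' @param n_env number of environments (default 4).
#' @param env_effect_sd standard deviation of environment main effects
#'   (default 0.5).
#' @param architecture `"additive"` or `"epistatic"` (adds pairwise
#'   products of a random 1% marker subset).
#' @param mu overall mean (default 0; traits are treated as standardized).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200L, p_markers = 500L,
                       maf_range = c(0.05, 0.5), h2 = 0.5, n_env = 4L,
                       env_effect_sd = 0.5,
                       architecture = c("additive", "epistatic"),
                       mu = 0, seed = NULL) {
  architecture <- match.arg(architecture)
  if (h2 < 0 || h2 > 1) stop("'h2' must be in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("'maf_range' must be within (0, 0.5]")
  }
  if (env_effect_sd < 0) stop("'env_effect_sd' must be >= 0")
  structure(list(n_lines = as.integer(n_lines),
                 p_markers = as.integer(p_markers),
                 maf_range = maf_range, h2 = h2,
                 n_env = as.integer(n_env),
                 env_effect_sd = env_effect_sd,
                 architecture = architecture, mu = mu, seed = seed),
            class = "sim_config")
}

#' Simulate a marker dosage matrix
#'
#' Each marker j draws an allele frequency `q_j ~ Uniform(maf_range)` and
#' dosages `Binomial(2, q_j)` independently per line (Hardy-Weinberg, no
#' LD). Monomorphic columns are resampled so every marker is informative.
#'
#' @param cfg a [sim_config()].
#' @return an `n_lines x p_markers` matrix of 0/1/2 dosages with line ids
#'   `L001, ...` and attribute `allele_freq`.
#' @export
simulate_markers <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_lines
    p <- cfg$p_markers
    q <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
    X <- vapply(seq_len(p), function(j) {
      stats::rbinom(n, 2, q[j])
    }, numeric(n))
    for (j in seq_len(p)) {
      while (length(unique(X[, j])) < 2) {
        q[j] <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
        X[, j] <- stats::rbinom(n, 2, q[j])
      }
    }
    rownames(X) <- sprintf("L%03d", seq_len(n))
    colnames(X) <- sprintf("M%04d", seq_len(p))
    attr(X, "allele_freq") <- q
    X
  })
}

#' Simulate multi-environment phenotypes with known architecture
#'
#' Genetic values are `g = X_scaled beta` with `beta ~ N(0, 1/p)`
#' (epistatic architecture adds pairwise products of a random 1% marker
#' subset), rescaled to variance `sigma2_u = h2`. Records are `y =
#' mu + env_effect + g + e` with `e ~ N(0, sigma2_e)` per line-by-
#' environment record and `env_effect ~ N(0, env_effect_sd^2)` per
#' environment: one record per line and environment.
#'
#' @param X marker matrix from [simulate_markers()].
#' @param cfg a [sim_config()].
#' @return a list of class `sim_data`: `$pheno` (data frame `Line`,
#'   `Env`, `y`), `$truth` (list with `beta`, `g`, `env_effects`,
#'   `sigma2_u`, `sigma2_e`, `h2`, `mu`).
#' @export
simulate_phenotypes <- function(X, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  X <- as_marker_matrix(X)
  n <- nrow(X)
  Xs <- center_scale(X)
  p <- ncol(Xs)
  seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1L
  with_seed(seed, {
    beta <- stats::rnorm(p, 0, sqrt(1 / p))
    g <- as.numeric(Xs %*% beta)
    if (cfg$architecture == "epistatic") {
      sub <- sample.int(p, max(2L, ceiling(0.01 * p)))
      pairs <- utils::combn(sub, 2)
      W <- Xs[, pairs[1, ], drop = FALSE] * Xs[, pairs[2, ], drop = FALSE]
      g <- g + as.numeric(W %*% stats::rnorm(ncol(W), 0,
                                             sqrt(1 / ncol(W))))
    }
    sigma2_u <- cfg$h2
    sigma2_e <- 1 - cfg$h2
    if (cfg$h2 == 0) {
      g <- rep(0, n)
    } else {
      g <- g * sqrt(sigma2_u / stats::var(g))
    }
    env_ids <- sprintf("E%d", seq_len(cfg$n_env))
    env_eff <- stats::rnorm(cfg$n_env, 0, cfg$env_effect_sd)
    names(env_eff) <- env_ids
    pheno <- expand.grid(Line = rownames(X), Env = env_ids,
                         stringsAsFactors = FALSE)
    e <- stats::rnorm(nrow(pheno), 0, sqrt(sigma2_e))
    pheno$y <- cfg$mu + env_eff[pheno$Env] +
      g[match(pheno$Line, rownames(X))] + e
    rownames(pheno) <- NULL
    structure(list(pheno = pheno,
                   truth = list(beta = beta, g = stats::setNames(g, rownames(X)),
                                env_effects = env_eff,
                                sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                                h2 = cfg$h2, mu = cfg$mu)),
              class = "sim_data")
  })
}

#' Simulate a complete dataset (markers + phenotypes)
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_data` with `$markers`, `$pheno`,
#'   `$truth`.
#' @export
simulate_dataset <- function(cfg) {
  X <- simulate_markers(cfg)
  sim <- simulate_phenotypes(X, cfg)
  structure(list(markers = X, pheno = sim$pheno, truth = sim$truth),
            class = "sim_data")
}
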