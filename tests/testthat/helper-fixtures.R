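# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite is self-contained.

# Small seeded marker-like matrix with line ids.
toy_markers <- function(n = 8, p = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("L%02d", seq_len(n)),
                                sprintf("M%02d", seq_len(p))))
    X
  })
}

# Seeded dosage matrix (0/1/2) via the package generator.
toy_dosages <- function(n = 10, p = 6, seed = 1) {
  simulate_markers(sim_config(n_lines = n, p_markers = p, seed = seed))
}

# Random symmetric PSD matrix with unit-ish scale.
random_psd <- function(n = 5, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n), n, n)
    K <- crossprod(A) / n
    dimnames(K) <- list(paste0("L", 1:n), paste0("L", 1:n))
    K
  })
}

all_kernel_configs <- function() {
  list(linear = kernel_config("linear"),
       polynomial = kernel_config("polynomial"),
       sigmoid = kernel_config("sigmoid"),
       gaussian = kernel_config("gaussian"),
       exponential = kernel_config("exponential"),
       arc_cosine1 = kernel_config("arc_cosine", arc_depth = 1),
       arc_cosine2 = kernel_config("arc_cosine", arc_depth = 2))
}

# Independent scalar-loop arc-cosine oracle (depth L) for two rows.
arc_oracle_pair <- function(x, z, depth) {
  kxx <- sum(x^2); kzz <- sum(z^2); kxz <- sum(x * z)
  for (l in seq_len(depth)) {
    step1 <- function(kaa, kbb, kab) {
      nn <- sqrt(kaa * kbb)
      if (nn == 0) return(0)
      ct <- min(1, max(-1, kab / nn))
      th <- acos(ct)
      (1 / pi) * nn * (sin(th) + (pi - th) * ct)
    }
    new_xz <- step1(kxx, kzz, kxz)
    kxx <- step1(kxx, kxx, kxx)
    kzz <- step1(kzz, kzz, kzz)
    kxz <- new_xz
  }
  kxz
}

# PSD-clamped pseudo-inverse Nystrom oracle (independent route through
# MASS::ginv on the clamped anchor kernel).
nystrom_oracle <- function(K, anchors) {
  Knm <- K[, anchors, drop = FALSE]
  Kmm <- K[anchors, anchors, drop = FALSE]
  eg <- eigen((Kmm + t(Kmm)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  lam[lam < 1e-10 * max(lam)] <- 0
  Kmm_plus <- eg$vectors %*% (lam * t(eg$vectors))
  Knm %*% MASS::ginv(Kmm_plus) %*% t(Knm)
}

# Closed-form centered ridge predictor (independent of the package fits).
ridge_oracle <- function(Xtr, ytr, Xte, lambda) {
  ctr <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, ctr)
  b <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)),
             crossprod(Xc, ytr - mean(ytr)))
  as.numeric(sweep(as.matrix(Xte), 2, ctr) %*% b) + mean(ytr)
}

# Closed-form kernel ridge from a precomputed kernel.
krr_oracle <- function(Ktr, Kte_tr, ytr, lambda = 0.1) {
  as.numeric(Kte_tr %*% solve(Ktr + lambda * diag(nrow(Ktr)),
                              ytr - mean(ytr))) + mean(ytr)
}
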