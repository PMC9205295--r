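test_that("response types are inferred from the data", {
  expect_identical(infer_response_type(c("a", "b", "a"))$type, "binary")
  expect_identical(infer_response_type(c("a", "b", "c"))$type, "categorical")
  expect_identical(infer_response_type(c(1.2, 3.4, 5.6))$type, "continuous")
  expect_error(infer_response_type(rep("a", 5)), "constant response")
  expect_warning(infer_response_type(c(0, 1, 2, 5, 3)), "counts")
})

test_that("fits carry the package-wide defaults", {
  sim <- simulate_dataset(sim_config(n_lines = 40, p_markers = 20,
                                     n_env = 1, env_effect_sd = 0,
                                     seed = 2))
  X <- center_scale(sim$markers)
  y <- sim$pheno$y[match(rownames(X), sim$pheno$Line)]
  rf <- fit("random_forest", X, y, seed = 1)
  expect_equal(rf$params$trees_number, 500L)
  expect_equal(rf$params$node_size, 5L)
  lm_ <- fit("linear_model", X, y, seed = 1)
  expect_equal(lm_$params$alpha, 1)
  expect_error(fit("no_such_model", X, y), "arg")
})

test_that("a signal-free design yields intercept-only predictions", {
  y <- c(1.5, 2.5, 3.5, 4.5, 2, 3)
  X <- matrix(0, 6, 1, dimnames = list(NULL, "m1"))
  m <- fit("linear_model", X, y, seed = 1)
  pred <- predict(m, X)
  expect_lt(max(abs(pred - mean(y))), 1e-6)
})

test_that("classification predictions carry normalized probabilities", {
  withr::with_seed(5, {
    n <- 60
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
    y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.3) > 0, "hi", "lo")
  })
  for (mod in c("random_forest", "svm", "linear_model",
                "boosted_machine")) {
    m <- fit(mod, X, y, seed = 7)
    pr <- predict(m, X)
    expect_true(all(pr$class %in% c("hi", "lo")))
    expect_lt(max(abs(rowSums(pr$probabilities) - 1)), 1e-8)
    expect_identical(colnames(pr$probabilities), c("hi", "lo"))
  }
})

test_that("a memorizing random forest recovers separable training labels", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(40, mean = -3), 20, 2),
               matrix(rnorm(40, mean = 3), 20, 2))
    colnames(X) <- c("m1", "m2")
    y <- rep(c("neg", "pos"), each = 20)
  })
  m <- fit("random_forest", X, y,
           hyperparams = list(node_size = 1L), seed = 3)
  expect_identical(as.character(predict(m, X)$class), y)
})

test_that("empty prediction inputs yield empty outputs, bad columns error", {
  sim <- simulate_dataset(sim_config(n_lines = 30, p_markers = 10,
                                     n_env = 1, env_effect_sd = 0,
                                     seed = 9))
  X <- center_scale(sim$markers)
  y <- sim$pheno$y[match(rownames(X), sim$pheno$Line)]
  m <- fit("random_forest", X, y, seed = 1)
  expect_length(predict(m, X[0, , drop = FALSE]), 0)
  X_bad <- X[, 1:3]
  expect_error(predict(m, X_bad), "missing from x_new")
})

test_that("BRR recovers coefficients on noiseless data and replays by seed", {
  withr::with_seed(21, {
    n <- 100; p <- 20
    X <- matrix(rnorm(n * p), n, p)
    b <- rnorm(p)
    y <- as.numeric(2 + X %*% b)
  })
  f <- fit_brr(X, y, seed = 11)
  expect_lt(sqrt(mean((f$effects - b)^2)) / sd(b), 0.05)

  f2 <- fit_brr(X, y, seed = 11)
  expect_identical(f$samples, f2$samples)
  expect_identical(f$effects, f2$effects)
  expect_error(fit_brr(X, y, iterations = 100, burn_in = 200), "exceed")
})

test_that("BRR approaches least squares when shrinkage vanishes", {
  withr::with_seed(22, {
    n <- 200; p <- 5
    X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)
    b <- c(2, -1, 0.5, 1.5, -0.25)
    y <- as.numeric(X %*% b + rnorm(n, 0, 0.1))
  })
  ols <- as.numeric(coef(lm(y ~ X))[-1])
  f <- fit_brr(X, y, seed = 5)
  expect_lt(max(abs(f$effects - ols)), 0.05)
})

test_that("GBLUP with an identity kernel matches BRR on line indicators", {
  sim <- simulate_dataset(sim_config(n_lines = 80, p_markers = 60,
                                     h2 = 0.6, n_env = 1,
                                     env_effect_sd = 0, seed = 31))
  X <- center_scale(sim$markers)
  y <- sim$pheno$y[match(rownames(X), sim$pheno$Line)]
  K_id <- diag(nrow(X))
  dimnames(K_id) <- list(rownames(X), rownames(X))
  g <- fit_gblup(K_id, y, seed = 41)
  b <- fit_brr(diag(nrow(X)), y, seed = 42)
  expect_gt(cor(predict(g), predict(b, diag(nrow(X)))), 0.99)
})

test_that("GBLUP detects a zero-residual limit", {
  # y = mu + u exactly, each line replicated in 3 noise-free environments
  sim <- simulate_dataset(sim_config(n_lines = 60, p_markers = 40,
                                     h2 = 1, n_env = 3,
                                     env_effect_sd = 0, seed = 32))
  X <- center_scale(sim$markers)
  K <- compute_kernel(X)
  f <- fit_gblup(K, sim$pheno$y, Z = sim$pheno$Line, seed = 43)
  expect_lt(median(f$samples$sigma2_e), 0.05 * median(f$samples$sigma2_u))
})

test_that("Gibbs chains are stable across half-chains", {
  sim <- simulate_dataset(sim_config(n_lines = 120, p_markers = 100,
                                     h2 = 0.5, n_env = 1,
                                     env_effect_sd = 0, seed = 33))
  X <- center_scale(sim$markers)
  K <- compute_kernel(X)
  y <- sim$pheno$y[match(rownames(X), sim$pheno$Line)]
  f <- fit_gblup(K, y, iterations = 3000, burn_in = 1000, seed = 44)
  s <- f$samples$sigma2_u
  h1 <- mean(s[seq_len(length(s) / 2)])
  h2_ <- mean(s[-seq_len(length(s) / 2)])
  expect_lt(abs(h1 - h2_) / mean(s), 0.05)
})

test_that("GBLUP handles unbalanced incidence and predicts new lines", {
  sim <- simulate_dataset(sim_config(n_lines = 50, p_markers = 40,
                                     h2 = 0.7, n_env = 2,
                                     env_effect_sd = 0.3, seed = 34))
  X <- center_scale(sim$markers)
  K <- compute_kernel(X)
  ph <- sim$pheno
  # drop some records so line replication is unequal (general sampler path)
  ph <- ph[-c(3, 10, 17, 55), ]
  train_lines <- rownames(K)[1:40]
  tr <- ph[ph$Line %in% train_lines, ]
  f <- fit_gblup(K[train_lines, train_lines], tr$y, Z = tr$Line, seed = 45)
  expect_length(predict(f, line_ids = tr$Line), nrow(tr))
  new_lines <- setdiff(rownames(K), train_lines)
  pr <- predict(f, K_new = K[new_lines, train_lines])
  expect_length(pr, length(new_lines))
  expect_error(predict(f, line_ids = new_lines), "absent")
  # bayesian samplers refuse non-continuous responses
  expect_error(fit("bayesian_brr", X, sample(c("a", "b"), 50, TRUE)),
               "continuous")
})
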