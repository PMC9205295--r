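make_toy_predictions <- function() {
  # 2 environments x 2 folds, 2 records per cell (8 records)
  data.frame(
    model = "m",
    fold = c(1, 1, 1, 1, 2, 2, 2, 2),
    env = c("E1", "E1", "E2", "E2", "E1", "E1", "E2", "E2"),
    line = paste0("L", 1:8),
    observed = c(1, 2, 3, 5, 2, 4, 1, 3),
    predicted = c(1.5, 1.5, 4, 4, 2.5, 3.5, 2, 2),
    stringsAsFactors = FALSE)
}

test_that("summaries match a spreadsheet-style manual computation", {
  su <- summaries(make_toy_predictions())
  pick <- function(metric, env) {
    su[su$metric == metric & su$env == env, ]
  }
  # E1 fold MSEs: f1 mean((1-1.5)^2,(2-1.5)^2)=0.25; f2 = 0.25
  r <- pick("MSE", "E1")
  expect_equal(r$mean, 0.25)
  expect_equal(r$se, 0)
  # E2 fold MSEs: f1 = ((3-4)^2+(5-4)^2)/2 = 1; f2 = ((1-2)^2+(3-2)^2)/2 = 1
  expect_equal(pick("MSE", "E2")$mean, 1)
  # Global: fold 1 pooled MSE = (0.25+0.25+1+1)/4 = 0.625; fold 2 same
  g <- pick("MSE", "Global")
  expect_equal(g$mean, 0.625)
  expect_equal(g$se, 0)
  # MAE, E1: both folds 0.5
  expect_equal(pick("MAE", "E1")$mean, 0.5)
  # SE definition: sd over folds / sqrt(folds)
  e2r <- pick("RMSE", "E2")
  expect_equal(e2r$se, sd(c(1, 1)) / sqrt(2))
})

test_that("pooled Global MSE is the record-weighted mean of env MSEs", {
  withr::with_seed(13, {
    preds <- data.frame(
      model = "m",
      fold = rep(1:3, each = 20),
      env = rep(rep(c("E1", "E2"), c(12, 8)), 3),
      line = paste0("L", 1:60),
      observed = rnorm(60),
      predicted = rnorm(60))
  })
  su <- summaries(preds)
  for (f in 1:3) {
    cell <- preds[preds$fold == f, ]
    pooled <- mse(cell$observed, cell$predicted)
    by_env <- sapply(split(cell, cell$env), function(d) {
      c(m = mse(d$observed, d$predicted), n = nrow(d))
    })
    expect_equal(pooled,
                 sum(by_env["m", ] * by_env["n", ]) / sum(by_env["n", ]),
                 tolerance = 1e-12)
  }
  # and the Global row is the fold average of the pooled values
  g <- su[su$metric == "MSE" & su$env == "Global", ]
  pooled_by_fold <- sapply(split(preds, preds$fold), function(d) {
    mse(d$observed, d$predicted)
  })
  expect_equal(g$mean, mean(pooled_by_fold), tolerance = 1e-12)
})

test_that("summaries are invariant to record order and warn on tiny cells", {
  preds <- make_toy_predictions()
  withr::with_seed(5, shuffled <- preds[sample(nrow(preds)), ])
  expect_equal(summaries(preds), summaries(shuffled))

  single <- preds[1, ]
  w <- testthat::capture_warnings(su <- summaries(single))
  expect_true(any(grepl("NRMSE", w)))
  expect_true(is.na(su$mean[su$metric == "NRMSE" & su$env == "E1"]))
  expect_true(all(is.na(su$se))) # one fold: no SE
})

test_that("categorical prediction tables are summarized with class metrics", {
  preds <- data.frame(
    fold = rep(1:2, each = 6),
    env = rep(c("E1", "E1", "E1", "E2", "E2", "E2"), 2),
    line = paste0("L", 1:12),
    observed = rep(c("a", "b", "a", "b", "a", "b"), 2),
    predicted = c("a", "b", "a", "b", "a", "b",
                  "a", "b", "b", "b", "a", "a"))
  su <- summaries(preds)
  expect_true(all(c("accuracy", "kappa") %in% su$metric))
  g <- su[su$metric == "accuracy" & su$env == "Global", ]
  expect_equal(g$mean, mean(c(1, 4 / 6)))
})

test_that("the benchmark loop produces complete, leak-free predictions", {
  sim <- simulate_dataset(sim_config(n_lines = 50, p_markers = 40,
                                     h2 = 0.8, n_env = 2,
                                     env_effect_sd = 0.3, seed = 61))
  X <- center_scale(sim$markers)
  parts <- make_random_partitions(nrow(sim$pheno), 0.2, 5, seed = 3,
                                  strata = sim$pheno$Env)
  preds <- run_benchmark(sim$pheno, X, models = "bayesian_brr",
                         partitions = parts, seed = 3)
  expect_equal(nrow(preds), 5 * 20) # 20% of 100 records x 5 partitions
  for (f in 1:5) {
    test_keys <- with(preds[preds$fold == f, ], paste(line, env))
    train_rows <- parts[[f]]$train
    train_keys <- paste(sim$pheno$Line[train_rows],
                        sim$pheno$Env[train_rows])
    expect_length(intersect(test_keys, train_keys), 0)
  }
  # reproducibility under the same seeds
  preds2 <- run_benchmark(sim$pheno, X, models = "bayesian_brr",
                          partitions = parts, seed = 3)
  expect_identical(preds, preds2)
})

test_that("gblup consumes the kernel directly in the benchmark", {
  sim <- simulate_dataset(sim_config(n_lines = 40, p_markers = 50,
                                     h2 = 0.8, n_env = 2,
                                     env_effect_sd = 0.2, seed = 62))
  X <- center_scale(sim$markers)
  K <- compute_kernel(X)
  parts <- make_random_partitions(nrow(sim$pheno), 0.25, 2, seed = 4,
                                  strata = sim$pheno$Env)
  preds <- run_benchmark(sim$pheno, K, models = "bayesian_gblup",
                         partitions = parts, seed = 4)
  expect_equal(nrow(preds), 2 * 20)
  expect_true(all(is.finite(preds$predicted)))
  expect_error(run_benchmark(sim$pheno, X, models = "bayesian_gblup",
                             partitions = parts),
               "symmetric kernel")
  bad <- sim$pheno
  bad$Line[1] <- "NOPE"
  expect_error(run_benchmark(bad, K, models = "bayesian_gblup",
                             partitions = parts), "NOPE")
})

test_that("genomic signal beats the intercept baseline at high heritability", {
  deltas <- sapply(1:10, function(s) {
    sim <- simulate_dataset(sim_config(n_lines = 80, p_markers = 60,
                                       h2 = 0.8, n_env = 1,
                                       env_effect_sd = 0, seed = 700 + s))
    X <- center_scale(sim$markers)
    K <- compute_kernel(X)
    y <- sim$pheno$y[match(rownames(X), sim$pheno$Line)]
    part <- make_random_partitions(80, 0.2, 1, seed = s)[[1]]
    f <- fit_gblup(K[part$train, part$train], y[part$train], seed = s)
    pred <- predict(f, K_new = K[part$test, part$train])
    c(model = nrmse(y[part$test], pred, "sd"),
      base = nrmse(y[part$test], rep(mean(y[part$train]),
                                     length(part$test)), "sd"))
  })
  expect_lt(mean(deltas["model", ]), 0.8 * mean(deltas["base", ]))
})

test_that("percent outperformance reproduces the worked arithmetic", {
  expect_equal(percent_outperformance(0.5951, 0.5769), 3.05)
  expect_equal(percent_outperformance(0.2603, 0.2059), 20.89)
  expect_equal(percent_outperformance(0.7, 0.7), 0)
  expect_equal(percent_outperformance(2, 3), -50)
  expect_error(percent_outperformance(0, 1), "positive")
  expect_error(percent_outperformance(-1, 1), "positive")
})
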