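test_that("regression metrics match direct arithmetic", {
  y <- c(1, 2); yh <- c(2, 2)
  expect_equal(mse(y, yh), 0.5)
  expect_equal(mae(y, yh), 0.5)
  expect_equal(rmse(y, yh), sqrt(0.5))
  expect_equal(as.numeric(maape(y, yh)), pi / 8)

  expect_equal(mse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(as.numeric(maape(y, y)), 0)

  # zero-observed limit contributes pi/2 and is counted
  m0 <- maape(0, 5)
  expect_equal(as.numeric(m0), pi / 2)
  expect_equal(attr(m0, "n_zero_observed"), 1L)
  expect_error(mse(1:3, 1:2), "lengths differ")
})

test_that("NRMSE normalizations follow their definitions", {
  y <- c(1, 2, 3); yh <- c(2, 2, 2)
  expect_equal(nrmse(y, yh, "sd"), sqrt(2 / 3) / 1, tolerance = 1e-12)
  expect_equal(nrmse(y, yh, "mean"), sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(nrmse(y, yh, "range"), sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(nrmse(y, yh, "iqr"), sqrt(2 / 3) / 1, tolerance = 1e-12)
  expect_equal(nrmse(y, y, "sd"), 0)

  # mean predictor scores sqrt((n-1)/n) under the sample-sd convention
  withr::with_seed(3, {
    for (n in c(5, 20, 100)) {
      yr <- rnorm(n)
      expect_equal(nrmse(yr, rep(mean(yr), n), "sd"),
                   sqrt((n - 1) / n), tolerance = 1e-12)
    }
  })
  expect_error(nrmse(c(1, 1), c(1, 2), "sd"), "normalizer")
  expect_error(nrmse(c(-1, 1), c(0, 0), "mean"), "normalizer")
})

test_that("confusion matrix counts observed x predicted", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unclass(cm),
               matrix(c(1, 0, 1, 1), 2, 2,
                      dimnames = list(observed = c("a", "b"),
                                      predicted = c("a", "b"))))
  expect_equal(sum(cm), 3)
  perfect <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion_matrix(c("a", "b"), c("a", "z")), "outside")
})

test_that("binary metrics reproduce the hand-counted 2x2 example", {
  # TP = 4, FN = 1, FP = 2, TN = 3 with positive class 'a'
  obs <- c(rep("a", 5), rep("b", 5))
  pred <- c("a", "a", "a", "a", "b", "a", "a", "b", "b", "b")
  expect_equal(accuracy(obs, pred), 0.7)
  expect_equal(sensitivity(obs, pred, positive = "a"), 0.8)
  expect_equal(specificity(obs, pred, positive = "a"), 0.6)
  expect_equal(precision(obs, pred, positive = "a"), 2 / 3)
  expect_equal(recall(obs, pred, positive = "a"), 0.8)
  expect_equal(f1_score(obs, pred, positive = "a"),
               2 * 0.8 * (2 / 3) / (0.8 + 2 / 3), tolerance = 1e-12)
})

test_that("chance-level and perfect predictions hit the metric boundaries", {
  obs <- rep(c("a", "b"), each = 10)
  expect_equal(kappa_coeff(obs, obs), 1)
  expect_equal(mcc(obs, obs), 1)
  expect_equal(accuracy(obs, obs), 1)
  all_a <- rep("a", 20)
  expect_equal(kappa_coeff(obs, all_a), 0)
  expect_equal(mcc(obs, all_a), 0)
})

test_that("every classification metric matches a brute-force recomputation", {
  brute <- function(cm) {
    tot <- sum(cm); L <- nrow(cm)
    acc <- sum(diag(cm)) / tot
    po <- acc
    pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
    kap <- (po - pe) / (1 - pe)
    per <- lapply(seq_len(L), function(i) {
      tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp
      fp <- sum(cm[, i]) - tp; tn <- tot - tp - fn - fp
      c(sens = tp / (tp + fn), spec = tn / (tn + fp),
        prec = tp / (tp + fp), f1 = 2 * tp / (2 * tp + fp + fn))
    })
    m <- do.call(rbind, per)
    num <- sum(diag(cm)) * tot - sum(colSums(cm) * rowSums(cm))
    den <- sqrt(tot^2 - sum(colSums(cm)^2)) * sqrt(tot^2 - sum(rowSums(cm)^2))
    pick <- function(col) {
      unname(if (L == 2) m[1, col] else mean(m[, col], na.rm = TRUE))
    }
    list(acc = acc, kappa = kap, sens = pick("sens"), spec = pick("spec"),
         prec = pick("prec"), f1 = pick("f1"),
         mcc = if (den == 0) 0 else num / den)
  }
  for (s in 1:100) {
    withr::with_seed(s, {
      L <- sample(2:4, 1)
      lv <- letters[seq_len(L)]
      n <- sample(20:60, 1)
      obs <- sample(lv, n, replace = TRUE)
      while (length(unique(obs)) < L) obs <- sample(lv, n, replace = TRUE)
      pred <- sample(lv, n, replace = TRUE)
    })
    cm <- confusion_matrix(obs, pred, lv)
    o <- brute(unclass(cm))
    expect_equal(accuracy(cm), o$acc)
    expect_equal(kappa_coeff(cm), o$kappa)
    expect_equal(sensitivity(cm, positive = lv[1]), o$sens)
    expect_equal(specificity(cm, positive = lv[1]), o$spec)
    expect_equal(precision(cm, positive = lv[1]), o$prec)
    expect_equal(f1_score(cm, positive = lv[1]), o$f1)
    expect_equal(mcc(cm), o$mcc)
  }
})

test_that("ROC-AUC equals the midrank Mann-Whitney statistic", {
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      n <- 40
      obs <- sample(c("pos", "neg"), n, replace = TRUE,
                    prob = c(0.4, 0.6))
      while (length(unique(obs)) < 2) {
        obs <- sample(c("pos", "neg"), n, replace = TRUE)
      }
      p <- round(runif(n), 2) # ties on purpose
    })
    is_pos <- obs == "pos"
    u <- sum(rank(p)[is_pos]) - sum(is_pos) * (sum(is_pos) + 1) / 2
    expect_equal(roc_auc(obs, p, positive = "pos"),
                 u / (sum(is_pos) * sum(!is_pos)))
  }
})

test_that("ROC-AUC agrees with pROC on binary problems", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    obs <- sample(c("pos", "neg"), 50, replace = TRUE)
    p <- runif(50)
  })
  ours <- roc_auc(obs, p, positive = "pos")
  ref <- as.numeric(pROC::auc(pROC::roc(response = obs, predictor = p,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("probability-based metrics validate and score correctly", {
  obs <- c("a", "a", "b")
  P <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  colnames(P) <- c("a", "b")
  expect_equal(brier_score(obs, P),
               mean(c((0.9 - 1)^2 + 0.1^2, (0.6 - 1)^2 + 0.4^2,
                      0.2^2 + (0.8 - 1)^2)))
  perfect <- rbind(c(1, 0), c(1, 0), c(0, 1))
  colnames(perfect) <- c("a", "b")
  expect_equal(brier_score(obs, perfect), 0)
  expect_equal(roc_auc(obs, P, positive = "a"), 1)
  expect_equal(pr_auc(obs, P, positive = "a"), 1)
  bad <- P; bad[1, ] <- c(0.7, 0.7)
  expect_error(brier_score(obs, bad), "sum to 1")
  bad2 <- P; bad2[1, ] <- c(1.4, -0.4)
  expect_error(brier_score(obs, bad2), "outside")
})

test_that("summary wrappers equal the individual metric calls bit-for-bit", {
  withr::with_seed(9, {
    y <- rnorm(30, 10, 2)
    yh <- y + rnorm(30, 0, 1)
  })
  rep_ <- numeric_summary(y, yh)
  expect_named(rep_, c("mse", "rmse", "nrmse", "mae", "maape"))
  expect_named(rep_$nrmse, c("sd", "mean", "range", "iqr"))
  expect_identical(rep_$mse, mse(y, yh))
  expect_identical(rep_$rmse, rmse(y, yh))
  expect_identical(rep_$mae, mae(y, yh))
  expect_identical(rep_$nrmse[["sd"]], nrmse(y, yh, "sd"))
  expect_identical(rep_$maape, as.numeric(maape(y, yh)))

  obs <- c(rep("a", 5), rep("b", 5))
  pred <- c("a", "a", "a", "a", "b", "a", "a", "b", "b", "b")
  cr <- categorical_summary(obs, pred, positive = "a")
  expect_identical(cr$accuracy, 0.7)
  expect_identical(cr$sensitivity, 0.8)
  expect_identical(cr$specificity, 0.6)
  expect_true(is.na(cr$roc_auc)) # no probabilities supplied
  expect_s3_class(attr(cr, "confusion"), "confusion_matrix")
})

test_that("metric ranges respect their theoretical bounds", {
  for (s in 1:20) {
    withr::with_seed(200 + s, {
      n <- 30
      obs <- sample(c("a", "b", "c"), n, replace = TRUE)
      while (length(unique(obs)) < 3) {
        obs <- sample(c("a", "b", "c"), n, replace = TRUE)
      }
      pred <- sample(c("a", "b", "c"), n, replace = TRUE)
      y <- rnorm(n); yh <- rnorm(n)
    })
    expect_true(accuracy(obs, pred) >= 0 && accuracy(obs, pred) <= 1)
    expect_true(kappa_coeff(obs, pred) >= -1 && kappa_coeff(obs, pred) <= 1)
    expect_true(mcc(obs, pred) >= -1 && mcc(obs, pred) <= 1)
    mv <- as.numeric(maape(y, yh))
    expect_true(mv >= 0 && mv <= pi / 2)
  }
})
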