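test_that("MCC follows the printed confusion formula", {
  # TP=45 TN=45 FP=5 FN=5 -> (2025-25)/2500 = 0.8
  pred <- c(rep(1, 45), rep(0, 5), rep(1, 5), rep(0, 45))
  lab  <- c(rep(1, 50), rep(0, 50))
  rep_ <- score_classifier(pred, lab)
  expect_equal(rep_$mcc, 0.8)
  expect_equal(c(rep_$tp, rep_$fn, rep_$fp, rep_$tn), c(45, 5, 5, 45))

  perfect <- score_classifier(lab, lab, scores = lab)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc, 1)

  # all-positive predictions: a zero denominator factor defines MCC = 0
  allpos <- score_classifier(rep(1, 100), lab)
  expect_equal(allpos$mcc, 0)
  expect_error(score_classifier(integer(0), integer(0)), "empty")
})

test_that("MCC equals an independent recomputation on random vectors", {
  set.seed(70)
  for (i in 1:20) {
    pred <- sample(0:1, 60, TRUE)
    lab <- sample(0:1, 60, TRUE)
    m <- score_classifier(pred, lab)$mcc
    tp <- sum(pred & lab); tn <- sum(!pred & !lab)
    fp <- sum(pred & !lab); fn <- sum(!pred & lab)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    expect_equal(m, if (den == 0) 0 else (tp * tn - fp * fn) / den)
  }
})

test_that("AUC is the normalized rank statistic and 0.5 for random scores", {
  set.seed(71)
  lab <- sample(0:1, 4000, TRUE)
  sc <- runif(4000)                       # independent of labels
  expect_lt(abs(score_classifier(as.integer(sc > 0.5), lab, scores = sc)$auc - 0.5),
            0.03)
  # against the Mann-Whitney U from wilcox.test
  lab2 <- sample(0:1, 100, TRUE)
  sc2 <- rnorm(100) + lab2
  auc <- score_classifier(as.integer(sc2 > 0), lab2, scores = sc2)$auc
  w <- wilcox.test(sc2[lab2 == 1], sc2[lab2 == 0])$statistic
  expect_equal(auc, unname(w) / (sum(lab2 == 1) * sum(lab2 == 0)))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  lab <- sample(0:1, 150, TRUE)
  sc <- runif(150) + 0.4 * lab
  ours <- score_classifier(as.integer(sc > 0.7), lab, scores = sc)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the structural-theory classifier follows 2kp(1-p) = 1", {
  expect_equal(st_theoretical_classify(2, 0.5), 0L)   # exactly critical
  expect_equal(st_theoretical_classify(8, 0.5), 1L)
  expect_equal(st_theoretical_classify(2, 0.05), 0L)
})

test_that("fitted boundaries put probability 0.5 exactly on the locus", {
  set.seed(73)
  rec <- simulate_boundary_records(800, c_true = 3, steepness = 6)
  for (cls in c(2, 3, 6)) {
    fit <- fit_model(rec, cls, kappa = "ke")
    b <- fit$boundary
    # construct a record lying on the fitted boundary
    if (cls == 2) {
      pq <- 0.2
      ke0 <- 1 / (b[["kappa_pq"]] * pq)
      p0 <- (1 - sqrt(1 - 4 * pq)) / 2
      on_boundary <- data.frame(k = 2, p = p0, ke = ke0, zeta = NA, chaotic = 1L)
      pr <- predict(fit, on_boundary)
      expect_equal(pr$prob, 0.5, tolerance = 1e-9)
      expect_equal(pr$pred, 1L)   # ties at tau go to chaotic
    } else {
      # check the identity b0 + sum(beta t) = 0 <=> sum(c t) = 1 directly
      beta <- fit$coefficients
      expect_equal(unname(-beta[-1] / beta[1]), unname(b))
    }
  }
})

test_that("a known class-2 law is recovered from noisy labels", {
  set.seed(74)
  rec <- simulate_boundary_records(1000, c_true = 3.94, steepness = 10)
  fit <- fit_model(rec, 2, kappa = "ke")
  c_hat <- fit$boundary[["kappa_pq"]]
  expect_lt(abs(c_hat - 3.94) / 3.94, 0.05)
  expect_error(fit_model(rec[rec$chaotic == 1, ], 2, "ke"), "both regime")
})

test_that("the interaction fit vanishes when only ke matters", {
  set.seed(75)
  rec <- simulate_boundary_records(4000, c_true = 2, steepness = 8)
  rec$p <- 0.5   # remove bias variation: label driven by ke only
  pq <- 0.25
  rec$chaotic <- rbinom(4000, 1, plogis(8 * (2 * rec$ke * pq - 1)))
  fit <- fit_interaction_model(rec)
  beta <- fit$coefficients
  # k and k:ke coefficients are negligible next to the ke coefficient
  expect_gt(abs(beta[["ke"]]), 7 * abs(beta[["k"]]))
  expect_gt(abs(beta[["ke"]]), 7 * abs(beta[["k_ke"]]))
  expect_error(fit_interaction_model(rec[rec$chaotic == 1, ]), "both regime")
})

test_that("nested CV yields 16 disjoint train/test folds, reproducibly", {
  set.seed(76)
  rec <- simulate_boundary_records(400, c_true = 3, steepness = 5)
  cv1 <- nested_cv(rec, 2, "ke", seed = 9L)
  cv2 <- nested_cv(rec, 2, "ke", seed = 9L)
  expect_equal(nrow(cv1), 16L)
  expect_identical(cv1, cv2)
  expect_true(all(is.finite(cv1$mcc)))
  s <- cv_summary(cv1)
  expect_named(s, c("mcc", "auc", "r2"))
  expect_error(nested_cv(rec[1:20, ], 2, "ke"), "at least 16")
})

test_that("fold assignments are shared across models under one seed", {
  set.seed(77)
  rec <- simulate_boundary_records(400, c_true = 3, steepness = 5)
  a <- nested_cv(rec, 2, "ke", seed = 4L)
  b <- nested_cv(rec, 1, "k", seed = 4L)
  expect_identical(a[, c("outer", "inner")], b[, c("outer", "inner")])
})

test_that("on class-2 data the class-2 fit is at least as good as class 1", {
  set.seed(78)
  rec <- simulate_boundary_records(1200, c_true = 3.94, steepness = 12)
  m2 <- cv_summary(nested_cv(rec, 2, "ke", seed = 1L))[["mcc"]]
  m1 <- cv_summary(nested_cv(rec, 1, "ke", seed = 1L))[["mcc"]]
  expect_gte(m2, m1)
})

test_that("the paired one-sided t-test handles regular and degenerate input", {
  set.seed(79)
  x <- rnorm(16)
  identical_case <- paired_t_onesided(x, x)
  expect_equal(identical_case$p_value, 0.5)
  expect_true(identical_case$degenerate)

  # exact dyadic values keep the constant shift exact in floating point
  xq <- sample(seq(-2, 2, by = 0.25), 16, replace = TRUE)
  shifted <- paired_t_onesided(xq + 1, xq)
  expect_equal(shifted$p_value, 0)
  expect_true(shifted$degenerate)

  y <- x + rnorm(16, mean = 0.5)
  ours <- paired_t_onesided(y, x)
  ref <- t.test(y, x, paired = TRUE, alternative = "greater")
  expect_equal(ours$p_value, unname(ref$p.value))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_false(ours$degenerate)
})

test_that("paired t p-values are uniform under the null", {
  set.seed(80)
  pv <- replicate(1000, {
    a <- rnorm(16); b <- rnorm(16)
    paired_t_onesided(a, b)$p_value
  })
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Pareto selection picks the earliest near-optimal class", {
  expect_equal(pareto_select(c(0.0, 0.96, 0.96, 0.97, 0.97, 0.97), 0.01), 2L)
  expect_equal(pareto_select(c(0.1, 0.3, 0.5, 0.7, 0.85, 0.99), 0.01), 6L)
  expect_equal(pareto_select(rep(0.5, 6), 0.01), 1L)
})

test_that("McFadden R2 uses the supplied null probability", {
  set.seed(81)
  lab <- rbinom(200, 1, 0.7)
  sc <- ifelse(lab == 1, 0.9, 0.1)
  r <- score_classifier(as.integer(sc > 0.5), lab, scores = sc,
                        null_prob = mean(lab))
  ll <- sum(lab * log(sc) + (1 - lab) * log(1 - sc))
  p0 <- mean(lab)
  ll0 <- sum(lab * log(p0) + (1 - lab) * log(1 - p0))
  expect_equal(r$r2, 1 - ll / ll0)
  expect_lte(r$r2, 1)
})
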