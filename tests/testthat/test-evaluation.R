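test_that("auc_score agrees with exhaustive pair counting and handles ties", {
  # perfect ranking and all-ties limits
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(0.7, 6), c(0, 1, 0, 1, 0, 1)), 0.5)

  # 6-point hand example vs brute force
  s <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  y <- c(1, 0, 1, 1, 0, 0)
  expect_equal(auc_score(s, y), auc_bruteforce(s, y))

  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    expect_equal(auc_score(s, y), auc_bruteforce(s, y), tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  set.seed(12)
  y <- c(rep(0, 10), rep(1, 10))
  s <- rnorm(20)
  expect_equal(auc_score(exp(s), y), auc_score(s, y))
  expect_equal(auc_score(2 * s + 5, y), auc_score(s, y))

  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("threshold metrics recompute from the confusion matrix definitions", {
  # all correct
  tm <- threshold_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(tm$accuracy, 1)
  expect_equal(tm$f_score, 1)

  # constructed confusion TN=3 FP=1 FN=2 TP=4
  scores <- c(rep(0.2, 3), 0.8, rep(0.2, 2), rep(0.8, 4))
  labels <- c(rep(0, 4), rep(1, 6))
  tm2 <- threshold_metrics(scores, labels)
  expect_equal(unname(as.vector(tm2$confusion)), c(3, 2, 1, 4))
  expect_equal(tm2$recall, 4 / 6)
  expect_equal(tm2$precision, 4 / 5)
  expect_equal(tm2$f_score, 2 * (4 / 5) * (4 / 6) / (4 / 5 + 4 / 6))
  expect_equal(tm2$accuracy, 7 / 10)
  expect_equal(sum(tm2$confusion), 10)

  # flipping predictions swaps TP<->FN and TN<->FP
  tm3 <- threshold_metrics(1 - scores, labels)
  expect_equal(tm3$confusion[2, 1], tm2$confusion[2, 2])  # FN' = TP
  expect_equal(tm3$confusion[1, 2], tm2$confusion[1, 1])  # FP' = TN

  # no positive predictions: precision flagged, reported as 0
  expect_warning(tm4 <- threshold_metrics(c(0.1, 0.2), c(0, 1)), "precision")
  expect_true(tm4$precision_undefined)
  expect_equal(tm4$precision, 0)
})

test_that("two-sample t-tests match stats::t.test and are antisymmetric", {
  set.seed(13)
  x <- matrix(rnorm(16 * 3), 16, 3,
              dimnames = list(NULL, feature_catalog()$name[1:3]))
  y <- rep(c(0, 1), each = 8)
  x[y == 1, 1] <- x[y == 1, 1] + 2

  tt <- two_sample_t(x, y)
  for (j in 1:3) {
    ref <- t.test(x[y == 1, j], x[y == 0, j], var.equal = TRUE)
    expect_equal(tt$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tt$p[j], ref$p.value, tolerance = 1e-12)
  }

  # 4+4 closed-form pooled-variance check
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  xs <- matrix(c(a, b), 8, 1, dimnames = list(NULL, "glcm_Contrast"))
  ys <- rep(c(1, 0), each = 4)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(two_sample_t(xs, ys)$t, t_hand, tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  xi <- matrix(rep(c(1, 2, 3), 2), 6, 1, dimnames = list(NULL, "glcm_Id"))
  tt_id <- two_sample_t(xi, rep(c(0, 1), each = 3))
  expect_equal(tt_id$t, 0)
  expect_equal(tt_id$p, 1)

  # swapping groups negates t, preserves p
  tt_sw <- two_sample_t(x, 1 - y)
  expect_equal(tt_sw$t, -tt$t, tolerance = 1e-12)
  expect_equal(tt_sw$p, tt$p, tolerance = 1e-12)

  # Welch option agrees with t.test default
  ttw <- two_sample_t(x, y, var_equal = FALSE)
  refw <- t.test(x[y == 1, 2], x[y == 0, 2])
  expect_equal(ttw$t[2], unname(refw$statistic), tolerance = 1e-12)
  expect_equal(ttw$p[2], refw$p.value, tolerance = 1e-12)

  expect_error(two_sample_t(x, rep(1, 16)), "class")
})

test_that("rank-based AUC cross-checks against pROC", {
  set.seed(14)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(auc_score(s, y), ref, tolerance = 1e-12)
})

test_that("evaluation reports are internally consistent and serialize", {
  set.seed(15)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- plogis(rnorm(40) + 1.5 * y)
  rep_ <- make_report(s, y, model_id = "secnn", cohort_id = "internal_test")
  expect_equal(rep_$n, 40)
  expect_equal(sum(rep_$confusion), 40)
  expect_equal(rep_$auc, auc_score(s, y))
  tm <- threshold_metrics(s, y)
  expect_equal(rep_$accuracy, tm$accuracy)
  expect_equal(rep_$f_score, tm$f_score)
  # ROC endpoints
  expect_equal(rep_$roc_points$fpr[1], 1)
  expect_equal(rep_$roc_points$tpr[1], 1)
  expect_equal(rep_$roc_points$fpr[nrow(rep_$roc_points)], 0)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$auc, rep_$auc, tolerance = 1e-12)
  expect_equal(back$confusion$tp, unname(rep_$confusion[2, 2]))
})
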