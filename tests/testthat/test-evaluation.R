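test_that("confusion metrics evaluate the standard formulas and flag 0/0", {
  m <- confusion_metrics(list(TP = 3, TN = 3, FP = 0, FN = 0, N = 6))
  expect_equal(unlist(m[c("sensitivity", "specificity", "accuracy")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))

  m2 <- confusion_metrics(list(TP = 5, TN = 0, FP = 0, FN = 5, N = 10))
  expect_equal(m2$sensitivity, 0.5)
  expect_true(is.nan(m2$specificity) && m2$undefined_specificity)

  expect_error(confusion_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0, N = 0)),
               "empty")

  set.seed(10)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    actual <- sample(c("responder", "non_responder"), n, replace = TRUE)
    pred <- sample(c("responder", "non_responder"), n, replace = TRUE)
    cts <- confusion_counts(pred, actual)
    expect_identical(cts$TP + cts$TN + cts$FP + cts$FN, cts$N)
    met <- confusion_metrics(cts)
    expect_equal(met$accuracy, mean(pred == actual))
    n_pos <- sum(actual == "responder"); n_neg <- cts$N - n_pos
    if (n_pos > 0 && n_neg > 0)
      expect_equal(met$accuracy,
                   (met$sensitivity * n_pos + met$specificity * n_neg) / cts$N)
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise statistic", {
  labs <- rep(c("responder", "non_responder"), each = 4)
  expect_equal(roc_auc(c(5, 6, 7, 8, 1, 2, 3, 4), labs)$auc, 1)
  expect_equal(roc_auc(rep(1, 8), labs)$auc, 0.5)

  set.seed(20)
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    lab <- rep(c("responder", "non_responder"), c(n1, n2))
    sc <- round(rnorm(n1 + n2), 1)          # rounded to force ties
    r <- roc_auc(sc, lab)
    expect_equal(r$auc, mw_auc(sc, lab), tolerance = 1e-12)
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[length(r$fpr)], 1)
    expect_false(is.unsorted(r$fpr) || is.unsorted(r$tpr))
    # complement symmetry (tie-free case)
    sc2 <- rnorm(n1 + n2)
    expect_equal(roc_auc(sc2, lab)$auc + roc_auc(-sc2, lab)$auc, 1,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("responder", 4)), "both classes")
})

test_that("cross-validation is stratified, seeded, and leak-free", {
  cfg <- sim_config(n_genes = 300, de_fraction = 0.05, log2_effect = 3,
                    n_responders = 6, n_nonresponders = 6, seed = 61)
  co <- simulate_cohort(cfg)
  genes <- co$truth$gene_id[1:5]
  cv1 <- kfold_cv(co$expression, genes, k = 5, repeats = 2, seed = 17)
  cv2 <- kfold_cv(co$expression, genes, k = 5, repeats = 2, seed = 17)
  expect_identical(cv1$assignments, cv2$assignments)
  expect_identical(cv1$folds, cv2$folds)

  # folds partition the samples and stratify both classes
  for (r in 1:2) {
    f <- cv1$assignments[, r]
    expect_setequal_sorted(names(f), names(co$expression$labels))
    per_fold <- table(f, co$expression$labels[names(f)])
    expect_true(all(per_fold >= 1))
  }

  expect_error(kfold_cv(co$expression, genes, k = 1), "at least 2")
  expect_warning(kfold_cv(co$expression, genes, k = 10, repeats = 1,
                          seed = 1), "reducing k")
})

test_that("cross-validation recovers strong planted signal and stays null under permutation", {
  accs <- vapply(1:5, function(s) {
    co <- simulate_cohort(sim_config(n_genes = 200, de_fraction = 0.05,
                                     log2_effect = 4, seed = 400 + s))
    genes <- co$truth$gene_id[1:6]
    kfold_cv(co$expression, genes, k = 5, repeats = 2,
             seed = s)$overall[["accuracy"]]
  }, numeric(1))
  expect_gte(mean(accs), 0.9)

  set.seed(500)
  aucs <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(n_genes = 200, de_fraction = 0.05,
                                     log2_effect = 4, seed = 600 + s))
    genes <- co$truth$gene_id[1:6]
    perm <- stats::setNames(sample(co$expression$labels),
                            names(co$expression$labels))
    expr <- expression_matrix(co$expression$values, perm)
    kfold_cv(expr, genes, k = 3, repeats = 2, seed = s)$overall[["auc"]]
  }, numeric(1))
  expect_gte(mean(aucs), 0.3)
  expect_lte(mean(aucs), 0.7)
})

test_that("the DeLong comparison is internally consistent and detects real differences", {
  labs <- rep(c("responder", "non_responder"), each = 100)
  set.seed(70)
  good <- c(rnorm(100, 3), rnorm(100, 0))
  noise <- rnorm(200)
  cmp <- compare_auc(good, noise, labs)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$auc_a, roc_auc(good, labs)$auc, tolerance = 1e-12)
  expect_equal(cmp$auc_b, roc_auc(noise, labs)$auc, tolerance = 1e-12)

  self <- compare_auc(good, good, labs)
  expect_equal(self$auc_a, self$auc_b)
  expect_equal(self$p_value, 1)

  expect_error(compare_auc(good, noise[1:10], labs), "same samples")
})

test_that("one-way ANOVA matches the pooled t and a permutation oracle", {
  g <- rep(c("a", "b"), each = 6)
  v <- c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6)
  same <- compare_groups_anova(v, g)
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(80)
  x <- c(rnorm(8), rnorm(8, 1))
  an <- compare_groups_anova(x, rep(c("a", "b"), each = 8))
  tt <- t.test(x[1:8], x[9:16], var.equal = TRUE)
  expect_equal(an$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-9)

  # permutation oracle on a small two-group problem
  set.seed(81)
  y <- c(rnorm(6), rnorm(6, 1.2))
  grp <- rep(c("a", "b"), each = 6)
  obs <- compare_groups_anova(y, grp)
  perm_f <- replicate(10000, compare_groups_anova(y, sample(grp))$f_statistic)
  p_perm <- mean(perm_f >= obs$f_statistic)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01
  expect_lt(abs(obs$p_value - p_perm), mc_err + 0.03)

  expect_error(compare_groups_anova(1:3, c("a", "a", "b")), "at least 2")
})
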