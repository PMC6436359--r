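test_that("Cronbach's alpha hits its definitional anchors", {
  m <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)   # identical non-constant items
  expect_equal(cronbach_alpha(m), 1)

  orth <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  expect_equal(cronbach_alpha(orth), 0)      # pairwise zero covariance

  worked <- matrix(c(2, 4, 3, 5,
                     1, 3, 2, 6,
                     3, 5, 5, 7), 4, 3)
  expect_equal(cronbach_alpha(worked), oracle_alpha(worked), tolerance = 1e-12)

  expect_error(cronbach_alpha(matrix(1:6, 3, 2) * 0),
               class = "scaspd_validation_error")  # zero variance
  expect_error(cronbach_alpha(matrix(1:6, 6, 1)),
               class = "scaspd_validation_error")  # single item

  # anti-correlated items: negative alpha is reported unclamped, with warning
  expect_warning(neg <- cronbach_alpha(cbind(c(1, 2, 3, 4), c(4, 3, 2, 1.5))),
                 "negative")
  expect_lt(neg, 0)
})

test_that("alpha is invariant to item shifts and joint positive rescaling", {
  set.seed(7)
  for (i in 1:20) {
    # common factor keeps alpha positive; invariance is what is under test
    m <- matrix(rnorm(60), 12, 5) + rnorm(12)
    a <- cronbach_alpha(m)
    shifted <- sweep(m, 2, runif(5, -10, 10), `+`)
    expect_equal(cronbach_alpha(shifted), a, tolerance = 1e-10)
    expect_equal(cronbach_alpha(m * runif(1, 0.1, 9)), a, tolerance = 1e-10)
  }
})

test_that("ICC anchors: identical columns, constant shifts, toy oracle", {
  x <- cbind(c(1, 2, 3, 4, 5, 7), c(1, 2, 3, 4, 5, 7))
  expect_equal(icc(x)$icc, 1)

  y <- cbind(a = c(1, 2, 3, 4, 5, 7), b = c(3, 4, 5, 6, 7, 9))  # b = a + 2
  expect_equal(icc(y, "twoway_mixed_consistency")$icc, 1)
  expect_lt(icc(y, "twoway_random_absolute")$icc, 1)

  toy <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2), c(5, 3, 6, 2, 6, 4))
  for (model in c("twoway_random_absolute", "twoway_mixed_consistency",
                  "oneway")) {
    for (unit in c("single", "average")) {
      expect_equal(icc(toy, model, unit)$icc, oracle_icc(toy, model, unit),
                   tolerance = 1e-10, label = paste(model, unit))
    }
  }
  expect_error(icc(matrix(3, 4, 2)), class = "scaspd_validation_error")
})

test_that("ICC confidence interval brackets the estimate and p is valid", {
  set.seed(21)
  for (i in 1:20) {
    subj <- rnorm(6, sd = 2)
    x <- cbind(subj + rnorm(6, sd = 0.5), subj + rnorm(6, sd = 0.5))
    r <- icc(x)
    expect_true(r$ci[1] <= r$icc + 1e-8 && r$icc <= r$ci[2] + 1e-8)
    expect_true(r$p >= 0 && r$p <= 1)
  }
})

test_that("weighted kappa anchors: perfect, chance and worked tables", {
  diag_tab <- diag(c(4, 6, 5))
  expect_equal(weighted_kappa(diag_tab)$kappa, 1)

  # observed counts exactly proportional to margin products -> kappa 0
  chance <- outer(c(2, 3, 5), c(4, 1, 5))
  expect_equal(weighted_kappa(chance, "linear")$kappa, 0, tolerance = 1e-12)
  expect_equal(weighted_kappa(chance, "quadratic")$kappa, 0, tolerance = 1e-12)

  worked <- matrix(c(11, 2, 19, 3, 30, 5, 1, 13, 16), 3, 3)
  for (w in c("linear", "quadratic"))
    expect_equal(weighted_kappa(worked, w)$kappa,
                 oracle_weighted_kappa(worked, w), tolerance = 1e-12)

  expect_error(weighted_kappa(matrix(1, 2, 3)),
               class = "scaspd_validation_error")
  expect_warning(k1 <- weighted_kappa(diag(c(7, 0))), "degenerate")
  expect_equal(k1$kappa, 1)
})

test_that("quadratic and linear weighted kappa coincide with Cohen's kappa on 2x2", {
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    kl <- weighted_kappa(tab, "linear")$kappa
    kq <- weighted_kappa(tab, "quadratic")$kappa
    ku <- cohen_kappa(tab)$kappa
    expect_equal(kl, kq, tolerance = 1e-12)
    expect_equal(kl, ku, tolerance = 1e-12)
  }
})

test_that("per-level kappa equals the 2x2 closed form and its degenerate limits", {
  a <- c("normal", "normal", "mild", "severe", "mild", "normal")
  b <- c("normal", "mild", "mild", "severe", "normal", "normal")
  pk <- per_level_kappa(a, b, "normal")
  tab <- table(factor(a == "normal", c(TRUE, FALSE)),
               factor(b == "normal", c(TRUE, FALSE)))
  expect_equal(pk$kappa,
               oracle_kappa_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
               tolerance = 1e-12)

  expect_equal(per_level_kappa(a, a, "mild")$kappa, 1)    # perfect agreement
  const <- rep("normal", 6)
  expect_equal(per_level_kappa(a, const, "normal")$kappa, 0)  # constant rater
  expect_error(per_level_kappa(a, b, "moderate"),
               class = "scaspd_validation_error")          # level absent
})

test_that("ROC anchors: separation, ties, label inversion, score negation", {
  r <- roc_curve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(roc_curve(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), class = "scaspd_validation_error")

  set.seed(13)
  for (i in 1:30) {
    sc <- sample(0:15, 20, TRUE)
    tr <- c(0, 1, rbinom(18, 1, 0.5))
    a <- roc_curve(sc, tr)$auc
    expect_equal(roc_curve(-sc, tr)$auc, 1 - a, tolerance = 1e-12)
    expect_equal(roc_curve(sc, 1 - tr)$auc, 1 - a, tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    rr <- roc_curve(sc, tr)
    expect_true(all(diff(rr$tpr) >= 0) && all(diff(rr$fpr) >= 0))
    expect_equal(c(rr$fpr[1], rr$tpr[1]), c(0, 0))
    expect_equal(c(rev(rr$fpr)[1], rev(rr$tpr)[1]), c(1, 1))
  }
})

test_that("AUC and DeLong variance agree with pROC on a toy set", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- sample(1:30, 40, TRUE)
  tr <- c(0, 1, rbinom(38, 1, 0.45))
  pr <- pROC::roc(tr, sc, quiet = TRUE)
  expect_equal(roc_curve(sc, tr)$auc, as.numeric(pROC::auc(pr)),
               tolerance = 1e-12)
  ci <- auc_ci(sc, tr, "delong")
  pci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(ci$low, ci$high), pci[c(1, 3)], tolerance = 1e-10)
})

test_that("DeLong variance matches the naive structural-components oracle", {
  set.seed(17)
  for (i in 1:25) {
    sc <- sample(0:12, 18, TRUE)
    tr <- c(0, 1, rbinom(16, 1, 0.5))
    d <- scaspd:::delong_components(sc, tr)
    expect_equal(d$var, oracle_delong_var(sc, tr), tolerance = 1e-12)
  }
})

test_that("bootstrap AUC interval is deterministic given the seed and bounded", {
  sc <- c(1, 2, 3, 4, 10, 11, 12, 13)
  tr <- c(0, 0, 0, 0, 1, 1, 1, 1)
  ci1 <- auc_ci(sc, tr, "bootstrap", n_boot = 200, seed = 99)
  ci2 <- auc_ci(sc, tr, "bootstrap", n_boot = 200, seed = 99)
  expect_identical(ci1, ci2)
  expect_equal(ci1$high, 1)              # auc cannot exceed 1
  expect_error(auc_ci(sc, tr, "bootstrap", n_boot = 200),
               class = "scaspd_validation_error")  # seed required
})

test_that("optimal cutoff maximizes Youden's J with the stated tie-breaks", {
  oc <- optimal_cutoff(c(1, 2, 3, 10, 12), c(0, 0, 0, 1, 1))
  expect_equal(oc$cutoff, 3)             # largest score classified negative
  expect_equal(oc$sensitivity, 1)
  expect_equal(oc$specificity, 1)

  set.seed(23)
  for (i in 1:100) {
    sc <- sample(0:20, 25, TRUE)
    tr <- c(0, 1, rbinom(23, 1, 0.5))
    mine <- optimal_cutoff(sc, tr)
    ref <- oracle_cutoff(sc, tr)
    expect_equal(mine$cutoff, ref$cutoff)
    expect_equal(mine$sensitivity, ref$se)
    expect_equal(mine$specificity, ref$sp)
  }
})

test_that("a 16-negative confusion with 2 false positives gives Se 100 / Sp 87.5", {
  scores <- c(rep(30, 15), rep(c(10, 25), c(14, 2)))
  truth <- rep(c(1, 0), c(15, 16))
  perf <- performance_at_cutoff(scores, truth, 19)
  expect_equal(c(perf$tp, perf$fn, perf$tn, perf$fp), c(15, 0, 14, 2))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 0.875)
})
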