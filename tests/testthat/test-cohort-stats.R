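test_that("summary-statistic ANOVA matches aov on the raw data", {
  for (s in 1:3) {
    raw <- withr::with_seed(s, data.frame(
      g = rep(c("a", "b", "c"), times = c(8, 12, 10)),
      y = rnorm(30, rep(c(0, 0.5, 1), times = c(8, 12, 10)), 1)))
    groups <- dplyr::summarise(dplyr::group_by(raw, label = g),
                               n = dplyr::n(), mean = mean(y), sd = sd(y))
    mine <- anova_oneway_from_summary(groups)
    ref <- summary(stats::aov(y ~ g, raw))[[1]]
    expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  for (s in 1:5) {
    g <- withr::with_seed(s, group_summary(
      c("a", "b"), n = sample(5:40, 2), mean = rnorm(2, 10, 3),
      sd = runif(2, 0.5, 4)))
    a <- anova_oneway_from_summary(g)
    t <- t_test_from_summary(g[1, ], g[2, ], variant = "pooled")
    expect_equal(a$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(a$p_value, t$p_value, tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate inputs behave as declared", {
  eq <- group_summary(c("a", "b"), c(10, 10), c(5, 5), c(2, 2))
  res <- anova_oneway_from_summary(eq)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  zero <- group_summary(c("a", "b"), c(5, 5), c(1, 2), c(0, 0))
  expect_warning(res0 <- anova_oneway_from_summary(zero), "zero")
  expect_equal(res0$p_value, 0)
  expect_error(anova_oneway_from_summary(eq[1, ]),
               class = "cytomesf_input_error")
})

test_that("summary t-tests agree with t.test on raw vectors", {
  for (s in 1:3) {
    x <- withr::with_seed(s, rnorm(14, 0, 1))
    y <- withr::with_seed(s + 50, rnorm(9, 0.8, 1.7))
    gx <- list(n = length(x), mean = mean(x), sd = sd(x))
    gy <- list(n = length(y), mean = mean(y), sd = sd(y))
    pooled <- t_test_from_summary(gx, gy, "pooled")
    welch <- t_test_from_summary(gx, gy, "welch")
    expect_equal(pooled$p_value,
                 stats::t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(welch$p_value, stats::t.test(x, y)$p.value,
                 tolerance = 1e-10)
    expect_equal(welch$df, unname(stats::t.test(x, y)$parameter),
                 tolerance = 1e-8)
  }
  g <- list(n = 10, mean = 3, sd = 1.5)
  same <- t_test_from_summary(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("LSD pools the within-group variance over all supplied groups", {
  groups <- group_summary(c("a", "b", "c"), c(12, 8, 10), c(5, 7, 6),
                          c(2, 2.5, 1.8))
  res <- lsd_pairwise_from_summary(groups, "b", "c")
  msw <- sum((groups$n - 1) * groups$sd^2) / (sum(groups$n) - 3)
  t_manual <- (7 - 6) / sqrt(msw * (1 / 8 + 1 / 10))
  expect_equal(res$statistic, t_manual)
  expect_equal(res$df, sum(groups$n) - 3)

  ident <- group_summary(c("a", "b"), c(6, 6), c(4, 4), c(1, 1))
  same <- lsd_pairwise_from_summary(ident, 1, 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lsd_pairwise_from_summary(
    group_summary(c("a", "b"), c(6, 6), c(4, 5), c(0, 0)), 1, 2),
    class = "cytomesf_input_error")
})

test_that("chi-square and Fisher tests match exact references", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  res <- chi_square_test(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  fis <- chi_square_test(matrix(c(3, 1, 1, 3), 2), method = "fisher")
  expect_equal(fis$p_value, 34 / 70, tolerance = 1e-12)

  tab <- matrix(c(45, 20, 25, 25), 2, byrow = TRUE)
  perm <- tab[2:1, 2:1]
  expect_equal(chi_square_test(tab)$statistic,
               chi_square_test(perm)$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)),
               class = "cytomesf_input_error")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)),
               class = "cytomesf_input_error")
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  for (s in 1:20) {
    n <- withr::with_seed(s, sample(10:200, 1))
    scores <- withr::with_seed(s + 100,
                               round(rnorm(n, 0, 2), sample(0:2, 1)))
    labels <- withr::with_seed(s + 200, rbinom(n, 1, 0.4))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_analysis(scores, labels)$auc,
                 auc_pairwise(scores, labels))
  }
})

test_that("AUC complements under score negation in the absence of ties", {
  scores <- withr::with_seed(9, rnorm(150))
  labels <- withr::with_seed(10, rbinom(150, 1, 0.5))
  a1 <- roc_analysis(scores, labels)$auc
  a2 <- roc_analysis(-scores, labels)$auc
  expect_equal(a1 + a2, 1)
})

test_that("ROC agrees with pROC and the Youden rule picks the best cutoff", {
  scores <- withr::with_seed(4, c(rnorm(80, 0), rnorm(60, 1.2)))
  labels <- rep(c(0, 1), c(80, 60))
  mine <- roc_analysis(scores, labels)
  ref <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-12)
  best <- suppressMessages(pROC::coords(ref, "best",
                                        best.method = "youden"))
  expect_equal(mine$sensitivity + mine$specificity - 1,
               best$sensitivity + best$specificity - 1, tolerance = 1e-9)

  perfect <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden, 1)

  expect_error(roc_analysis(1:5, c(1, 1, 1, 1, 1)),
               class = "cytomesf_input_error")
})

test_that("ROC direction '<' ranks low scores as positive", {
  scores <- withr::with_seed(6, c(rnorm(50, 2), rnorm(50, 0)))
  labels <- rep(c(0, 1), each = 50)
  res <- roc_analysis(scores, labels, direction = "<")
  expect_gt(res$auc, 0.8)
})

test_that("logistic fit matches an independent Newton-Raphson oracle", {
  fix <- data.frame(x = c(1, 2, 3, 4, 5, 6, 7, 8),
                    y = c(0, 1, 0, 0, 1, 0, 1, 1))
  fit <- logistic_fit(fix, "y", "x", mode = "univariate")
  beta <- logistic_newton(fix$x, fix$y)
  expect_equal(fit$terms$estimate, beta[2], tolerance = 1e-6)
  expect_equal(fit$terms$or, exp(beta[2]), tolerance = 1e-6)
})

test_that("a null covariate shows no association in a large sample", {
  dat <- withr::with_seed(31, data.frame(
    y = rbinom(400, 1, 0.5), x = rbinom(400, 1, 0.5)))
  fit <- logistic_fit(dat, "y", "x", mode = "univariate")
  expect_gt(fit$terms$p_value, 0.05)
  expect_gt(fit$terms$or, 0.7)
  expect_lt(fit$terms$or, 1.4)
})

test_that("multivariate mode screens covariates by univariate p-value", {
  dat <- withr::with_seed(12, {
    x1 <- rnorm(300)
    x2 <- rnorm(300)
    noise <- rnorm(300)
    y <- rbinom(300, 1, plogis(-0.2 + 1.2 * x1 + 0.8 * x2))
    data.frame(y, x1, x2, noise)
  })
  fit <- logistic_fit(dat, "y", mode = "multivariate")
  expect_setequal(fit$covariates, c("x1", "x2"))
  expect_equal(nrow(fit$terms), 2)
})

test_that("separation is flagged but estimates are still reported", {
  sep <- data.frame(x = c(1, 2, 3, 10, 11, 12), y = c(0, 0, 0, 1, 1, 1))
  expect_warning(fit <- logistic_fit(sep, "y", "x", mode = "univariate"),
                 "converge")
  expect_false(fit$converged)
  expect_equal(nrow(fit$terms), 1)
})
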