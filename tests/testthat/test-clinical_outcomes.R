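test_that("signature scoring is a mean of per-gene z-scores", {
  expr <- matrix(c(1, 2, 3,
                   4, 6, 8,
                   5, 5, 5), 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("S1", "S2", "S3")))
  # single-gene signature: the gene's z-score
  expect_equal(unname(signature_score(expr, "g1")),
               unname((expr["g1", ] - 2) / sd(expr["g1", ])))
  # hand computation for two genes
  z1 <- (expr["g1", ] - mean(expr["g1", ])) / sd(expr["g1", ])
  z2 <- (expr["g2", ] - mean(expr["g2", ])) / sd(expr["g2", ])
  expect_equal(signature_score(expr, c("g1", "g2")), (z1 + z2) / 2)
  # constant gene excluded with a warning
  expect_warning(s <- signature_score(expr, c("g1", "g3")), "zero-variance")
  expect_equal(unname(s), unname(z1))
  expect_error(signature_score(expr, "absent"), "no signature gene")
})

test_that("median dichotomization puts ties in the low group", {
  expect_equal(dichotomize_median(c(-1, -0.5, 0.5, 1)),
               c("low", "low", "high", "high"))
  expect_equal(dichotomize_median(c(1, 2, 3)), c("low", "low", "high"))
  expect_warning(lab <- dichotomize_median(c(2, 2, 2)), "low")
  expect_equal(lab, rep("low", 3))
})

test_that("Cox fit matches a brute-force likelihood grid on 6 subjects", {
  x <- c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1)
  tm <- c(5, 8, 11, 2, 20, 14)
  ev <- c(1, 1, 0, 1, 1, 1)
  fit <- cox_univariate(x, tm, ev)
  # independent oracle: numerically maximize the written-out partial
  # likelihood sum_events [ beta*x_i - log sum_{j: t_j >= t_i} exp(beta*x_j) ]
  pl <- function(beta) {
    sum(vapply(which(ev == 1), function(i) {
      risk <- tm >= tm[i]
      beta * x[i] - log(sum(exp(beta * x[risk])))
    }, 0))
  }
  opt <- optimize(pl, c(-10, 10), maximum = TRUE)
  expect_equal(fit$beta, opt$maximum, tolerance = 1e-4)
  expect_true(fit$converged && !fit$flagged)
  expect_true(fit$ci95_low <= fit$hr && fit$hr <= fit$ci95_high)
})

test_that("Cox fit agrees with survival::coxph including ties", {
  skip_if_not_installed("survival")
  set.seed(15)
  for (i in 1:10) {
    n <- 50
    x <- rnorm(n)
    tm <- ceiling(rexp(n, exp(0.3 * x)) * 6)  # discretized: ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) next
    for (tie in c("efron", "breslow")) {
      fit <- cox_univariate(x, tm, ev, ties = tie)
      m <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = tie)
      expect_equal(fit$beta, unname(coef(m)), tolerance = 1e-6)
      expect_equal(fit$se, sqrt(unname(m$var[1, 1])), tolerance = 1e-6)
    }
  }
})

test_that("Cox z and p are invariant under affine covariate rescaling", {
  set.seed(16)
  x <- rnorm(80); tm <- rexp(80, exp(0.4 * x)); ev <- rbinom(80, 1, 0.8)
  f1 <- cox_univariate(x, tm, ev)
  f2 <- cox_univariate(10 * x + 3, tm, ev)
  expect_equal(f1$z, f2$z, tolerance = 1e-6)
  expect_equal(f1$p, f2$p, tolerance = 1e-6)
  expect_equal(f1$beta, 10 * f2$beta, tolerance = 1e-6)
  expect_error(cox_univariate(rep(1, 80), tm, ev), "constant")
  expect_error(cox_univariate(x, tm, rep(0, 80)), "2 events")
})

test_that("log-rank matches hand computation and survdiff", {
  # identical groups duplicated: no difference
  lr0 <- logrank_test(rep(c("a", "b"), each = 3),
                      rep(c(3, 6, 9), 2), rep(c(1, 1, 0), 2))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)
  # hand-worked 6-subject table
  labels <- c("a", "a", "a", "b", "b", "b")
  tm <- c(1, 3, 5, 2, 4, 6); ev <- c(1, 1, 1, 1, 0, 1)
  lr <- logrank_test(labels, tm, ev)
  # manual O-E and variance per event time (t = 1,2,3,5,6)
  # t=1: n=6 n_a=3 -> E 0.5 V .25; t=2: n=5 n_a=2 E .4 V .24
  # t=3: n=4 n_a=2 E .5 V .25; t=5: n=2 n_a=1 E .5 V .25; t=6: n=1 n_a=0
  O <- 3; E <- 0.5 + 0.4 + 0.5 + 0.5 + 0
  V <- 0.25 + 0.24 + 0.25 + 0.25 + 0
  expect_equal(lr$chi2, (O - E)^2 / V)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ labels)
  expect_equal(lr$chi2, unname(sd$chisq), tolerance = 1e-9)
  expect_error(logrank_test(rep("a", 6), tm, ev), "two groups")
})

test_that("concordance calls need k significant cohorts with one sign", {
  fits <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 3),
                     cohort_id = rep(c("c1", "c2", "c3"), 3),
                     beta = c(1, 1, -1,   1, 1, 1,   1, -1, 1),
                     p = c(0.01, 0.03, 0.4,  0.01, 0.2, 0.3,  0.01, 0.01, 0.9))
  calls <- concordance_call(fits)
  expect_equal(calls$reproducible[calls$gene == "g1"], TRUE)
  expect_equal(calls$reproducible[calls$gene == "g2"], FALSE) # one cohort
  expect_equal(calls$reproducible[calls$gene == "g3"], FALSE) # sign clash
  expect_equal(calls$direction[calls$gene == "g1"], 1)
  # monotone in alpha: lowering alpha never adds reproducible genes
  n_rep <- vapply(c(0.05, 0.02, 0.005), function(a)
    sum(concordance_call(fits, alpha = a)$reproducible), 0L)
  expect_true(all(diff(n_rep) <= 0))
  # flagged fits never count
  fits$flagged <- c(TRUE, FALSE, FALSE, rep(FALSE, 6))
  expect_equal(concordance_call(fits)$reproducible[1], FALSE)
})

test_that("Mann-Whitney differential expression is exact on small groups", {
  a <- matrix(c(1, 2, 3), 1, dimnames = list("g", NULL))
  b <- matrix(c(4, 5, 6), 1, dimnames = list("g", NULL))
  de <- diff_expression(a, b)
  expect_equal(de$p, 0.1)  # 2 * 1/20 over C(6,3) arrangements
  expect_equal(de$direction, "up")
  expect_true(!de$significant)
  # identical groups: p = 1
  de2 <- diff_expression(a, a)
  expect_equal(de2$p, 1)
  expect_equal(de2$direction, "none")
  # oracle: exact wilcox.test on random untied samples
  set.seed(17)
  for (i in 1:10) {
    av <- matrix(rnorm(6), 1, dimnames = list("g", NULL))
    bv <- matrix(rnorm(7), 1, dimnames = list("g", NULL))
    de3 <- diff_expression(av, bv)
    expect_equal(de3$p, wilcox.test(av[1, ], bv[1, ], exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("exact and approximate Mann-Whitney agree at size (8, 8)", {
  set.seed(18)
  for (i in 1:10) {
    av <- matrix(rnorm(8), 1, dimnames = list("g", NULL))
    bv <- matrix(rnorm(8) + 0.5, 1, dimnames = list("g", NULL))
    p_exact <- diff_expression(av, bv, exact_max = 8)$p
    p_norm <- diff_expression(av, bv, exact_max = 0)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("fold-change summary rounds half-up", {
  expect_equal(fold_change_summary(1.073, 0.5975), 1.8)
  expect_equal(fold_change_summary(1.286, 0.8540), 1.5)
  expect_equal(fold_change_summary(3.14, 3.14), 1.0)
  expect_equal(fold_change_summary(0.25, 1), 0.3)  # half-up, not banker's
  expect_error(fold_change_summary(1, 0), "positive")
})

test_that("Pearson correlation matches the product-moment formula", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  x <- c(1, 3, 2, 5, 4); y <- c(2, 1, 4, 3, 5)
  expect_equal(pearson_correlation(x, y), cor(x, y))
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})
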