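test_that("midrank AUC equals the all-pairs oracle, ties included", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)  # all ties
  set.seed(42)
  for (i in 1:30) {
    n <- sample(10:150, 1)
    score <- sample(1:20, n, replace = TRUE)  # heavy ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    r <- roc_auc(score, pos)
    expect_equal(r$auc, auc_pairs_oracle(score, pos), tolerance = 1e-12)
    # curve area equals the AUC (trapezoid over the tie diagonals)
    cv <- r$curve
    area <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(area, r$auc, tolerance = 1e-10)
    expect_equal(cv[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(cv[nrow(cv), ], use.names = FALSE), c(1, 1))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong test: self-comparison null, consistency with roc_auc", {
  set.seed(7)
  s <- rnorm(60); lab <- runif(60) < 0.5
  dl <- delong_test(s, s, lab)
  expect_equal(dl$z, 0)
  expect_equal(dl$p_value, 1)
  s2 <- rnorm(60)
  dl2 <- delong_test(s, s2, lab)
  expect_equal(dl2$auc_a, roc_auc(s, lab)$auc)
  expect_equal(dl2$auc_b, roc_auc(s2, lab)$auc)
  expect_true(dl2$p_value >= 0 && dl2$p_value <= 1)
  expect_error(delong_test(s, s2[-1], lab), "paired")
  expect_error(delong_test(s, s2, c(TRUE, rep(FALSE, 59))), ">= 2")
})

test_that("DeLong variance agrees with a stratified bootstrap", {
  set.seed(123)
  n <- 100
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  score <- rnorm(n, mean = ifelse(lab, 1, 0))
  v_delong <- roc_auc(score, lab)$variance
  ip <- which(lab); ineg <- which(!lab)
  boot <- replicate(2000, {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    auc_pairs_oracle(score[idx], lab[idx])
  })
  expect_lt(abs(v_delong - var(boot)) / var(boot), 0.10)
})

test_that("Fisher p equals hypergeometric enumeration", {
  r <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, fisher_enum_oracle(tab),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("rank tests: Wilcoxon for 2 groups, Kruskal-Wallis beyond", {
  x <- c(1:10, 1:10); g <- rep(c("a", "b"), each = 10)
  r <- rank_tests(x, g)
  expect_identical(r$test, "wilcoxon")
  expect_equal(r$p_value, 1, tolerance = 1e-12)   # identical groups, z = 0
  # full separation: W at its maximum (all 100 pairs won)
  r2 <- rank_tests(c(1:10, 101:110), g)
  expect_equal(unname(r2$statistic), 0)   # first group loses every pair
  r3 <- rank_tests(c(101:110, 1:10), g)
  expect_equal(unname(r3$statistic), 100)
  # KW on 2 groups ~ squared Wilcoxon z
  set.seed(1)
  y <- rnorm(40); h <- rep(c("a", "b"), 20)
  kw <- kruskal.test(y, factor(h))
  wz <- qnorm(rank_tests(y, h)$p_value / 2)
  expect_equal(unname(kw$statistic), wz^2, tolerance = 1e-6)
  r4 <- rank_tests(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_identical(r4$test, "kruskal-wallis")
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  # step-up by hand: p_(i) * m / i, cumulative min from the top
  hand <- rev(cummin(rev(p * 5 / seq_len(5))))
  expect_equal(bh_adjust(p), pmin(hand, 1))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("logistic fit recovers parameters and flags separation", {
  fit0 <- logistic_fit(matrix(nrow = 40, ncol = 0), rep(c(0, 1), 20))
  expect_equal(fit0$coefficients$estimate[1], 0, tolerance = 1e-8)
  set.seed(2)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 2 * x))
  fit <- logistic_fit(cbind(x = x), y)
  est <- fit$coefficients
  expect_true(abs(est$estimate[1] - (-1)) < 3 * est$se[1])
  expect_true(abs(est$estimate[2] - 2) < 3 * est$se[2])
  # scaling equivariance
  fit2 <- logistic_fit(cbind(x = 2 * x), y)
  expect_equal(fit2$coefficients$estimate[2], est$estimate[2] / 2,
               tolerance = 1e-6)
  # complete separation
  xs <- c(rnorm(20, -3), rnorm(20, 3)); ys <- rep(c(0, 1), each = 20)
  expect_warning(fs <- logistic_fit(cbind(x = xs), ys),
                 class = "tsescore_separation")
  expect_true(fs$separation)
  expect_error(logistic_fit(cbind(a = 1:10, b = 2 * (1:10)), rep(c(0, 1), 5)),
               "rank")
})

test_that("KM equals the empirical survivor function without censoring", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2, 1, 0) / 3)
  set.seed(4)
  t <- rexp(50)
  km2 <- km_fit(t, rep(1, 50))
  emp <- vapply(km2$time, function(u) mean(t > u), 0)
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))
  expect_error(km_fit(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank and Cox behave on identical and planted-effect data", {
  t <- rep(c(1, 2, 3, 4), 2); e <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_gt(lr$p_value, 0.99)
  set.seed(6)
  n <- 2000
  z <- rep(c(0, 1), each = n / 2)
  tt <- rexp(n, 0.1 * 2^z)
  cc <- rexp(n, 0.03)
  fit <- cox_fit(pmin(tt, cc), as.numeric(tt <= cc), data.frame(z = z))
  expect_true(abs(fit$coef - log(2)) < 3 * fit$se)
  expect_true(fit$hr_lower < fit$hr & fit$hr < fit$hr_upper)
})

test_that("null log-rank and DeLong p-values are approximately uniform", {
  set.seed(8)
  p_lr <- replicate(300, {
    t <- rexp(40); e <- rbinom(40, 1, 0.8); g <- rep(c("a", "b"), 20)
    logrank_test(t, e, g)$p_value
  })
  expect_gt(ks.test(p_lr, "punif")$p.value, 0.01)
  p_dl <- replicate(300, {
    s1 <- rnorm(40); s2 <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
    delong_test(s1, s2, lab)$p_value
  })
  # discrete AUC values can tie; ks.test's tie warning is immaterial here
  expect_gt(suppressWarnings(ks.test(p_dl, "punif"))$p.value, 0.01)
})
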