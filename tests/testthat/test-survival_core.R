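test_that("fit_cox recovers a known log hazard ratio", {
  d <- make_two_group_data(n = 2000, log_hr = 0.8, seed = 7)
  fit <- fit_cox(d$x, d$time, d$event)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[[1]] - 0.8), 0.1)
  expect_lt(fit$score_max, 1e-8)
})

test_that("a constant-zero covariate yields beta 0 and the null likelihood", {
  d <- make_two_group_data(n = 80, log_hr = 0, seed = 2)
  fit <- fit_cox(rep(0, 80), d$time, d$event)
  expect_equal(fit$coefficients[[1]], 0)
  expect_equal(fit$log_likelihood, fit$null_log_likelihood)
})

test_that("fit_cox agrees with a generic optimizer of the partial likelihood", {
  withr::with_seed(11, {
    n <- 30
    X <- cbind(rnorm(n), rnorm(n))
    time <- round(rexp(n), 6) + runif(n, 0, 1e-3)  # no ties
    event <- rbinom(n, 1, 0.7)
    event[1] <- 1L
  })
  fit <- fit_cox(X, time, event, tol_score = 1e-12)
  opt <- optim(c(0, 0), function(b) -naive_cox_pll(b, X, time, event),
               method = "BFGS", control = list(reltol = 1e-16, maxit = 1000))
  expect_lt(max(abs(fit$coefficients - opt$par)), 1e-6)
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-10)
})

test_that("both tie conventions match the survival package", {
  withr::with_seed(3, {
    n <- 120
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    time <- sample(1:20, n, replace = TRUE) + 0  # heavy ties
    event <- rbinom(n, 1, 0.6)
  })
  for (tie in c("breslow", "efron")) {
    fit <- fit_cox(X, time, event, ties = tie)
    ref <- survival::coxph(survival::Surv(time, event) ~ X, ties = tie)
    expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-8)
    expect_lt(max(abs(fit$standard_errors - sqrt(diag(vcov(ref))))), 1e-8)
    expect_equal(fit$log_likelihood, ref$loglik[2], tolerance = 1e-10)
  }
})

test_that("ridge penalty shrinks coefficients monotonically toward zero", {
  d <- make_two_group_data(n = 300, log_hr = 1.2, seed = 5)
  X <- cbind(d$x, withr::with_seed(6, rnorm(300)))
  norms <- vapply(c(0, 1, 10, 100, 10000), function(l)
    sqrt(sum(fit_cox(X, d$time, d$event, ridge_lambda = l)$coefficients^2)),
    numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 0.01)
})

test_that("wald_test computes two-sided normal p-values", {
  d <- make_two_group_data(n = 400, log_hr = 1.5, seed = 8)
  fit <- fit_cox(d$x, d$time, d$event)
  wt <- wald_test(fit)
  expect_equal(wt$z, fit$coefficients / fit$standard_errors, ignore_attr = TRUE)
  expect_equal(wt$p, 2 * pnorm(-abs(wt$z)), ignore_attr = TRUE)
  expect_lt(wt$p[1], 0.001)
  fit$converged <- FALSE
  expect_error(wald_test(fit), "converge")
})

test_that("linear_predictor is X beta with no centering", {
  fit <- structure(list(coefficients = c(a = 1, b = -1)), class = "cox_fit")
  expect_equal(linear_predictor(fit, matrix(c(2, 3), 1)), -1)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(linear_predictor(fit, X), drop(X %*% c(1, -1)))
  # shifting one column shifts every score by beta_k * const
  Xs <- X
  Xs[, 2] <- Xs[, 2] + 10
  expect_equal(linear_predictor(fit, Xs), linear_predictor(fit, X) - 10)
  expect_error(linear_predictor(fit, matrix(1, 2, 3)), "columns")
})

test_that("concordance handles perfect ranking, constant risk, and ties", {
  time <- c(5, 3, 9, 1, 7)
  event <- rep(1L, 5)
  expect_equal(concordance_index(time, event, -time), 1)
  expect_equal(concordance_index(time, event, rep(2, 5)), 0.5)
  expect_error(concordance_index(c(1, 1), c(1, 1), c(1, 2)), "comparable")
})

test_that("concordance matches exhaustive enumeration on random instances", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      inst <- random_survival_instance(sample(4:20, 1))
      ok <- tryCatch(exhaustive_cindex(inst$time, inst$event, inst$risk),
                     error = function(e) NULL)
      if (is.null(ok)) next
      expect_identical(concordance_index(inst$time, inst$event, inst$risk), ok)
    }
  })
})

test_that("complementary risks give complementary concordance", {
  withr::with_seed(31, {
    time <- rexp(40) + 0.01
    event <- rbinom(40, 1, 0.6)
    event[1] <- 1L
    risk <- rnorm(40)  # continuous: no risk ties
  })
  expect_equal(concordance_index(time, event, risk) +
               concordance_index(time, event, -risk), 1)
})

test_that("Kaplan-Meier matches hand computations", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  km_cens <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km_cens$survival, c(1, 1, 1))
  # 6 samples, mixed censoring, worked out by hand
  km6 <- kaplan_meier(c(1, 2, 3, 4, 4, 5), c(1, 0, 1, 1, 1, 0))
  expect_equal(km6$time, c(1, 2, 3, 4, 5))
  expect_equal(km6$survival, c(5 / 6, 5 / 6, 5 / 8, 5 / 24, 5 / 24))
})

test_that("Kaplan-Meier is a nonincreasing step function in [0,1] agreeing with survfit", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      inst <- random_survival_instance(30)
      km <- kaplan_meier(inst$time, inst$event)
      expect_true(all(diff(km$survival) <= 1e-12))
      expect_true(all(km$survival >= 0 & km$survival <= 1))
      sf <- survival::survfit(survival::Surv(inst$time, inst$event) ~ 1)
      expect_equal(km$survival[km$time %in% sf$time], sf$surv, tolerance = 1e-12)
    }
  })
})

test_that("log-rank is zero for identical groups and detects separation", {
  t1 <- c(1, 2, 3, 4, 5)
  e1 <- c(1, 0, 1, 1, 0)
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  d <- withr::with_seed(51, {
    ta <- -log(runif(100)) / 0.1
    tb <- -log(runif(100)) / 0.3
    list(ta = ta, tb = tb)
  })
  strong <- logrank_test(d$ta, rep(1, 100), d$tb, rep(1, 100))
  expect_lt(strong$p.value, 0.001)
  expect_error(logrank_test(numeric(0), integer(0), t1, e1), "nonempty")
})

test_that("log-rank matches survdiff and is calibrated under the null", {
  withr::with_seed(61, {
    for (rep in 1:10) {
      ia <- random_survival_instance(25)
      ib <- random_survival_instance(20)
      ours <- logrank_test(ia$time, ia$event, ib$time, ib$event)
      ref <- survival::survdiff(
        survival::Surv(c(ia$time, ib$time), c(ia$event, ib$event)) ~
          rep(1:2, c(25, 20)))
      expect_equal(ours$statistic, ref$chisq, tolerance = 1e-8)
    }
    # permutation null: p-values approximately uniform
    tt <- rexp(60) + 0.01
    ee <- rbinom(60, 1, 0.7)
    ps <- replicate(500, {
      g <- sample(rep(c(TRUE, FALSE), 30))
      logrank_test(tt[g], ee[g], tt[!g], ee[!g])$p.value
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("rank-sum test matches the stats implementation and the exact null", {
  expect_equal(wilcoxon_ranksum(1:5, 1:5)$p.value, 1)
  extreme <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(extreme$statistic, 0)
  withr::with_seed(71, {
    for (rep in 1:20) {
      a <- sample(1:8, sample(3:10, 1), replace = TRUE)
      b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
      ours <- wilcoxon_ranksum(a, b)
      ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
    # normal approximation close to exhaustive enumeration at small n
    for (rep in 1:5) {
      a <- rnorm(5)
      b <- rnorm(4, 0.5)
      expect_lt(abs(wilcoxon_ranksum(a, b)$p.value - exact_ranksum_p(a, b)), 0.08)
    }
  })
})

test_that("signed-rank test handles identical pairs and matches stats", {
  expect_equal(wilcoxon_signedrank(1:6, 1:6)$p.value, 1)
  withr::with_seed(81, {
    for (rep in 1:10) {
      a <- rnorm(15)
      b <- a + rnorm(15, 0.3)
      ours <- wilcoxon_signedrank(a, b)
      ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                 exact = FALSE, correct = TRUE))
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("pearson correlation handles exact linearity and matches cor", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -2 * x + 5), -1)
  withr::with_seed(91, {
    for (rep in 1:10) {
      a <- rnorm(20)
      b <- rnorm(20)
      expect_equal(pearson_correlation(a, b), cor(a, b), tolerance = 1e-12)
    }
  })
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
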