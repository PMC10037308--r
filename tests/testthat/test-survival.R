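test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median_survival, 2)

  kmC <- kmCurve(c(5, 6, 7), c(0, 0, 0))
  expect_equal(length(kmC$event_times), 0L)
  expect_true(is.na(kmC$median_survival))

  # events at 1, 3, 4; censorings at 2 and 5
  km5 <- kmCurve(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(km5$event_times, c(1, 3, 4))
  expect_equal(km5$survival, c(0.8, 0.8 * 2 / 3, 0.8 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
})

test_that("log-rank is null on identical groups and powered under HR 3", {
  tt <- rep(c(1, 2, 3, 4), 2); ev <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank(tt, ev, grp)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank(tt, ev, rep("a", 8)), "2 groups")

  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    t2 <- c(stats::rexp(100, 1e-3), stats::rexp(100, 3e-3))
    if (logrank(t2, rep(1, 200), rep(c("lo", "hi"), each = 100))$p < 0.001)
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("merging duplicate groups reduces the 3-group test to the 2-group one", {
  set.seed(3)
  tt <- stats::rexp(90, c(1e-3, 2e-3))
  ev <- rbinom(90, 1, 0.8)
  g3 <- rep(c("a", "b1", "b2"), each = 30)
  g2 <- ifelse(g3 == "a", "a", "b")
  # b1/b2 duplicated population: pooled statistic must be close
  lr3 <- logrank(tt, ev, g3)
  lr2 <- logrank(tt, ev, g2)
  expect_equal(lr3$df, 2L)
  expect_equal(lr2$df, 1L)
  expect_gte(lr3$chi2, lr2$chi2 - 1e-9)  # 2-group contrast nested in 3-group
})

test_that("Cox recovers a known hazard ratio and scales under duplication", {
  set.seed(5)
  x <- rep(c(0, 1), each = 250)
  tt <- stats::rexp(500, 1e-3 * exp(log(2) * x))
  fit <- coxFit(cbind(trt = x), tt, rep(1, 500))
  expect_lt(abs(fit$beta - log(2)), 0.3)
  expect_equal(fit$hr, exp(fit$beta))
  expect_equal(fit$ci95_lo, exp(fit$beta - 1.96 * fit$se))

  dup <- coxFit(cbind(trt = rep(x, 2)), rep(tt, 2), rep(1, 1000))
  expect_lt(abs(dup$beta - fit$beta), 0.05)
  expect_lt(dup$se, fit$se)
  expect_equal(dup$se, fit$se / sqrt(2), tolerance = 0.1)
  expect_error(coxFit(cbind(rep(1, 10)), stats::rexp(10), rep(1, 10)),
               "constant")
})

test_that("risk model orders samples by expression for a single hazardous gene", {
  set.seed(7)
  n <- 120
  expr <- matrix(stats::rnorm(3 * n), 3, n,
                 dimnames = list(c("gA", "gB", "gC"), sprintf("p%03d", 1:n)))
  tt <- stats::rexp(n, 1e-3 * exp(1.2 * expr["gA", ]))
  cl <- surv_clinical(tt, rep(1, n), colnames(expr))
  rm1 <- riskModel(expr, "gA", cl)
  expect_equal(order(rm1$risk), order(expr["gA", ] * sign(rm1$fit$beta)))
  expect_lte(abs(sum(rm1$group == "high") - sum(rm1$group == "low")), 1)

  rm3 <- riskModel(expr, c("gA", "gB", "gC"), cl)
  expect_lt(rm3$logrank$p, 0.01)
})

test_that("time-dependent AUC hits its analytic anchors", {
  set.seed(9)
  n <- 200
  tt <- stats::rexp(n, 1e-3)
  cl <- surv_clinical(tt, rep(1, n))
  risk <- stats::setNames(-tt, cl$sample_id)  # perfect ranking
  a <- tdAuc(risk, cl, horizons = stats::median(tt))
  expect_equal(unname(a), 1)

  # symmetry: anti-predictive risk mirrors around 0.5
  r2 <- stats::setNames(stats::rnorm(n), cl$sample_id)
  h <- stats::quantile(tt, 0.5)
  expect_equal(unname(tdAuc(r2, cl, h) + tdAuc(-r2, cl, h)), 1,
               tolerance = 1e-10)
  expect_warning(tdAuc(r2, cl, max(tt) + 1), "beyond")
})

test_that("AUC of an uninformative risk concentrates at one half", {
  aucs <- numeric(30)
  for (s in 1:30) {
    set.seed(s + 90)
    n <- 500
    tt <- stats::rexp(n, 1e-3)
    ev <- as.integer(tt < stats::rexp(n, 4e-4))
    cl <- surv_clinical(pmin(tt, 4000), ev)
    aucs[s] <- tdAuc(stats::setNames(stats::rnorm(n), cl$sample_id), cl,
                     stats::quantile(tt, 0.4))
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  expect_true(all(abs(aucs - 0.5) < 0.08))
})

test_that("optimalCutoff scans only floor-respecting candidates", {
  set.seed(11)
  score <- stats::setNames(1:20 + 0, sprintf("p%03d", 1:20))
  cl <- surv_clinical(stats::rexp(20, 1e-3), rep(1, 20), names(score))
  res <- optimalCutoff(score, cl, floor = 0.4, nPerm = 0)
  # both sides >= 8 of 20: cutoffs must lie in the middle 20% of scores
  expect_true(all(res$candidates >= 8 & res$candidates <= 12))
  expect_error(optimalCutoff(rep(1, 20), cl), "identical")
})

test_that("optimalCutoff recovers a planted hazard boundary", {
  hit <- 0
  for (s in 1:10) {
    set.seed(s + 200)
    n <- 150
    score <- stats::setNames(sort(stats::runif(n, 0, 10)), sprintf("p%03d", 1:n))
    grp <- score > 5
    tt <- stats::rexp(n, ifelse(grp, 5e-3, 5e-4))
    cl <- surv_clinical(tt, rep(1, n), names(score))
    res <- optimalCutoff(score, cl, nPerm = 0)
    if (abs(res$cutoff - 5) < 1) hit <- hit + 1
  }
  expect_gte(hit, 9)
})

test_that("the maximal chi-square equals the exported log-rank at the chosen cutoff", {
  set.seed(13)
  n <- 80
  score <- stats::setNames(stats::rnorm(n), sprintf("p%03d", 1:n))
  tt <- stats::rexp(n, 1e-3 * exp(0.5 * score))
  cl <- surv_clinical(tt, rbinom(n, 1, 0.8), names(score))
  res <- optimalCutoff(score, cl, nPerm = 0)
  lr <- logrank(cl$os_time, cl$os_event, score > res$cutoff)
  expect_equal(res$chi2, lr$chi2, tolerance = 1e-8)
})

test_that("selection-adjusted permutation p is calibrated under the null", {
  hits <- 0
  for (s in 1:60) {
    set.seed(s + 300)
    n <- 40
    score <- stats::setNames(stats::rnorm(n), sprintf("p%02d", 1:n))
    cl <- surv_clinical(stats::rexp(n, 1e-3), rep(1, n), names(score))
    res <- optimalCutoff(score, cl, nPerm = 99, seed = s)
    if (res$perm_p < 0.05) hits <- hits + 1
  }
  # ~5% of 60; binomial 99% band
  expect_lte(hits, 9)
})

test_that("null Cox Wald p-values are uniform", {
  ps <- numeric(100)
  for (s in 1:100) {
    set.seed(s + 700)
    x <- stats::rnorm(80)
    tt <- stats::rexp(80, 1e-3)
    ps[s] <- coxFit(cbind(x = x), tt, rep(1, 80))$wald_p
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
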