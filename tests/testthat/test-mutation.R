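test_that("TMB counts only non-silent classes and zero-fills absent samples", {
  maf <- data.frame(
    Tumor_Sample_Barcode = c(rep("s1", 4), "s2"),
    Hugo_Symbol = c("A", "B", "C", "D", "E"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Silent", "Intron"))
  tmb <- computeTmb(maf, c("s1", "s2", "s3"))
  expect_equal(tmb, c(s1 = 3L, s2 = 0L, s3 = 0L))
})

test_that("simulated TMB hits its Poisson mean", {
  ids <- sprintf("p%03d", 1:300)
  set.seed(1)
  maf <- simulateMaf(ids, stats::rnorm(300), tmbSlope = 0, seed = 2)
  expect_lt(abs(mean(computeTmb(maf, ids)) - 10), 0.6)
})

test_that("Yates chi-square matches its degenerate anchors and Fisher sanity band", {
  flat <- yatesChisq(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  expect_error(yatesChisq(matrix(c(0, 0, 5, 7), 2, 2, byrow = TRUE)), "margin")

  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(stats::rpois(4, 7) + 1, 2, 2)
    p <- yatesChisq(tab)$p
    pf <- stats::fisher.test(tab)$p.value
    expect_lt(p, pf * 3 + 1e-12)
    expect_gt(p, pf / 3 - 1e-12)
  }
})

test_that("mutation contingency tables reproduce printed-style counts exactly", {
  fx <- contingency_maf("CHD6", highMut = 10, lowMut = 7, highN = 69, lowN = 217)
  tab <- mutatedGeneTable(fx$maf, fx$groups, topN = 5)
  row <- tab[tab$gene == "CHD6", ]
  expect_equal(row$high_wild, 59)
  expect_equal(row$high_mut, 10)
  expect_equal(row$low_wild, 210)
  expect_equal(row$low_mut, 7)
  expect_equal(row$high_pct, 100 * 10 / 69, tolerance = 1e-12)
  expect_equal(signif(row$p, 4), 0.001602)
})

test_that("a gene mutated in every sample shows no group association", {
  ids <- c(paste0("H", 1:5), paste0("L", 1:5))
  groups <- stats::setNames(rep(c("high", "low"), each = 5), ids)
  maf <- data.frame(Tumor_Sample_Barcode = ids, Hugo_Symbol = "EVERY",
                    Variant_Classification = "Missense_Mutation")
  tab <- mutatedGeneTable(maf, groups, topN = 3)
  expect_equal(tab$chi2[tab$gene == "EVERY"], 0)
  expect_equal(tab$p[tab$gene == "EVERY"], 1)
})

test_that("a planted group-biased gene ranks first by p", {
  first <- 0
  for (s in 1:15) {
    set.seed(s)
    score <- stats::rnorm(300)
    ids <- sprintf("p%03d", 1:300)
    maf <- simulateMaf(ids, score, tmbSlope = 0, biasOdds = 8, seed = s)
    groups <- stats::setNames(ifelse(score > stats::median(score), "high", "low"), ids)
    tab <- mutatedGeneTable(maf, groups)
    if (tab$gene[1] %in% c("MUT001", "MUT002", "MUT003")) first <- first + 1
  }
  expect_gte(first, 13)
})

test_that("group sizes are constant across genes and percentages exact", {
  set.seed(9)
  ids <- sprintf("p%03d", 1:100)
  score <- stats::rnorm(100)
  maf <- simulateMaf(ids, score, seed = 10)
  groups <- stats::setNames(ifelse(score > 0, "high", "low"), ids)
  tab <- mutatedGeneTable(maf, groups, topN = 10)
  expect_true(all(tab$high_wild + tab$high_mut == sum(groups == "high")))
  expect_true(all(tab$low_wild + tab$low_mut == sum(groups == "low")))
  expect_equal(tab$high_pct, 100 * tab$high_mut / sum(groups == "high"))
})

test_that("Spearman association obeys its rank anchors", {
  x <- c(1, 4, 9, 16, 25, 36, 49, 64, 81, 100)
  mono <- tmbScoreAssociation(x, sqrt(x))
  expect_equal(mono$rho, 1)
  set.seed(11)
  a <- stats::rnorm(50); b <- stats::rpois(50, 8)
  expect_equal(tmbScoreAssociation(b, a)$rho,
               tmbScoreAssociation(rank(b), rank(a))$rho, tolerance = 1e-12)
  expect_error(tmbScoreAssociation(rep(1, 10), stats::rnorm(10)), "constant")
})

test_that("independent TMB and score show near-zero correlation", {
  ok <- 0
  for (s in 1:40) {
    set.seed(s + 20)
    if (abs(tmbScoreAssociation(stats::rpois(300, 10), stats::rnorm(300))$rho) < 0.15)
      ok <- ok + 1
  }
  expect_gte(ok, 38)
})

test_that("TMB-by-ICI strata behave under planted and degenerate inputs", {
  set.seed(13)
  n <- 200
  ids <- sprintf("p%03d", 1:n)
  ici <- stats::setNames(rep(c("high", "low"), each = n / 2), ids)
  tmb <- stats::setNames(stats::rpois(n, 10), ids)

  # only the ICI axis drives hazard
  tt <- stats::rexp(n, ifelse(ici == "high", 5e-4, 2e-3))
  cl <- surv_clinical(tt, rep(1, n), ids)
  res <- tmbIciStrata(tmb, ici, cl)
  expect_equal(res$logrank$df, 3L)
  expect_lt(res$logrank$p, 0.01)

  # all TMB equal: only two strata remain
  flat <- stats::setNames(rep(5, n), ids)
  expect_warning(res2 <- tmbIciStrata(flat, ici, cl), "empty stratum")
  expect_equal(res2$logrank$df, 1L)

  # both axes prognostic: ordered median survival across strata
  ordered <- 0
  for (s in 1:15) {
    set.seed(s + 40)
    tmb2 <- stats::setNames(stats::rpois(n, 10), ids)
    haz <- 2e-3 * ifelse(ici == "high", 0.3, 1) * ifelse(tmb2 > 10, 0.5, 1)
    tt2 <- stats::rexp(n, haz)
    cl2 <- surv_clinical(tt2, rep(1, n), ids)
    st <- tmbIciStrata(tmb2, ici, cl2)
    med <- sapply(split(seq_len(n), st$strata), function(i)
      kmCurve(tt2[i], rep(1, length(i)))$median_survival)
    best <- med["highTMB/highICI"]; worst <- med["lowTMB/lowICI"]
    if (!anyNA(c(best, worst)) && best > worst) ordered <- ordered + 1
  }
  expect_gte(ordered, 12)
})
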