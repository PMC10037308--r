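sim_two_group <- function(nGenes = 100, n0 = 5, n1 = 5, delta = 0, nDe = 0,
                          seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(nGenes * (n0 + n1)), nGenes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n0 + n1))))
  if (nDe > 0) x[seq_len(nDe), seq_len(n1) + n0] <- x[seq_len(nDe), seq_len(n1) + n0] + delta
  list(x = x, group = rep(c(0, 1), c(n0, n1)))
}

test_that("with shrinkage disabled the moderated t is the pooled t-test", {
  d <- sim_two_group(50, 6, 7, seed = 2)
  de <- moderatedT(d$x, d$group, shrink = FALSE)
  for (i in c(1, 17, 50)) {
    tt <- stats::t.test(d$x[i, d$group == 1], d$x[i, d$group == 0],
                        var.equal = TRUE)
    expect_equal(de$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("equal gene variances make moderated and ordinary t coincide", {
  d <- sim_two_group(40, 5, 5, seed = 3)
  # force identical pooled variances by scaling each gene's residuals
  x <- d$x
  g1 <- d$group == 1
  for (i in seq_len(nrow(x))) {
    m0 <- mean(x[i, !g1]); m1 <- mean(x[i, g1])
    r <- x[i, ] - ifelse(g1, m1, m0)
    s <- sqrt(sum(r^2) / 8)
    x[i, ] <- ifelse(g1, m1, m0) + r / s
  }
  mod <- moderatedT(x, d$group, shrink = TRUE)
  ord <- moderatedT(x, d$group, shrink = FALSE)
  expect_equal(mod$t_stat, ord$t_stat, tolerance = 1e-8)
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  d <- sim_two_group(200, 8, 8, delta = 1.5, nDe = 20, seed = 5)
  # heterogeneous true variances so the prior df is finite
  set.seed(6)
  d$x <- d$x * sqrt(stats::rgamma(200, 2, 2))
  de <- moderatedT(d$x, d$group)
  expect_true(is.finite(attr(de, "prior")$d0))
  design <- cbind(1, d$group)
  fit <- limma::eBayes(limma::lmFit(d$x, design))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(de$t_stat, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("swapping group labels negates the statistic but keeps p", {
  d <- sim_two_group(60, 5, 6, delta = 1, nDe = 10, seed = 7)
  de1 <- moderatedT(d$x, factor(d$group, levels = c(0, 1)))
  de2 <- moderatedT(d$x, factor(d$group, levels = c(1, 0)))
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$t_stat, -de2$t_stat)
  expect_equal(de1$p, de2$p)
})

test_that("BH adjustment is monotone in p", {
  d <- sim_two_group(80, 5, 5, seed = 11)
  de <- moderatedT(d$x, d$group)
  expect_true(all(de$p_adj >= de$p))
  expect_identical(order(de$p), order(de$p_adj, de$p))
})

test_that("zero-variance genes get p = 1 and group size is enforced", {
  d <- sim_two_group(20, 4, 4, seed = 13)
  d$x[1, ] <- 3
  expect_message(de <- moderatedT(d$x, d$group), "zero variance")
  expect_equal(de$p[1], 1)
  expect_error(moderatedT(d$x, rep(c(0, 1), c(1, 7))), ">= 2 samples")
})

test_that("selectDegs applies the joint fold-change and p rule", {
  de <- data.frame(gene_id = c("a", "b", "c"), log2fc = c(1.5, 0.9, -1.2),
                   t_stat = 0, p = c(0.01, 1e-8, 0.2), p_adj = c(0.02, 1e-7, 0.3))
  expect_identical(selectDegs(de), "a")
  expect_identical(selectDegs(de, pThresh = 0.3), c("a", "c"))
})

test_that("planted DEGs are recovered with few false discoveries", {
  d <- sim_two_group(1000, 50, 50, delta = 2, nDe = 30, seed = 17)
  de <- moderatedT(d$x, d$group)
  hits <- selectDegs(de)
  truth <- sprintf("g%03d", 1:30)
  expect_gte(length(intersect(hits, truth)) / 30, 0.9)
  expect_lte(length(setdiff(hits, truth)), 5)
})

test_that("sharedDegs with k = 2 equals the single two-group contrast", {
  d <- sim_two_group(150, 10, 10, delta = 2, nDe = 15, seed = 19)
  lab <- ifelse(d$group == 1, "c2", "c1")
  shared <- sharedDegs(d$x, lab)
  single <- selectDegs(moderatedT(d$x, lab))
  expect_setequal(as.character(shared), single)
})

test_that("sharedDegs recovers disjoint marker blocks of three subtypes", {
  set.seed(23)
  n <- 60
  lab <- rep(c("A", "B", "C"), each = n / 3)
  x <- matrix(stats::rnorm(300 * n), 300, n,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:n)))
  markers <- split(1:45, rep(1:3, each = 15))
  for (i in 1:3) x[markers[[i]], lab == c("A", "B", "C")[i]] <-
    x[markers[[i]], lab == c("A", "B", "C")[i]] + 3
  shared <- sharedDegs(x, lab)
  expect_gte(length(intersect(shared, sprintf("g%03d", 1:45))) / 45, 0.9)
  hits <- attr(shared, "contrasts")
  expect_true(is.matrix(hits) && all(colnames(hits) == c("A", "B", "C")))
})

test_that("shuffled labels produce few spurious shared DEGs", {
  sizes <- numeric(20)
  for (s in 1:20) {
    set.seed(s + 400)
    x <- matrix(stats::rnorm(500 * 30), 500, 30,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:30)))
    lab <- sample(rep(c("A", "B", "C"), each = 10))
    sizes[s] <- length(sharedDegs(x, lab))
  }
  # null |log2fc| > 1 plus p < 0.05 jointly: bounded by p-threshold expectation
  expect_lte(mean(sizes), 2 * 0.05 * 500 * 3)
})
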