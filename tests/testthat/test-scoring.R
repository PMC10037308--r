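test_that("signature genes split by the sign of the cluster mean difference", {
  x <- matrix(c(5, 5, 2, 2,    # up in A
                1, 1, 4, 4,    # up in B
                3, 3, 3, 3),   # tie -> excluded
              3, 4, byrow = TRUE,
              dimnames = list(c("up", "down", "flat"), paste0("s", 1:4)))
  lab <- c("A", "A", "B", "B")
  expect_warning(sp <- assignSignatureGenes(x, rownames(x), lab), "excluded")
  expect_identical(sp$genesA, "up")
  expect_identical(sp$genesB, "down")
  expect_identical(sp$excluded, "flat")
  expect_error(assignSignatureGenes(x, rownames(x), rep("A", 4)), "A.*B")
})

test_that("planted two-block DEG structure is split exactly at zero noise", {
  lab <- rep(c("A", "B"), each = 10)
  blockA <- matrix(rep(c(4, 1), c(10, 10)), 5, 20, byrow = TRUE)
  blockB <- matrix(rep(c(1, 4), c(10, 10)), 5, 20, byrow = TRUE)
  x <- rbind(blockA, blockB)
  dimnames(x) <- list(c(paste0("a", 1:5), paste0("b", 1:5)), paste0("s", 1:20))
  sp <- assignSignatureGenes(x, rownames(x), lab)
  expect_setequal(sp$genesA, paste0("a", 1:5))
  expect_setequal(sp$genesB, paste0("b", 1:5))
})

test_that("shadow-feature selection confirms the informative feature and rejects noise", {
  confirmedHit <- 0; rejectedFrac <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    y <- rep(c("A", "B"), each = n / 2)
    X <- cbind(signal = as.numeric(y == "A") + stats::rnorm(n, 0, 0.05),
               matrix(stats::rnorm(n * 50), n, 50,
                      dimnames = list(NULL, paste0("noise", 1:50))))
    res <- borutaSelect(X, y, nIter = 25, trees = 100, seed = s)
    confirmedHit <- confirmedHit + ("signal" %in% res$confirmed)
    rejectedFrac[s] <- sum(grepl("noise", res$rejected)) / 50
  }
  expect_equal(confirmedHit, 20)
  expect_gte(mean(rejectedFrac), 0.95)
})

test_that("pure-noise features are almost never confirmed", {
  confirmed <- integer(10)
  for (s in 1:10) {
    set.seed(s + 50)
    X <- matrix(stats::rnorm(100 * 30), 100, 30)
    y <- rep(c("A", "B"), each = 50)
    confirmed[s] <- length(borutaSelect(X, y, nIter = 25, trees = 100,
                                        seed = s)$confirmed)
  }
  expect_gte(mean(confirmed == 0), 0.9)
})

test_that("boruta input contracts are enforced", {
  X <- matrix(stats::rnorm(40), 20, 2)
  y <- rep(c("A", "B"), 10)
  expect_error(borutaSelect(X, y, nIter = 10), ">= 20")
  Xc <- cbind(X, const = 1)
  expect_warning(borutaSelect(Xc, y, nIter = 20, trees = 50, seed = 1),
                 "constant")
})

test_that("PC1 scores are the oriented leading-eigenvector projection", {
  set.seed(31)
  # rank-1: two perfectly correlated genes
  base <- stats::rnorm(12)
  x <- rbind(g1 = base, g2 = 2 * base + 5)
  colnames(x) <- paste0("s", 1:12)
  s <- pc1Scores(x, c("g1", "g2"))
  expect_equal(abs(stats::cor(s, base)), 1, tolerance = 1e-10)

  # independent linear-algebra oracle on a 10-gene set
  y <- matrix(stats::rnorm(10 * 25), 10, 25,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:25)))
  z <- t(scale(t(y)))
  ev <- eigen(stats::cov(t(z)))$vectors[, 1]
  proj <- as.vector(t(z) %*% ev)
  if (stats::cor(proj, colMeans(z)) < 0) proj <- -proj
  expect_equal(unname(pc1Scores(y, paste0("g", 1:10))), proj, tolerance = 1e-8)

  # sign flip of the data is undone by the orientation rule
  sFlip <- pc1Scores(-y, paste0("g", 1:10))
  mFlip <- colMeans(t(scale(t(-y))))
  expect_gte(stats::cor(sFlip, mFlip), 0)
  expect_error(pc1Scores(y, "g1"), ">= 2")
})

test_that("the ICI score is the A-sum minus B-sum and tolerates empty sides", {
  a <- c(s1 = 2.0, s2 = 1.0)
  b <- c(s1 = 0.5, s2 = -1.0)
  expect_equal(iciScore(a, b), c(s1 = 1.5, s2 = 2.0))
  expect_equal(iciScore(a, NULL), a)
  expect_equal(iciScore(list(a, a), b), c(s1 = 3.5, s2 = 3.0))
  bad <- c(sX = 1, sY = 2)
  expect_error(iciScore(a, bad), "mismatch")
})

test_that("ICI score is invariant to adding a constant to every gene of every sample", {
  co <- simulateCohort(nSamples = 40, nGenes = 200, seed = 33)
  logE <- log2(exprValues(co$expression) + 1)
  genesA <- rownames(logE)[1:20]; genesB <- rownames(logE)[21:40]
  s1 <- iciScore(pc1Scores(logE, genesA), pc1Scores(logE, genesB))
  s2 <- iciScore(pc1Scores(logE + 7, genesA), pc1Scores(logE + 7, genesB))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("planted immune-hot samples score higher", {
  co <- simulateCohort(nSamples = 150, seed = 35)
  logE <- log2(exprValues(co$expression) + 1)
  # signature sides straight from the planted marker blocks
  immune <- co$immuneMarkers
  tumor <- setdiff(rownames(co$signature)[1:250], immune)[1:50]
  score <- iciScore(pc1Scores(logE, immune), pc1Scores(logE, tumor))
  hot <- co$truthSubtype == "B"; cold <- co$truthSubtype == "C"
  expect_gt(mean(score[hot]), mean(score[cold]))
  expect_lt(stats::wilcox.test(score[hot], score[cold])$p.value, 0.01)
})

test_that("dichotomize recovers an engineered optimal cutoff and respects the floor", {
  scores <- stats::setNames(as.numeric(1:100), sprintf("p%03d", 1:100))
  # hazard jumps exactly above score 50
  set.seed(37)
  times <- c(stats::rexp(50, 1e-3), stats::rexp(50, 8e-3))
  cl <- surv_clinical(times, rep(1, 100))
  res <- dichotomize(scores, NULL, cl)
  expect_lte(abs(res@cutoff - 50), 3)
  grp <- scoreGroups(res)
  expect_gte(min(table(grp)) / 100, 0.1)

  # degenerate survival: no events at all
  cl0 <- surv_clinical(rep(10, 100), rep(0, 100))
  expect_warning(res0 <- dichotomize(scores, NULL, cl0), "median")
  expect_equal(res0@cutoff, stats::median(scores))
})
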