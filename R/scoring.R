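#' Split signature genes by gene-cluster association
#'
#' For each DEG, the difference of its mean expression between gene cluster A
#' and gene cluster B samples decides its side: positive differences go to
#' `genesA` (the set positively associated with cluster A), negative to
#' `genesB`; exact ties are excluded with a warning.
#'
#' @param expr log-scale genes-by-samples matrix or [ICIExpression-class].
#' @param degs DEG gene ids.
#' @param geneClusterLabels per-sample label with exactly two levels, `"A"`
#'   and `"B"`.
#' @return list of class `SignatureSplit`: `genesA`, `genesB`, `excluded`,
#'   `labels`.
#' @export
assignSignatureGenes <- function(expr, degs, geneClusterLabels) {
  if (methods::is(expr, "ICIExpression")) expr <- exprValues(expr)
  lab <- as.character(geneClusterLabels)
  if (!setequal(unique(lab), c("A", "B")))
    stop("geneClusterLabels must take exactly the two values 'A' and 'B'")
  degs <- intersect(degs, rownames(expr))
  if (!length(degs)) stop("no DEGs present in the expression matrix")
  dA <- rowMeans(expr[degs, lab == "A", drop = FALSE])
  dB <- rowMeans(expr[degs, lab == "B", drop = FALSE])
  diffAB <- dA - dB
  ties <- diffAB == 0
  if (any(ties))
    warning(sum(ties), " DEG(s) with identical cluster means excluded")
  structure(list(genesA = degs[diffAB > 0], genesB = degs[diffAB < 0],
                 excluded = degs[ties],
                 labels = stats::setNames(lab, colnames(expr))),
            class = "SignatureSplit")
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' Each iteration appends a column-shuffled "shadow" copy of every feature,
#' fits a random-forest classifier ([ranger::ranger]) and scores a hit for any
#' real feature whose impurity importance exceeds the maximal shadow
#' importance. After `nIter` iterations, features whose hit counts fall outside
#' the two-sided binomial(nIter, 0.5) band at level `alpha` are confirmed
#' (above) or rejected (below); the remainder stay tentative and are excluded
#' from the confirmed list. Constant features are removed with a warning.
#'
#' @param features samples-by-features numeric matrix.
#' @param response per-sample class label (>= 2 classes).
#' @param nIter iterations (>= 20; default 100).
#' @param trees trees per forest (default 300).
#' @param alpha two-sided binomial level (default 0.01).
#' @param seed integer seed.
#' @return list: `confirmed`, `rejected`, `tentative` (feature names), `hits`
#'   (named counts), `nIter`.
#' @export
borutaSelect <- function(features, response, nIter = 100L, trees = 300L,
                         alpha = 0.01, seed = 2020L) {
  if (nIter < 20L) stop("nIter must be >= 20")
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.factor(response)
  if (nlevels(y) < 2L) stop("response needs >= 2 classes")
  keep <- apply(X, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) removed")
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  set.seed(seed)
  hits <- stats::setNames(integer(p), colnames(X))
  for (it in seq_len(nIter)) {
    shadow <- apply(X, 2L, sample)
    colnames(shadow) <- paste0(".shadow", seq_len(p))
    df <- data.frame(.y = y, X, shadow, check.names = FALSE)
    rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                         num.trees = trees, importance = "impurity",
                         num.threads = 1L, seed = sample.int(.Machine$integer.max, 1L))
    imp <- rf$variable.importance
    thr <- max(imp[paste0(".shadow", seq_len(p))])
    hits <- hits + (imp[colnames(X)] > thr)
  }
  hi <- stats::qbinom(1 - alpha / 2, nIter, 0.5)   # confirm when P(X > hi) < alpha/2
  lo <- stats::qbinom(alpha / 2, nIter, 0.5)       # reject when below the lower band
  confirmed <- names(hits)[hits > hi]
  rejected <- names(hits)[hits < lo]
  list(confirmed = confirmed, rejected = rejected,
       tentative = setdiff(names(hits), c(confirmed, rejected)),
       hits = hits, nIter = nIter)
}

#' Per-sample PC1 score of a gene set
#'
#' Standardizes each gene across samples, projects samples on the leading
#' eigenvector of the gene-gene covariance (the first principal component) and
#' orients the sign so the score correlates positively with the mean
#' standardized expression of the set — the PCA sign is otherwise arbitrary
#' and would silently flip downstream scores.
#'
#' @param expr log-scale genes-by-samples matrix or [ICIExpression-class].
#' @param genes gene set (>= 2 usable genes after intersection).
#' @return named per-sample numeric vector.
#' @export
pc1Scores <- function(expr, genes) {
  if (methods::is(expr, "ICIExpression")) expr <- exprValues(expr)
  genes <- intersect(genes, rownames(expr))
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  if (nrow(x) < 2L) stop("need >= 2 usable (non-constant) genes in the set")
  z <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  s <- pc$x[, 1L]
  m <- colMeans(z)
  if (stats::sd(m) > 0 && suppressWarnings(stats::cor(s, m)) < 0) s <- -s
  stats::setNames(as.numeric(s), colnames(expr))
}

#' Combine signature-side PC1 vectors into the ICI score
#'
#' The per-sample score is the sum of the A-side PC1 values minus the sum of
#' the B-side PC1 values. Each side accepts one vector or a list of vectors
#' (multiple signature sets per side); either side may be empty.
#'
#' @param pc1A,pc1B named numeric vector(s), aligned on sample names.
#' @return named per-sample numeric vector.
#' @export
iciScore <- function(pc1A, pc1B = NULL) {
  norm <- function(x) if (is.null(x)) list() else if (is.list(x)) x else list(x)
  la <- norm(pc1A); lb <- norm(pc1B)
  all <- c(la, lb)
  if (!length(all)) stop("at least one PC1 vector required")
  ids <- names(all[[1L]])
  if (is.null(ids)) stop("PC1 vectors must be named by sample")
  for (v in all) {
    if (!identical(names(v), ids)) {
      if (!setequal(names(v), ids)) stop("sample mismatch across PC1 vectors")
    }
  }
  add <- function(acc, v) acc + v[ids]
  a <- Reduce(add, la, stats::setNames(numeric(length(ids)), ids))
  b <- Reduce(add, lb, stats::setNames(numeric(length(ids)), ids))
  a - b
}

#' Dichotomize ICI scores at the survival-optimal cutoff
#'
#' Finds the maximally selected log-rank cutoff ([optimalCutoff()]) and labels
#' samples `high` when the score strictly exceeds it (ties go low). When the
#' survival data are degenerate (no events, or all events at identical
#' follow-up) the cutoff falls back to the median score with a warning.
#'
#' @param pc1A,pc1B named per-sample PC1 vectors (B may be NULL); the score is
#'   their difference.
#' @param clinical clinical table covering all scored samples.
#' @param floor minimum group fraction (default 0.1).
#' @param nPerm permutations for the selection-adjusted p (default 0).
#' @param seed integer seed.
#' @return An [ICIScores-class]; the cutoff search result is attached as
#'   `attr(, "cutoffSearch")`.
#' @export
dichotomize <- function(pc1A, pc1B = NULL, clinical, floor = 0.1, nPerm = 0L,
                        seed = 2020L) {
  score <- iciScore(pc1A, pc1B)
  clinical <- validateClinical(clinical)
  ord <- match(names(score), clinical$sample_id)
  if (anyNA(ord)) stop("survival data missing for some scored samples")
  cl <- clinical[ord, ]
  degenerate <- sum(cl$os_event) == 0 ||
    length(unique(cl$os_time[cl$os_event == 1])) < 2L
  search <- NULL
  if (degenerate) {
    warning("degenerate survival data: cutoff falls back to the median score")
    cutoff <- stats::median(score)
  } else {
    search <- optimalCutoff(score, cl, floor = floor, nPerm = nPerm, seed = seed)
    cutoff <- search$cutoff
  }
  pb <- if (is.null(pc1B)) stats::setNames(numeric(length(score)), names(score))
        else if (is.list(pc1B)) iciScore(pc1B) else pc1B[names(score)]
  pa <- score + pb
  res <- ICIScores(names(score), pa, pb, cutoff)
  attr(res, "cutoffSearch") <- search
  res
}
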