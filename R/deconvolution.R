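#' Estimate immune cell fractions by non-negative least squares
#'
#' Solves, per sample, `min ||S w - y||` subject to `w >= 0` over the genes
#' shared between the expression object and the signature matrix, then
#' renormalizes the weights to the unit simplex. This is the linear mixture
#' model underlying reference-based deconvolution; externally computed fraction
#' tables (e.g. canonical CIBERSORT/LM22 output) can be substituted anywhere a
#' [FractionMatrix-class] is accepted, via [FractionMatrix()].
#'
#' The optional permutation test shuffles the gene labels of each sample's
#' signature-gene vector `nPerm` times and refits; the p-value is the fraction
#' of permutations whose fitted-vs-observed correlation reaches the unpermuted
#' one.
#'
#' @param expr an [ICIExpression-class] (linear scale: TPM or FPKM).
#' @param signature genes-by-celltypes non-negative matrix.
#' @param nPerm permutations for the per-sample p-value (0 skips the test).
#' @param seed integer seed for the permutations.
#' @return A [FractionMatrix-class].
#' @export
estimateFractions <- function(expr, signature, nPerm = 0L, seed = 2020L) {
  stopifnot(methods::is(expr, "ICIExpression"))
  v <- exprValues(expr)
  genes <- intersect(rownames(signature), rownames(v))
  S <- as.matrix(signature)[genes, , drop = FALSE]
  perType <- colSums(S > 0)
  if (length(genes) < 2L || any(perType < 2L))
    stop("need >= 2 signature genes per cell type present in the expression matrix")
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    cc <- stats::cor(S)
    bad <- unique(colnames(S)[which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)])
    stop("rank-deficient signature (collinear cell types): ",
         paste(if (length(bad)) bad else colnames(S), collapse = ", "))
  }
  Y <- v[genes, , drop = FALSE]
  n <- ncol(Y)
  fr <- matrix(0, n, ncol(S), dimnames = list(colnames(Y), colnames(S)))
  pp <- rep(NA_real_, n)
  set.seed(seed)
  for (i in seq_len(n)) {
    y <- Y[, i]
    w <- pracma::lsqnonneg(S, y)$x
    if (sum(w) <= 0) {
      warning("all-zero fit for sample ", colnames(Y)[i], "; uniform fractions returned")
      w <- rep(1, ncol(S))
    }
    fr[i, ] <- w / sum(w)
    if (nPerm > 0L) {
      obs <- suppressWarnings(stats::cor(as.vector(S %*% w), y))
      nullc <- replicate(nPerm, {
        yp <- sample(y)
        wp <- pracma::lsqnonneg(S, yp)$x
        suppressWarnings(stats::cor(as.vector(S %*% wp), yp))
      })
      nullc[is.na(nullc)] <- -Inf
      pp[i] <- mean(nullc >= obs)
    }
  }
  FractionMatrix(fr, permP = pp)
}

.ssgsea_one <- function(r, ord, inset, alpha) {
  # r: ranks (ties averaged, largest expression = largest rank); ord: positions
  # in decreasing expression order; inset: logical per gene
  N <- length(r)
  m <- sum(inset)
  if (m == N) return(0)  # hit and miss ECDFs coincide
  hit <- inset[ord]
  w <- (r[ord]^alpha) * hit
  Pin <- cumsum(w) / sum(w)
  Pout <- cumsum(!hit) / (N - m)
  sum(Pin - Pout)
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (descending order; ties get
#' average ranks) and the score of a set is the sum over the ranked list of the
#' difference between the rank-weighted in-set ECDF (weights `rank^alpha`) and
#' the unweighted out-of-set ECDF. Being rank-based, scores are invariant under
#' any monotone transformation of a sample's expression values.
#'
#' @param expr an [ICIExpression-class].
#' @param geneSets named list of gene-id vectors (see [readGmt()]).
#' @param alpha rank-weight exponent (default 0.25).
#' @return samples-by-sets numeric matrix.
#' @export
ssgseaScores <- function(expr, geneSets, alpha = 0.25) {
  stopifnot(methods::is(expr, "ICIExpression"), is.list(geneSets))
  v <- exprValues(expr)
  insets <- lapply(geneSets, function(g) rownames(v) %in% g)
  empty <- vapply(insets, function(x) sum(x) == 0L, TRUE)
  if (any(empty)) stop("gene set(s) empty after intersection: ",
                       paste(names(geneSets)[empty], collapse = ", "))
  out <- matrix(NA_real_, ncol(v), length(geneSets),
                dimnames = list(colnames(v), names(geneSets)))
  for (j in seq_len(ncol(v))) {
    y <- v[, j]
    r <- rank(y)                      # largest expression -> largest rank
    ord <- order(y, decreasing = TRUE)
    for (s in seq_along(insets))
      out[j, s] <- .ssgsea_one(r, ord, insets[[s]], alpha)
  }
  out
}

#' Stromal, immune and combined microenvironment scores
#'
#' Computes stromal and immune ssGSEA scores, their sum (the combined
#' microenvironment score indexing non-tumor content), and — only when platform
#' calibration coefficients `(a, b)` are supplied — tumor purity as
#' `cos(a + b * combined)` clipped to `[0, 1]` with a warning. Purity
#' coefficients are platform-specific, so no default is hard-coded; without
#' them the purity column is `NA`.
#'
#' @param expr an [ICIExpression-class].
#' @param stromalSet,immuneSet character vectors of gene ids.
#' @param purityCoeffs optional numeric `c(a, b)`.
#' @param alpha ssGSEA rank-weight exponent.
#' @return data.frame with `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `purity`.
#' @export
estimateTmeScores <- function(expr, stromalSet, immuneSet, purityCoeffs = NULL,
                              alpha = 0.25) {
  sc <- ssgseaScores(expr, list(stromal = stromalSet, immune = immuneSet),
                     alpha = alpha)
  est <- sc[, "stromal"] + sc[, "immune"]
  purity <- rep(NA_real_, length(est))
  if (!is.null(purityCoeffs)) {
    stopifnot(length(purityCoeffs) == 2L)
    purity <- cos(purityCoeffs[1L] + purityCoeffs[2L] * est)
    if (any(purity < 0 | purity > 1)) {
      warning("purity outside [0, 1] clipped")
      purity <- pmin(pmax(purity, 0), 1)
    }
  }
  data.frame(sample_id = rownames(sc), stromal_score = sc[, "stromal"],
             immune_score = sc[, "immune"], estimate_score = est,
             purity = purity, row.names = NULL)
}
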