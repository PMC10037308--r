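.trigamma_inverse <- function(x) {
  # Newton solve trigamma(y) = x on log scale; x > 0
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

.fit_fdist <- function(s2, df) {
  # moment-match the scaled-F prior of gene variances on the log scale:
  # log s2_g = log s0^2 + log chi2/df terms; returns prior df d0 and s0^2
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s20 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread of the log variances is at or below chi-square sampling
    # noise: shrink fully to the geometric mean of the observed variances, so
    # that identical sample variances are a fixed point of the shrinkage
    d0 <- Inf
    s20 <- exp(mean(z))
  }
  list(d0 = d0, s20 = s20)
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per gene: the log2 fold change is the group-1 minus group-0 mean, the pooled
#' residual variance \eqn{s_g^2} (df = n0 + n1 - 2) is shrunk toward a prior
#' \eqn{s_0^2} estimated by moment matching the distribution of the
#' \eqn{s_g^2} on the log scale, giving
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, and the
#' moderated t statistic \eqn{t = \Delta / (\tilde{s}_g \sqrt{1/n_0 + 1/n_1})}
#' is referred to a t distribution on \eqn{d_0 + d_g} df. P-values are
#' BH-adjusted across genes. With `shrink = FALSE` (the \eqn{d_0 = 0} limit)
#' this is the ordinary pooled two-sample t-test. Genes with zero variance in
#' both groups and zero fold change get `p = 1` and are reported with a
#' message.
#'
#' @param expr genes-by-samples matrix on a log scale, or an
#'   [ICIExpression-class] with `unitTag == "LOG2TPM"`.
#' @param group per-sample binary label; the *second* factor level (or larger
#'   value) is the "1" group whose mean enters positively.
#' @param shrink apply empirical-Bayes shrinkage (default TRUE).
#' @return data.frame `gene_id`, `log2fc`, `t_stat`, `p`, `p_adj`, `df`,
#'   `contrast`, sorted in input gene order; prior parameters in
#'   `attr(, "prior")`.
#' @export
moderatedT <- function(expr, group, shrink = TRUE) {
  if (methods::is(expr, "ICIExpression")) expr <- exprValues(expr)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples")
  i1 <- g == levels(g)[2L]
  n0 <- sum(!i1); n1 <- sum(i1)
  m0 <- rowMeans(expr[, !i1, drop = FALSE])
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  v0 <- rowSums((expr[, !i1, drop = FALSE] - m0)^2)
  v1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2)
  df <- n0 + n1 - 2
  s2 <- (v0 + v1) / df
  fc <- m1 - m0

  if (shrink && sum(s2 > 0) >= 3L) {
    pr <- .fit_fdist(s2, df)
    d0 <- pr$d0; s20 <- pr$s20
  } else {
    d0 <- 0; s20 <- 0
  }
  s2post <- if (is.infinite(d0)) rep(s20, length(s2)) else
    (d0 * s20 + df * s2) / (d0 + df)
  dfTotal <- min(d0 + df, .Machine$double.xmax)

  se <- sqrt(s2post * (1 / n0 + 1 / n1))
  t <- ifelse(se > 0, fc / se, sign(fc) * Inf)
  degen <- s2 == 0
  if (any(degen))
    message(sum(degen), " gene(s) with zero variance in both groups: p set to 1")
  t[degen & fc == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df = dfTotal)
  p[degen & fc == 0] <- 1
  res <- data.frame(gene_id = rownames(expr), log2fc = fc, t_stat = t, p = p,
                    p_adj = stats::p.adjust(p, "BH"), df = dfTotal,
                    contrast = paste(levels(g)[2L], "vs", levels(g)[1L]),
                    row.names = NULL)
  attr(res, "prior") <- list(d0 = d0, s20 = s20)
  res
}

#' Select differentially expressed genes
#'
#' Applies the joint threshold rule: `|log2fc| > fcThresh` and (raw or
#' BH-adjusted) `p < pThresh`. The absolute-fold-change criterion is read on
#' the log2 scale, the convention under which a threshold of 1 (a two-fold
#' change) is meaningful.
#'
#' @param de data.frame from [moderatedT()].
#' @param fcThresh absolute log2 fold-change threshold (default 1).
#' @param pThresh p-value threshold (default 0.05).
#' @param useAdjusted threshold `p_adj` instead of `p` (default FALSE).
#' @return character vector of selected gene ids.
#' @export
selectDegs <- function(de, fcThresh = 1, pThresh = 0.05, useAdjusted = FALSE) {
  stopifnot(nrow(de) > 0L)
  p <- if (useAdjusted) de$p_adj else de$p
  de$gene_id[abs(de$log2fc) > fcThresh & p < pThresh]
}

#' DEGs shared across k clusters by one-vs-rest contrasts
#'
#' Runs [moderatedT()] one-vs-rest for every cluster and combines the
#' per-contrast [selectDegs()] lists — by union (default; a gene significant in
#' any contrast) or intersection. The per-gene record of which contrasts fired
#' is returned alongside.
#'
#' @param expr log-scale genes-by-samples matrix or [ICIExpression-class].
#' @param labels per-sample cluster label (k >= 2 levels, every cluster with
#'   >= 2 samples).
#' @param fcThresh,pThresh,useAdjusted passed to [selectDegs()].
#' @param mode `"union"` (default) or `"intersect"`.
#' @return character vector of gene ids with a logical genes-by-contrasts
#'   matrix in `attr(, "contrasts")`.
#' @export
sharedDegs <- function(expr, labels, fcThresh = 1, pThresh = 0.05,
                       useAdjusted = FALSE, mode = c("union", "intersect")) {
  mode <- match.arg(mode)
  if (methods::is(expr, "ICIExpression")) expr <- exprValues(expr)
  g <- as.factor(labels)
  if (nlevels(g) < 2L) stop("need >= 2 clusters")
  if (any(table(g) < 2L)) stop("every cluster needs >= 2 samples")
  lv <- levels(g)
  hits <- matrix(FALSE, nrow(expr), length(lv),
                 dimnames = list(rownames(expr), lv))
  for (cl in lv) {
    onevs <- factor(ifelse(g == cl, cl, "rest"), levels = c("rest", cl))
    de <- moderatedT(expr, onevs)
    hits[, cl] <- rownames(expr) %in%
      selectDegs(de, fcThresh, pThresh, useAdjusted)
  }
  sel <- if (mode == "union") rowSums(hits) > 0 else rowSums(hits) == length(lv)
  out <- rownames(expr)[sel]
  attr(out, "contrasts") <- hits[sel, , drop = FALSE]
  out
}
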