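.NONSILENT <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
                "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site")

#' Tumor mutational burden per sample
#'
#' TMB is the raw count of non-silent MAF records per sample (missense,
#' nonsense, frameshift and in-frame indels, splice site, nonstop, translation
#' start site); Silent/UTR/intron classes are excluded. Samples listed in
#' `samples` but absent from the MAF count 0. Divide by the captured megabases
#' yourself if a per-Mb rate is wanted.
#'
#' @param maf MAF data.frame (see [readMaf()]).
#' @param samples full sample list, including zero-mutation samples.
#' @param classes variant classes counted (default the non-silent set).
#' @return named integer vector.
#' @export
computeTmb <- function(maf, samples, classes = .NONSILENT) {
  ns <- maf[maf$Variant_Classification %in% classes, ]
  tab <- table(factor(ns$Tumor_Sample_Barcode, levels = samples))
  stats::setNames(as.integer(tab), samples)
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Pearson chi-square with continuity correction (0.5 subtracted from each
#' |observed - expected|), 1 df, upper-tail p-value — the convention under
#' which small-count mutation contingency tables are customarily tested.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply the continuity correction (default TRUE).
#' @return list `chi2`, `p`.
#' @export
yatesChisq <- function(table, correct = TRUE) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == 2L), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("undefined: zero margin in 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Per-gene mutation contingency table between score groups
#'
#' For every gene, counts the samples of each group carrying at least one
#' non-silent record; the per-group top `topN` genes by mutation frequency are
#' pooled and each tested for group association with [yatesChisq()]. Rows are
#' sorted by p-value. Percentages are exact count/group-size ratios and the
#' group sizes are constant across genes.
#'
#' @param maf MAF data.frame.
#' @param groups named per-sample `"high"`/`"low"` label covering every MAF
#'   sample.
#' @param topN genes kept per group (default 20).
#' @return data.frame `gene`, `high_wild`, `high_mut`, `high_pct`, `low_wild`,
#'   `low_mut`, `low_pct`, `chi2`, `p`.
#' @export
mutatedGeneTable <- function(maf, groups, topN = 20L) {
  stopifnot(!is.null(names(groups)), all(groups %in% c("high", "low")))
  if (!all(unique(maf$Tumor_Sample_Barcode) %in% names(groups)))
    stop("every MAF sample needs a group label")
  nH <- sum(groups == "high"); nL <- sum(groups == "low")
  if (nH == 0L || nL == 0L) stop("both groups need >= 1 sample")
  ns <- maf[maf$Variant_Classification %in% .NONSILENT, ]
  mutated <- unique(ns[, c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  mutated$group <- groups[mutated$Tumor_Sample_Barcode]
  cnt <- table(factor(mutated$Hugo_Symbol),
               factor(mutated$group, levels = c("high", "low")))
  topH <- rownames(cnt)[order(-cnt[, "high"])][seq_len(min(topN, nrow(cnt)))]
  topL <- rownames(cnt)[order(-cnt[, "low"])][seq_len(min(topN, nrow(cnt)))]
  genes <- union(topH, topL)
  res <- do.call(rbind, lapply(genes, function(g) {
    hM <- cnt[g, "high"]; lM <- cnt[g, "low"]
    tab <- matrix(c(nH - hM, hM, nL - lM, lM), 2L, 2L, byrow = TRUE)
    ct <- if ((hM == nH && lM == nL) || (hM == 0L && lM == 0L))
      list(chi2 = 0, p = 1)   # identical mutation status everywhere: no association
    else tryCatch(yatesChisq(tab), error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(gene = g, high_wild = nH - hM, high_mut = hM,
               high_pct = 100 * hM / nH, low_wild = nL - lM, low_mut = lM,
               low_pct = 100 * lM / nL, chi2 = ct$chi2, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}

#' Spearman association between TMB and a score
#'
#' Rank correlation with average ranks on ties; the p-value uses the
#' large-sample t approximation.
#'
#' @param tmb,score aligned per-sample numeric vectors (n >= 10).
#' @return list `rho`, `p`.
#' @export
tmbScoreAssociation <- function(tmb, score) {
  stopifnot(length(tmb) == length(score), length(tmb) >= 10L)
  if (stats::sd(tmb) == 0 || stats::sd(score) == 0)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(tmb, score, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Survival across TMB-by-ICI strata
#'
#' Dichotomizes TMB at its median (ties low), crosses it with the ICI score
#' group into up to four strata, and tests them jointly by log-rank. Empty
#' strata are dropped with a warning (reducing the df).
#'
#' @param tmb named per-sample TMB.
#' @param scoreGroups named per-sample `"high"`/`"low"` ICI group.
#' @param clinical clinical table covering the samples.
#' @return list: `strata` (named labels like `"highTMB/highICI"`), `logrank`.
#' @export
tmbIciStrata <- function(tmb, scoreGroups, clinical) {
  clinical <- validateClinical(clinical)
  ids <- intersect(names(tmb), names(scoreGroups))
  cl <- clinical[match(ids, clinical$sample_id), ]
  if (anyNA(cl$sample_id)) stop("survival data missing for some samples")
  tmbGrp <- ifelse(tmb[ids] > stats::median(tmb[ids]), "highTMB", "lowTMB")
  strata <- paste(tmbGrp, ifelse(scoreGroups[ids] == "high", "highICI", "lowICI"),
                  sep = "/")
  full <- c(outer(c("highTMB", "lowTMB"), c("highICI", "lowICI"), paste, sep = "/"))
  present <- intersect(full, unique(strata))
  if (length(present) < 4L)
    warning("empty stratum(ta): ", paste(setdiff(full, present), collapse = ", "),
            "; df reduced")
  if (length(present) < 2L) stop("fewer than 2 non-empty strata")
  list(strata = stats::setNames(strata, ids),
       logrank = logrank(cl$os_time, cl$os_event, strata))
}
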