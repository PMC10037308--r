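#' Single-cell QC filter
#'
#' Keeps a cell iff it has at least `minGenes` detected genes, a mitochondrial
#' fraction of at most `maxMito`, and a novelty score
#' (`log10(n_genes) / log10(n_umi)`) of at least `minNovelty` — the boundary
#' values themselves are kept, matching filters phrased as removing cells
#' *below* 200 genes, *above* 15% mitochondrial counts or *below* 0.8 novelty.
#' The removal summary counts rule violations non-exclusively (a cell can fail
#' several rules). The filter is idempotent.
#'
#' @param cells data.frame with `cell_id`, `n_genes`, `n_umi`,
#'   `mito_fraction`.
#' @param minGenes minimum detected genes (default 200).
#' @param maxMito maximum mitochondrial fraction (default 0.15).
#' @param minNovelty minimum novelty score (default 0.8).
#' @return list: `cells` (input plus `novelty` and `keep` columns), `kept`
#'   (filtered table), `summary` (removals per rule and total).
#' @export
cellQcFilter <- function(cells, minGenes = 200L, maxMito = 0.15,
                         minNovelty = 0.8) {
  need <- c("cell_id", "n_genes", "n_umi", "mito_fraction")
  miss <- setdiff(need, colnames(cells))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(cells$n_genes < 0) || any(cells$n_umi < 0))
    stop("negative counts")
  novelty <- ifelse(cells$n_umi > 1,
                    log10(pmax(cells$n_genes, 1)) / log10(cells$n_umi),
                    NA_real_)
  failGenes <- cells$n_genes < minGenes
  failMito <- cells$mito_fraction > maxMito
  failNov <- !is.na(novelty) & novelty < minNovelty
  keep <- !failGenes & !failMito & !failNov
  cells$novelty <- novelty
  cells$keep <- keep
  list(cells = cells, kept = cells[keep, , drop = FALSE],
       summary = list(n_cells = nrow(cells), removed = sum(!keep),
                      fail_genes = sum(failGenes), fail_mito = sum(failMito),
                      fail_novelty = sum(failNov)))
}

#' Highly variable gene selection by binned standardized variance
#'
#' Library-size normalizes to counts per 10k, log1p-transforms, computes the
#' per-gene variance of the log values, and standardizes it within 20
#' equal-occupancy bins of the gene mean (so the mean-variance trend does not
#' dominate). The `nTop` genes by standardized variance are returned.
#'
#' @param counts non-negative genes-by-cells matrix.
#' @param nTop genes to return (default 2000; must not exceed the gene count).
#' @param nBins mean bins (default 20).
#' @return character vector of gene ids, ranked.
#' @export
hvgSelect <- function(counts, nTop = 2000L, nBins = 20L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nTop > nrow(counts)) stop("nTop exceeds the number of genes")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  sz <- colSums(counts)
  sz[sz == 0] <- 1
  lx <- log1p(sweep(counts, 2L, sz, "/") * 1e4)
  mu <- rowMeans(lx)
  v <- rowSums((lx - mu)^2) / (ncol(lx) - 1L)
  nBins <- min(nBins, length(unique(mu)))
  bins <- cut(rank(mu, ties.method = "first"), breaks = nBins, labels = FALSE)
  z <- v
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(v[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
  }
  rownames(counts)[order(-z)][seq_len(nTop)]
}
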