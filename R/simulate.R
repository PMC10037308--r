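.rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("degenerate Dirichlet: all concentrations must be > 0")
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

.default_dirichlet <- function(nCelltypes) {
  # subtype B is immune-hot (immune-rich, best survival), C cold/tumor-heavy.
  base <- matrix(10, nrow = 3, ncol = nCelltypes,
                 dimnames = list(c("A", "B", "C"), NULL))
  rest <- nCelltypes - 3L
  base["A", 1:3] <- c(40, 10, 20); base["A", -(1:3)] <- 30 / rest
  base["B", 1:3] <- c(15, 40, 25); base["B", -(1:3)] <- 20 / rest
  base["C", 1:3] <- c(70, 5, 5); base["C", -(1:3)] <- 20 / rest
  base * 1.5
}

.celltype_names <- function(k) {
  base <- c("Tumor", "T.cells.CD8", "T.cells.CD4", "Macrophage", "NK.cells")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, paste0("Immune.", seq_len(k - length(base))))
}

#' Simulate a bulk cohort with planted immune subtypes and survival
#'
#' Generates the generative structure the scoring pipeline assumes: a
#' genes-by-celltypes signature matrix with disjoint high-expression marker
#' blocks (cell type 1 plays the tumor compartment, the rest immune), per-sample
#' cell-type proportions drawn from a subtype-specific Dirichlet, expression as
#' the signature-weighted mixture perturbed by multiplicative log-normal noise,
#' and exponential survival with a subtype-specific hazard under independent
#' exponential censoring. Subtype B is simulated immune-hot with the most
#' favorable hazard, subtype C immune-cold with the worst, mirroring the
#' three-cluster structure the analysis is designed to recover.
#'
#' @param nSamples number of samples (default 300).
#' @param nGenes number of genes (default 1000).
#' @param nCelltypes number of cell types (>= 3, default 5).
#' @param subtypeDirichlet 3-row matrix of Dirichlet concentrations (rows
#'   subtypes A/B/C, columns cell types); default planted mixture described
#'   above.
#' @param noiseSd standard deviation of the log-normal multiplicative noise
#'   (default 0.3).
#' @param hazardBySubtype per-subtype exponential hazard per day
#'   (default `c(A = 1e-3, B = 5e-4, C = 2e-3)`).
#' @param censorRate independent exponential censoring rate (default 5e-4).
#' @param markerFold fold elevation of a marker gene in its own cell type
#'   (default 12).
#' @param markersPerType marker genes per cell type; default
#'   `min(50, nGenes %/% (2 * nCelltypes))` so marker blocks never exceed half
#'   the genes.
#' @param seed integer seed; the cohort is a pure function of the arguments.
#' @return A list of class `SyntheticCohort`: `expression`
#'   ([ICIExpression-class], TPM-like units), `clinical` (data.frame),
#'   `truthSubtype`, `truthFractions` ([FractionMatrix-class]), `signature`
#'   (genes-by-celltypes matrix) and `immuneMarkers` (markers of the immune
#'   cell types, useful to orient scores).
#' @export
simulateCohort <- function(nSamples = 300L, nGenes = 1000L, nCelltypes = 5L,
                           subtypeDirichlet = .default_dirichlet(nCelltypes),
                           noiseSd = 0.3,
                           hazardBySubtype = c(A = 1e-3, B = 5e-4, C = 2e-3),
                           censorRate = 5e-4, markerFold = 12,
                           markersPerType = NULL, seed = 2020L) {
  if (is.null(markersPerType))
    markersPerType <- max(2L, min(50L, nGenes %/% (2L * nCelltypes)))
  stopifnot(nCelltypes >= 3L, nrow(subtypeDirichlet) == 3L,
            ncol(subtypeDirichlet) == nCelltypes,
            all(hazardBySubtype > 0), markersPerType * nCelltypes <= nGenes)
  if (any(subtypeDirichlet <= 0))
    stop("degenerate Dirichlet: all concentrations must be > 0")
  set.seed(seed)
  ct <- .celltype_names(nCelltypes)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  samples <- sprintf("sample%03d", seq_len(nSamples))

  baseline <- exp(stats::rnorm(nGenes, 0, 0.5))
  sig <- matrix(baseline, nGenes, nCelltypes, dimnames = list(genes, ct))
  markerIdx <- split(seq_len(markersPerType * nCelltypes),
                     rep(seq_len(nCelltypes), each = markersPerType))
  for (c in seq_len(nCelltypes)) sig[markerIdx[[c]], c] <- baseline[markerIdx[[c]]] * markerFold

  subtype <- rep_len(c("A", "B", "C"), nSamples)
  frac <- matrix(NA_real_, nSamples, nCelltypes, dimnames = list(samples, ct))
  for (s in c("A", "B", "C")) {
    idx <- which(subtype == s)
    frac[idx, ] <- .rdirichlet(length(idx), subtypeDirichlet[s, ])
  }

  mix <- sig %*% t(frac)
  noise <- if (noiseSd > 0)
    matrix(exp(stats::rnorm(nGenes * nSamples, 0, noiseSd)), nGenes, nSamples)
  else 1
  expr <- mix * noise
  dimnames(expr) <- list(genes, samples)

  haz <- hazardBySubtype[subtype]
  tEvent <- stats::rexp(nSamples, rate = haz)
  tCens <- if (censorRate > 0) stats::rexp(nSamples, rate = censorRate) else Inf
  clinical <- data.frame(
    sample_id = samples,
    os_time = pmin(tEvent, tCens),
    os_event = as.integer(tEvent <= tCens),
    age = round(stats::runif(nSamples, 25, 80)),
    grade = sample(c("G1", "G2", "G3"), nSamples, replace = TRUE),
    stringsAsFactors = FALSE)

  structure(list(
    expression = ICIExpression(expr, unitTag = "TPM", cohort = "synthetic"),
    clinical = clinical,
    truthSubtype = stats::setNames(subtype, samples),
    truthFractions = FractionMatrix(frac),
    signature = sig,
    immuneMarkers = genes[unlist(markerIdx[-1L])]
  ), class = "SyntheticCohort")
}

#' Simulate a MAF with score-linked mutation burden
#'
#' Per-sample non-silent mutation counts are Poisson with log mean
#' `log(baseRate) + tmbSlope * z(score)`, so `tmbSlope > 0` plants a positive
#' score-TMB association. Mutated genes are drawn from a fixed catalog in which
#' the first three genes get `biasOdds`-fold sampling odds in samples above the
#' median score, creating contingency-table contrasts between score groups.
#' Each record receives a random non-silent variant class; additional Silent
#' records (Poisson mean 2 per sample) are added as TMB-neutral background.
#'
#' @param sampleIds sample identifiers, or a `SyntheticCohort`.
#' @param score per-sample numeric score aligned with `sampleIds`.
#' @param tmbSlope log-linear effect of the standardized score on the mutation
#'   rate (default 0.5).
#' @param nMutGenes catalog size (default 200).
#' @param baseRate expected non-silent mutations per sample at score 0
#'   (default 10).
#' @param biasOdds sampling-odds multiplier of the three group-biased genes in
#'   high-score samples (default 5).
#' @param seed integer seed.
#' @return A MAF-style `data.frame` (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `Variant_Classification`).
#' @export
simulateMaf <- function(sampleIds, score, tmbSlope = 0.5, nMutGenes = 200L,
                        baseRate = 10, biasOdds = 5, seed = 2020L) {
  if (inherits(sampleIds, "SyntheticCohort"))
    sampleIds <- sampleIds$clinical$sample_id
  stopifnot(length(score) == length(sampleIds))
  if (nMutGenes <= 3L) stop("nMutGenes must exceed the 3 biased catalog genes")
  set.seed(seed)
  catalog <- sprintf("MUT%03d", seq_len(nMutGenes))
  nonsilent <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
                 "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                 "Splice_Site", "Nonstop_Mutation")
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score) else score * 0
  lam <- exp(log(baseRate) + tmbSlope * z)
  high <- score > stats::median(score)
  recs <- vector("list", length(sampleIds))
  for (i in seq_along(sampleIds)) {
    k <- stats::rpois(1L, lam[i])
    w <- rep(1, nMutGenes)
    if (high[i]) w[1:3] <- biasOdds
    kSil <- stats::rpois(1L, 2)
    if (k + kSil == 0L) next
    recs[[i]] <- data.frame(
      Tumor_Sample_Barcode = rep(sampleIds[i], k + kSil),
      Hugo_Symbol = c(sample(catalog, k, replace = TRUE, prob = w),
                      sample(catalog, kSil, replace = TRUE)),
      Variant_Classification = c(sample(nonsilent, k, replace = TRUE),
                                 rep("Silent", kSil)),
      stringsAsFactors = FALSE)
  }
  maf <- do.call(rbind, recs)
  unique(maf)
}

#' Simulate per-cell QC metadata with planted low-quality cells
#'
#' Produces detected-gene counts, UMI counts and mitochondrial fractions for
#' `nCells` cells: a clean majority passing every default filter plus three
#' planted subpopulations each violating exactly one rule — too few detected
#' genes, excessive mitochondrial fraction, or low novelty
#' (log10 genes / log10 UMI).
#'
#' @param nCells total cells (default 1000).
#' @param nLowGenes planted cells with < 200 detected genes (default 30).
#' @param nHighMito planted cells with mitochondrial fraction > 0.15
#'   (default 25).
#' @param nLowNovelty planted cells with novelty < 0.8 (default 20).
#' @param mitoZero set every mitochondrial fraction to 0 (disables the mito
#'   rule's planted failures).
#' @param seed integer seed.
#' @return data.frame `cell_id`, `n_genes`, `n_umi`, `mito_fraction` with the
#'   planted counts in `attr(, "planted")`.
#' @export
simulateScMetadata <- function(nCells = 1000L, nLowGenes = 30L, nHighMito = 25L,
                               nLowNovelty = 20L, mitoZero = FALSE,
                               seed = 2020L) {
  stopifnot(nCells >= 1L, nLowGenes + nHighMito + nLowNovelty <= nCells)
  set.seed(seed)
  nGood <- nCells - nLowGenes - nHighMito - nLowNovelty
  # clean cells: genes = umi^0.85 so novelty ~ 0.85, genes >> 200, mito <= 0.10
  umiGood <- round(exp(stats::runif(nGood, log(2000), log(20000))))
  good <- data.frame(n_umi = umiGood, n_genes = round(umiGood^0.85),
                     mito_fraction = stats::runif(nGood, 0, 0.10))
  gLow <- sample(50:199, nLowGenes, replace = TRUE)
  lowGenes <- data.frame(n_umi = gLow * 2L, n_genes = gLow,
                         mito_fraction = stats::runif(nLowGenes, 0, 0.10))
  umiMito <- round(exp(stats::runif(nHighMito, log(2000), log(20000))))
  highMito <- data.frame(n_umi = umiMito, n_genes = round(umiMito^0.85),
                         mito_fraction = stats::runif(nHighMito, 0.16, 0.50))
  # novelty: log10(300)/log10(5000..20000) ~ 0.60-0.67 < 0.8, genes >= 200
  umiNov <- round(exp(stats::runif(nLowNovelty, log(5000), log(20000))))
  lowNov <- data.frame(n_umi = umiNov, n_genes = 300L,
                       mito_fraction = stats::runif(nLowNovelty, 0, 0.10))
  cells <- rbind(good, lowGenes, highMito, lowNov)
  if (mitoZero) cells$mito_fraction <- 0
  ord <- sample.int(nrow(cells))
  cells <- cells[ord, ]
  cells <- data.frame(cell_id = sprintf("cell%04d", seq_len(nCells)), cells,
                      row.names = NULL)
  attr(cells, "planted") <- list(
    lowGenes = nLowGenes, highMito = if (mitoZero) 0L else nHighMito,
    lowNovelty = nLowNovelty)
  cells
}
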