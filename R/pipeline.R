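#' End-to-end ICI scoring on an in-memory cohort
#'
#' Runs the full scoring chain: immune-fraction deconvolution, consensus
#' clustering of the fraction profiles into `kIci` ICI clusters, one-vs-rest
#' DEGs between the clusters, consensus clustering of the DEG expression into
#' two gene clusters (relabelled A/B by decreasing size), the signature-gene
#' split, optional shadow-feature reduction per side, per-side PC1 scores, the
#' ICI score (PC1A - PC1B), and high/low stratification at the maximally
#' selected log-rank cutoff.
#'
#' Because the A/B gene-cluster labels come from unsupervised clustering, the
#' global sign of the score is arbitrary. When `orientBy` (any per-sample
#' immune-content covariate, e.g. an immune ssGSEA score) is supplied and the
#' score anti-correlates with it, the A/B designation is swapped so "high ICI"
#' means immune-rich.
#'
#' @param expr [ICIExpression-class] in TPM or FPKM (FPKM is converted).
#' @param clinical clinical table (see [validateClinical()]).
#' @param signature genes-by-celltypes signature matrix for deconvolution, or
#'   a precomputed [FractionMatrix-class].
#' @param kIci number of ICI clusters (default 3).
#' @param reps consensus resampling iterations (default 1000).
#' @param fcThresh,pThresh DEG thresholds (defaults 1 and 0.05).
#' @param boruta apply [borutaSelect()] to each signature side (default
#'   FALSE).
#' @param orientBy optional named per-sample numeric used to orient the score.
#' @param floor,nPermCutoff passed to [optimalCutoff()].
#' @param seed integer seed governing every randomized stage.
#' @return list: `fractions`, `iciClusters` ([ConsensusResult-class]), `degs`,
#'   `geneClusters`, `split` (`SignatureSplit`), `scores`
#'   ([ICIScores-class]), `logrank` (high vs low), `oriented` (TRUE when the
#'   A/B designation was swapped).
#' @export
scoreCohort <- function(expr, clinical, signature, kIci = 3L, reps = 1000L,
                        fcThresh = 1, pThresh = 0.05, boruta = FALSE,
                        orientBy = NULL, floor = 0.1, nPermCutoff = 0L,
                        seed = 2020L) {
  stopifnot(methods::is(expr, "ICIExpression"))
  if (unitTag(expr) == "FPKM") expr <- fpkmToTpm(expr)
  clinical <- validateClinical(clinical)

  fr <- if (methods::is(signature, "FractionMatrix")) signature
        else estimateFractions(expr, signature, nPerm = 0L, seed = seed)

  ici <- consensusMatrix(fractions(fr), k = kIci, reps = reps, seed = seed + 1L)
  logExpr <- if (unitTag(expr) == "LOG2TPM") exprValues(expr)
             else log2(exprValues(expr) + 1)
  degs <- sharedDegs(logExpr, clusterLabels(ici), fcThresh = fcThresh,
                     pThresh = pThresh)
  if (length(degs) < 4L) stop("too few DEGs (", length(degs), ") to build a signature")

  gc <- consensusMatrix(t(logExpr[degs, , drop = FALSE]), k = 2L, reps = reps,
                        seed = seed + 2L)
  gcLab <- c("A", "B")[clusterLabels(gc)]
  split <- assignSignatureGenes(logExpr, degs, gcLab)

  if (boruta) {
    feat <- t(logExpr[c(split$genesA, split$genesB), , drop = FALSE])
    bs <- borutaSelect(feat, gcLab, seed = seed + 3L)
    keepA <- intersect(split$genesA, bs$confirmed)
    keepB <- intersect(split$genesB, bs$confirmed)
    # fall back to the full side when reduction leaves too little signal
    if (length(keepA) >= 2L) split$genesA <- keepA
    if (length(keepB) >= 2L) split$genesB <- keepB
    split$boruta <- bs
  }

  pcA <- if (length(split$genesA) >= 2L) pc1Scores(logExpr, split$genesA) else NULL
  pcB <- if (length(split$genesB) >= 2L) pc1Scores(logExpr, split$genesB) else NULL
  if (is.null(pcA) && is.null(pcB)) stop("both signature sides degenerate")
  if (is.null(pcA)) { pcA <- pcB; pcB <- NULL; split[c("genesA", "genesB")] <- split[c("genesB", "genesA")] }

  oriented <- FALSE
  if (!is.null(orientBy)) {
    sc <- iciScore(pcA, pcB)
    ob <- orientBy[names(sc)]
    r <- suppressWarnings(stats::cor(sc, ob, method = "spearman"))
    if (!is.na(r) && r < 0) {
      oriented <- TRUE
      split[c("genesA", "genesB")] <- split[c("genesB", "genesA")]
      tmp <- pcA; pcA <- if (is.null(pcB)) -tmp else pcB
      pcB <- if (is.null(pcB)) NULL else tmp
    }
  }

  scores <- dichotomize(pcA, pcB, clinical, floor = floor,
                        nPerm = nPermCutoff, seed = seed + 4L)
  grp <- scoreGroups(scores)
  cl <- clinical[match(names(grp), clinical$sample_id), ]
  lr <- logrank(cl$os_time, cl$os_event, grp)

  list(fractions = fr, iciClusters = ici, degs = degs, geneClusters = gc,
       split = split, scores = scores, logrank = lr, oriented = oriented)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline from a configuration and write per-stage outputs
#'
#' Accepts a configuration list (or path to a YAML file with the same keys):
#' `expression` (path), `unit` (`FPKM`/`TPM`), `clinical` (path), `signature`
#' (path to a genes-by-celltypes TSV), optional `maf` (path), and optional
#' stage parameters `k_ici`, `reps`, `fc_thresh`, `p_thresh`, `boruta`,
#' `floor`, `seed`. All input files are validated before any stage runs;
#' stages then execute in order (deconvolution, ICI clusters, DEGs, gene
#' clusters, ICI score, survival, mutation) and each writes a TSV under
#' `outdir`, plus a `run_log.txt` recording the seed and parameters. A stage
#' failure aborts with the stage name and cause.
#'
#' @param config list or YAML path.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the [scoreCohort()] result list (plus `mutation` when a
#'   MAF was supplied).
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("expression", "clinical", "signature")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
  paths <- c(config$expression, config$clinical, config$signature, config$maf)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) stop("input file(s) not found: ",
                           paste(absent, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 2020L)

  stage <- function(name, f) tryCatch(f(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  expr <- stage("read_expression", function()
    readExpression(config$expression, unitTag = config$unit %||% "TPM"))
  clinical <- stage("read_clinical", function()
    validateClinical(utils::read.delim(config$clinical)))
  sig <- stage("read_signature", function() {
    s <- utils::read.delim(config$signature, row.names = 1L, check.names = FALSE)
    as.matrix(s)
  })

  res <- stage("scoring", function()
    scoreCohort(expr, clinical, sig,
                kIci = as.integer(config$k_ici %||% 3L),
                reps = as.integer(config$reps %||% 1000L),
                fcThresh = config$fc_thresh %||% 1,
                pThresh = config$p_thresh %||% 0.05,
                boruta = isTRUE(config$boruta),
                floor = config$floor %||% 0.1, seed = seed))

  fr <- fractions(res$fractions)
  .write_tsv(data.frame(sample_id = rownames(fr), fr, check.names = FALSE),
             file.path(outdir, "fractions.tsv"))
  .write_tsv(data.frame(sample_id = names(clusterLabels(res$iciClusters)),
                        ici_cluster = clusterLabels(res$iciClusters)),
             file.path(outdir, "ici_clusters.tsv"))
  .write_tsv(data.frame(gene_id = res$degs), file.path(outdir, "degs.tsv"))
  .write_tsv(data.frame(sample_id = names(res$split$labels),
                        gene_cluster = res$split$labels),
             file.path(outdir, "gene_clusters.tsv"))
  sc <- res$scores
  .write_tsv(data.frame(sample_id = sc@sampleIds, pc1_A = sc@pc1A,
                        pc1_B = sc@pc1B, ici_score = sc@score,
                        group = sc@group, cutoff = sc@cutoff),
             file.path(outdir, "ici_scores.tsv"))
  .write_tsv(data.frame(test = "logrank_high_vs_low", chi2 = res$logrank$chi2,
                        df = res$logrank$df, p = res$logrank$p),
             file.path(outdir, "survival.tsv"))

  if (!is.null(config$maf)) {
    maf <- stage("read_maf", function() readMaf(config$maf))
    mut <- stage("mutation", function() {
      tmb <- computeTmb(maf, sc@sampleIds)
      list(tmb = tmb,
           table = mutatedGeneTable(maf, scoreGroups(sc)),
           assoc = tmbScoreAssociation(tmb[sc@sampleIds], sc@score))
    })
    .write_tsv(data.frame(sample_id = names(mut$tmb), tmb = mut$tmb),
               file.path(outdir, "tmb.tsv"))
    .write_tsv(mut$table, file.path(outdir, "mutation_table.tsv"))
    res$mutation <- mut
  }

  writeLines(c(sprintf("seed: %d", seed),
               sprintf("k_ici: %s", config$k_ici %||% 3L),
               sprintf("reps: %s", config$reps %||% 1000L),
               sprintf("fc_thresh: %s", config$fc_thresh %||% 1),
               sprintf("p_thresh: %s", config$p_thresh %||% 0.05),
               sprintf("boruta: %s", isTRUE(config$boruta)),
               sprintf("n_degs: %d", length(res$degs)),
               sprintf("logrank_p: %.6g", res$logrank$p)),
             file.path(outdir, "run_log.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
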