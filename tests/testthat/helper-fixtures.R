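# fixtures are built in code at test time; nothing is stored on disk

write_expr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_maf_fixture <- function(records, path = tempfile(fileext = ".maf")) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# MAF data.frame with `mut` samples of `group` carrying one missense record in
# `gene`; used to reconstruct printed contingency tables exactly
contingency_maf <- function(gene, highMut, lowMut, highN, lowN) {
  ids <- c(sprintf("H%03d", seq_len(highN)), sprintf("L%03d", seq_len(lowN)))
  groups <- stats::setNames(rep(c("high", "low"), c(highN, lowN)), ids)
  carriers <- c(sprintf("H%03d", seq_len(highMut)), sprintf("L%03d", seq_len(lowMut)))
  maf <- data.frame(Tumor_Sample_Barcode = carriers, Hugo_Symbol = gene,
                    Variant_Classification = "Missense_Mutation",
                    stringsAsFactors = FALSE)
  list(maf = maf, groups = groups)
}

# small deterministic expression matrix
toy_expr <- function(nGenes = 6, nSamples = 4, seed = 1, unit = "TPM") {
  set.seed(seed)
  m <- matrix(stats::rexp(nGenes * nSamples, 0.1), nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  ICIExpression(m, unitTag = unit)
}

# exponential survival table
surv_clinical <- function(times, events, ids = sprintf("p%03d", seq_along(times))) {
  data.frame(sample_id = ids, os_time = times, os_event = events,
             stringsAsFactors = FALSE)
}
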