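.read_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    quote = "", comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a genes-by-samples expression table
#'
#' Expects a TSV/CSV with gene identifiers in the first column and sample
#' identifiers in the header. Duplicate gene rows are collapsed by their mean.
#' A non-numeric or missing cell is a parse error reported with its gene and
#' sample coordinates.
#'
#' @param path path to the table.
#' @param unitTag unit of the stored values (`"FPKM"`, `"TPM"`, `"LOG2TPM"`).
#' @param cohort cohort label to attach to every sample.
#' @return An [ICIExpression-class] object.
#' @export
readExpression <- function(path, unitTag = c("TPM", "FPKM", "LOG2TPM"),
                           cohort = "cohort1") {
  unitTag <- match.arg(unitTag)
  df <- .read_table(path)
  if (ncol(df) < 2L) stop("malformed expression table: need gene column plus >= 1 sample")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (nrow(df) == 0L) stop("empty expression matrix in ", path)
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                   genes[bad[1L]], samples[j], df[[j + 1L]][bad[1L]]))
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(vals) <- genes
  ICIExpression(vals, unitTag = unitTag, cohort = cohort)
}

#' Write an expression object to TSV
#'
#' Inverse of [readExpression()]: gene ids in the first column (`gene_id`),
#' sample ids in the header.
#'
#' @param x an [ICIExpression-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  v <- exprValues(x)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM expression to TPM
#'
#' Rescales every sample so its values sum to one million:
#' \eqn{TPM_{gs} = FPKM_{gs} / \sum_g FPKM_{gs} \times 10^6}. This is the
#' within-sample renormalization that makes FPKM cohorts comparable with TPM
#' cohorts.
#'
#' @param x an [ICIExpression-class] with `unitTag == "FPKM"`.
#' @return An [ICIExpression-class] in TPM.
#' @export
fpkmToTpm <- function(x) {
  stopifnot(methods::is(x, "ICIExpression"))
  if (unitTag(x) != "FPKM") stop("fpkmToTpm expects unitTag FPKM, got ", unitTag(x))
  v <- exprValues(x)
  cs <- colSums(v)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(v)[cs <= 0], collapse = ", "))
  ICIExpression(sweep(v, 2L, cs, "/") * 1e6, unitTag = "TPM",
                cohort = cohortLabels(x))
}

#' Merge expression cohorts on shared genes with within-cohort standardization
#'
#' Restricts all cohorts to their common genes, transforms to
#' \eqn{\log_2(TPM + 1)}, z-scores each gene within each cohort (removing
#' cohort-level location/scale differences), and concatenates the samples.
#' Genes with zero variance inside any cohort cannot be standardized and are
#' dropped with a message.
#'
#' @param cohorts list of [ICIExpression-class] objects in TPM (FPKM input is
#'   converted first).
#' @return An [ICIExpression-class] with `unitTag == "LOG2TPM"`, cohort labels
#'   preserved per sample.
#' @export
mergeCohorts <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2L)
  cohorts <- lapply(cohorts, function(x) {
    if (unitTag(x) == "FPKM") fpkmToTpm(x)
    else if (unitTag(x) == "TPM") x
    else stop("mergeCohorts expects FPKM or TPM cohorts")
  })
  genes <- Reduce(intersect, lapply(cohorts, function(x) rownames(exprValues(x))))
  if (length(genes) == 0L) stop("empty gene intersection across cohorts")
  allSamples <- unlist(lapply(cohorts, function(x) colnames(exprValues(x))))
  if (anyDuplicated(allSamples))
    stop("duplicate sample id across cohorts: ",
         paste(unique(allSamples[duplicated(allSamples)]), collapse = ", "))
  mats <- lapply(cohorts, function(x) log2(exprValues(x)[genes, , drop = FALSE] + 1))
  sds <- lapply(mats, function(m) apply(m, 1L, stats::sd))
  keep <- Reduce(`&`, lapply(sds, function(s) s > 0))
  if (!all(keep))
    message(sum(!keep), " gene(s) with zero within-cohort variance dropped before z-scoring")
  if (!any(keep)) stop("no genes with nonzero variance in every cohort")
  zmats <- mapply(function(m, s) {
    m <- m[keep, , drop = FALSE]
    (m - rowMeans(m)) / s[keep]
  }, mats, sds, SIMPLIFY = FALSE)
  merged <- do.call(cbind, zmats)
  cohortLab <- unlist(lapply(cohorts, function(x) unname(cohortLabels(x))))
  ICIExpression(merged, unitTag = "LOG2TPM", cohort = cohortLab)
}

.MAF_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site", "Silent", "Intron",
  "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA",
  "Targeted_Region", "Splice_Region")

#' Read a MAF somatic mutation table
#'
#' Parses a tab-separated MAF requiring at least `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification`; extra columns are
#' ignored, `#`-comment lines skipped, and fully duplicated records removed
#' with a warning. Variant classes outside the MAF controlled vocabulary raise
#' a warning.
#'
#' @param path path to the MAF file.
#' @return A `data.frame` with columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `Variant_Classification`.
#' @export
readMaf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("MAF missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df)) {
    warning(sum(duplicated(df)), " fully duplicated MAF record(s) removed")
    df <- unique(df)
  }
  unknown <- setdiff(unique(df$Variant_Classification), .MAF_CLASSES)
  if (length(unknown))
    warning("variant classification(s) outside the MAF vocabulary: ",
            paste(unknown, collapse = ", "))
  rownames(df) <- NULL
  df[, c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")]
}

#' Write a MAF table
#' @param maf data.frame as returned by [readMaf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(maf, path) {
  utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1L])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Validate a clinical table
#'
#' Checks the contract every survival stage relies on: unique `sample_id`,
#' non-negative `os_time` (days), `os_event` in \{0, 1\}; `age` and `grade`
#' optional.
#'
#' @param clinical a data.frame.
#' @return The table, invisibly, with `sample_id` as character.
#' @export
validateClinical <- function(clinical) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(clinical))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  clinical$sample_id <- as.character(clinical$sample_id)
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(!is.finite(clinical$os_time)) || any(clinical$os_time < 0))
    stop("os_time must be finite and non-negative")
  if (!all(clinical$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  invisible(clinical)
}
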