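#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.UNIT_TAGS <- c("FPKM", "TPM", "LOG2TPM")

#' Container for a genes-by-samples bulk expression matrix
#'
#' `ICIExpression` extends [SummarizedExperiment::SummarizedExperiment] with a
#' declared expression unit (`FPKM`, `TPM` or `LOG2TPM`) and a per-sample
#' cohort label. All pipeline stages consume and return this container so that
#' units and cohort membership travel with the values.
#'
#' Validity requires unique, non-empty gene and sample identifiers, finite
#' values throughout, and non-negative values unless the unit is `LOG2TPM`
#' (cohort standardization produces signed values).
#'
#' @name ICIExpression-class
#' @aliases ICIExpression-class
#' @exportClass ICIExpression
setClass("ICIExpression", contains = "SummarizedExperiment")

setValidity("ICIExpression", function(object) {
  msg <- character()
  x <- SummarizedExperiment::assay(object, withDimnames = TRUE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "gene and sample identifiers are required")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    msg <- c(msg, "duplicate gene identifiers")
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    msg <- c(msg, "duplicate sample identifiers")
  if (!all(is.finite(x)))
    msg <- c(msg, "all expression values must be finite")
  tag <- S4Vectors::metadata(object)$unitTag
  if (is.null(tag) || !tag %in% .UNIT_TAGS)
    msg <- c(msg, "metadata()$unitTag must be one of FPKM, TPM, LOG2TPM")
  else if (tag != "LOG2TPM" && any(x < 0))
    msg <- c(msg, sprintf("negative values are not allowed for unit %s", tag))
  if (!"cohort" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry a 'cohort' column")
  if (length(msg)) msg else TRUE
})

#' Construct an ICIExpression object
#'
#' @param values numeric genes-by-samples matrix with row and column names.
#' @param unitTag expression unit: `"FPKM"`, `"TPM"` or `"LOG2TPM"`.
#' @param cohort per-sample cohort label, recycled if length 1.
#' @return An [ICIExpression-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ICIExpression(m, unitTag = "TPM")
#' @export
ICIExpression <- function(values, unitTag = c("TPM", "FPKM", "LOG2TPM"),
                          cohort = "cohort1") {
  unitTag <- match.arg(unitTag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cohort <- rep_len(as.character(cohort), ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(cohort = cohort, row.names = colnames(values)),
    metadata = list(unitTag = unitTag)
  )
  methods::new("ICIExpression", se)
}

#' Per-sample immune cell fraction estimates
#'
#' Rows are samples, columns cell types; every row lies on the unit simplex.
#' `permP` carries the per-sample permutation p-value of the deconvolution fit
#' (`NA` when permutations were not run).
#'
#' @name FractionMatrix-class
#' @aliases FractionMatrix-class
#' @exportClass FractionMatrix
setClass("FractionMatrix",
  representation(fractions = "matrix", permP = "numeric"))

setValidity("FractionMatrix", function(object) {
  f <- object@fractions
  msg <- character()
  if (any(f < -1e-12)) msg <- c(msg, "fractions must be non-negative")
  if (any(abs(rowSums(f) - 1) > 1e-9))
    msg <- c(msg, "fraction rows must sum to 1 (tolerance 1e-9)")
  p <- object@permP
  if (length(p) != nrow(f)) msg <- c(msg, "permP must have one entry per sample")
  if (any(!is.na(p) & (p < 0 | p > 1))) msg <- c(msg, "permP must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname FractionMatrix-class
#' @param fractions samples-by-celltypes matrix, rows on the simplex.
#' @param permP per-sample permutation p-values (default all `NA`).
#' @export
FractionMatrix <- function(fractions, permP = rep(NA_real_, nrow(fractions))) {
  obj <- methods::new("FractionMatrix", fractions = as.matrix(fractions),
                      permP = as.numeric(permP))
  methods::validObject(obj)
  obj
}

#' Result of resampled consensus clustering
#'
#' Holds the symmetric samples-by-samples consensus matrix (entry ij = share of
#' co-sampled resamples in which i and j co-clustered), the cluster labels from
#' cutting the consensus tree at `k`, the proportion of ambiguous clustering
#' (PAC), the area under the consensus CDF, and the count of sample pairs that
#' were never co-sampled (their consensus entries are `NA`, never silently 0).
#'
#' @name ConsensusResult-class
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(k = "integer", consensus = "matrix", labels = "integer",
                 pac = "numeric", cdfArea = "numeric",
                 neverCoSampled = "integer"))

setValidity("ConsensusResult", function(object) {
  cm <- object@consensus
  msg <- character()
  if (nrow(cm) != ncol(cm)) msg <- c(msg, "consensus matrix must be square")
  if (!isTRUE(all.equal(cm, t(cm), tolerance = 1e-12)))
    msg <- c(msg, "consensus matrix must be symmetric")
  v <- cm[!is.na(cm)]
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    msg <- c(msg, "consensus entries must lie in [0, 1]")
  if (length(object@labels) != nrow(cm))
    msg <- c(msg, "one label per sample required")
  if (length(msg)) msg else TRUE
})

#' Per-sample ICI scores and high/low stratification
#'
#' Stores the two signature-side PC1 values, their difference (the ICI score),
#' the survival-derived cutoff and the resulting high/low group per sample.
#'
#' @name ICIScores-class
#' @aliases ICIScores-class
#' @exportClass ICIScores
setClass("ICIScores",
  representation(sampleIds = "character", pc1A = "numeric", pc1B = "numeric",
                 score = "numeric", group = "character", cutoff = "numeric"))

setValidity("ICIScores", function(object) {
  n <- length(object@sampleIds)
  msg <- character()
  if (length(object@pc1A) != n || length(object@pc1B) != n ||
      length(object@score) != n || length(object@group) != n)
    msg <- c(msg, "all per-sample slots must share one length")
  if (any(abs(object@score - (object@pc1A - object@pc1B)) > 1e-8))
    msg <- c(msg, "score must equal pc1A - pc1B")
  if (!all(object@group %in% c("high", "low")))
    msg <- c(msg, "group must be 'high' or 'low'")
  ok <- ifelse(object@score > object@cutoff, "high", "low")
  if (!identical(ok, object@group))
    msg <- c(msg, "group must follow score > cutoff (ties low)")
  if (length(msg)) msg else TRUE
})

ICIScores <- function(sampleIds, pc1A, pc1B, cutoff) {
  score <- pc1A - pc1B
  obj <- methods::new("ICIScores", sampleIds = as.character(sampleIds),
                      pc1A = as.numeric(pc1A), pc1B = as.numeric(pc1B),
                      score = as.numeric(score),
                      group = unname(ifelse(score > cutoff, "high", "low")),
                      cutoff = as.numeric(cutoff))
  methods::validObject(obj)
  obj
}
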