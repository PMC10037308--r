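#' Accessors for icikit classes
#'
#' `exprValues()` returns the genes-by-samples matrix, `unitTag()` the declared
#' expression unit, `cohortLabels()` the per-sample cohort; `fractions()` and
#' `permP()` access a [FractionMatrix-class]; `consensus()`, `clusterLabels()`
#' and `pac()` access a [ConsensusResult-class]; `iciScores()` and
#' `scoreGroups()` access an [ICIScores-class].
#'
#' @param x an icikit object.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))
#' @rdname accessors
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("pac", function(x) standardGeneric("pac"))
#' @rdname accessors
#' @export
setGeneric("iciScores", function(x) standardGeneric("iciScores"))
#' @rdname accessors
#' @export
setGeneric("scoreGroups", function(x) standardGeneric("scoreGroups"))

#' @rdname accessors
setMethod("exprValues", "ICIExpression", function(x)
  SummarizedExperiment::assay(x, "expr"))
#' @rdname accessors
setMethod("unitTag", "ICIExpression", function(x)
  S4Vectors::metadata(x)$unitTag)
#' @rdname accessors
setMethod("cohortLabels", "ICIExpression", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$cohort, colnames(x)))

#' @rdname accessors
setMethod("fractions", "FractionMatrix", function(x) x@fractions)
#' @rdname accessors
setMethod("permP", "FractionMatrix", function(x)
  stats::setNames(x@permP, rownames(x@fractions)))

#' @rdname accessors
setMethod("consensus", "ConsensusResult", function(x) x@consensus)
#' @rdname accessors
setMethod("clusterLabels", "ConsensusResult", function(x)
  stats::setNames(x@labels, rownames(x@consensus)))
#' @rdname accessors
setMethod("pac", "ConsensusResult", function(x) x@pac)

#' @rdname accessors
setMethod("iciScores", "ICIScores", function(x)
  stats::setNames(x@score, x@sampleIds))
#' @rdname accessors
setMethod("scoreGroups", "ICIScores", function(x)
  stats::setNames(x@group, x@sampleIds))

setMethod("show", "ICIExpression", function(object) {
  cat(sprintf("ICIExpression: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), unitTag(object)))
  cat("cohorts:", paste(sprintf("%s (%d)", names(table(cohortLabels(object))),
                                table(cohortLabels(object))), collapse = ", "), "\n")
})

setMethod("show", "FractionMatrix", function(object) {
  f <- object@fractions
  cat(sprintf("FractionMatrix: %d samples x %d cell types\n", nrow(f), ncol(f)))
  cat("cell types:", paste(colnames(f), collapse = ", "), "\n")
  if (any(!is.na(object@permP)))
    cat(sprintf("permutation p < 0.05 in %d/%d samples\n",
                sum(object@permP < 0.05, na.rm = TRUE), nrow(f)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k = %d, %d samples, PAC = %.3f, CDF area = %.3f\n",
              object@k, nrow(object@consensus), object@pac, object@cdfArea))
  cat("cluster sizes:", paste(table(object@labels), collapse = ", "), "\n")
  if (object@neverCoSampled > 0L)
    cat(sprintf("note: %d pairs never co-sampled (NA consensus)\n",
                object@neverCoSampled))
})

setMethod("show", "ICIScores", function(object) {
  cat(sprintf("ICIScores: %d samples, cutoff = %.4g (high: %d, low: %d)\n",
              length(object@score), object@cutoff,
              sum(object@group == "high"), sum(object@group == "low")))
})
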