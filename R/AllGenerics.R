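#' Depth-of-coverage matrix accessor
#'
#' @param x a [CoverageExperiment].
#' @return numeric matrix, targets x samples.
#' @export
setGeneric("docMatrix", function(x) standardGeneric("docMatrix"))

#' @rdname docMatrix
#' @export
setMethod("docMatrix", "CoverageExperiment",
          function(x) assay(x, "depth"))

#' @describeIn CoverageExperiment-class compact display.
#' @param object a `CoverageExperiment`.
#' @export
setMethod("show", "CoverageExperiment", function(object) {
  cat("CoverageExperiment:", nrow(object), "targets x",
      ncol(object), "samples\n")
  rd <- rowData(object)
  cat("  genes:", paste(unique(rd$gene), collapse = ", "), "\n")
  d <- assay(object, "depth")
  cat(sprintf("  mean depth: %.1f (range %.1f-%.1f)\n",
              mean(d), min(d), max(d)))
})

#' @describeIn ReferenceSet-class compact display.
#' @param object a `ReferenceSet`.
#' @export
setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet for sample", object@sample, "\n")
  cat(sprintf("  %d matched controls, mean percent difference %.2f%%%s\n",
              length(object@controls), object@meanPercentDifference,
              if (object@flagged) " [FLAGGED]" else ""))
})

#' @describeIn ContingencyTable-class 2x2 display with sensitivity and
#'   specificity.
#' @param object a `ContingencyTable`.
#' @export
setMethod("show", "ContingencyTable", function(object) {
  cat("2x2 contingency (test vs reference)\n")
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n",
              object@tp, object@fp, object@fn, object@tn))
  fmt <- function(x) if (is.na(x)) "N/A" else sprintf("%.1f%%", x)
  cat("  sensitivity:", fmt(object@sensitivity),
      " specificity:", fmt(object@specificity), "\n")
})

#' Matched-control identifiers of a ReferenceSet
#' @param object a [ReferenceSet].
#' @return character vector of control identifiers.
#' @export
setGeneric("refControls", function(object) standardGeneric("refControls"))

#' @rdname refControls
#' @export
setMethod("refControls", "ReferenceSet", function(object) object@controls)

#' Mean percent difference of a ReferenceSet
#' @param object a [ReferenceSet].
#' @return numeric scalar (percent).
#' @export
setGeneric("meanPercentDifference",
           function(object) standardGeneric("meanPercentDifference"))

#' @rdname meanPercentDifference
#' @export
setMethod("meanPercentDifference", "ReferenceSet",
          function(object) object@meanPercentDifference)

#' Poor-match flag of a ReferenceSet
#' @param object a [ReferenceSet].
#' @return logical scalar.
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))

#' @rdname isFlagged
#' @export
setMethod("isFlagged", "ReferenceSet", function(object) object@flagged)

#' Counts of a ContingencyTable
#' @param object a [ContingencyTable].
#' @return named integer vector `tp`, `fp`, `fn`, `tn`.
#' @export
setGeneric("tableCounts", function(object) standardGeneric("tableCounts"))

#' @rdname tableCounts
#' @export
setMethod("tableCounts", "ContingencyTable", function(object)
  c(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn))

#' Sensitivity of a ContingencyTable (percent)
#' @param object a [ContingencyTable].
#' @return numeric scalar, `NA` when undefined.
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "ContingencyTable",
          function(object) object@sensitivity)

#' Specificity of a ContingencyTable (percent)
#' @param object a [ContingencyTable].
#' @return numeric scalar, `NA` when undefined.
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname specificity
#' @export
setMethod("specificity", "ContingencyTable",
          function(object) object@specificity)
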