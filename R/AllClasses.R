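#' CoverageExperiment: per-target mean depth of coverage for a sample set
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one assay, `"depth"`: a targets x samples matrix of mean
#' depth-of-coverage values (reads per base, non-negative). Rows are the panel
#' target regions (a `GRanges` with `gene`, `label`, `gc` and `index`
#' metadata columns, see [ldlrPanel()]); columns are samples.
#'
#' @slot .Data inherited `RangedSummarizedExperiment` structure.
#' @seealso [CoverageExperiment()], [readCoverage()], [docMatrix()]
#' @export
setClass("CoverageExperiment", contains = "RangedSummarizedExperiment")

setValidity("CoverageExperiment", function(object) {
  msg <- character()
  if (!"depth" %in% assayNames(object))
    msg <- c(msg, "assay 'depth' is required")
  else {
    d <- assay(object, "depth")
    if (!is.numeric(d))
      msg <- c(msg, "'depth' assay must be numeric")
    else if (any(!is.finite(d)) || any(d < 0))
      msg <- c(msg, "'depth' assay must be finite and non-negative")
  }
  rd <- rowData(object)
  need <- c("gene", "label", "gc", "index")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(miss)) {
    for (g in unique(rd$gene)) {
      lab <- rd$label[rd$gene == g]
      if (anyDuplicated(lab))
        msg <- c(msg, paste0("duplicate target label within gene ", g))
    }
    if (any(rd$gc < 0 | rd$gc > 1))
      msg <- c(msg, "gc fractions must lie in [0, 1]")
  }
  if (is.null(colnames(object)))
    msg <- c(msg, "samples must be named (colnames)")
  if (length(msg)) msg else TRUE
})

#' Reference control set matched to one test sample
#'
#' Result of [selectReferences()]: the `k` pool controls with the smallest
#' percent difference in normalized coverage relative to the test sample.
#' A sample whose mean percent difference to its selected controls exceeds
#' the flag threshold is flagged as poorly matched.
#'
#' @slot sample test sample identifier.
#' @slot controls ordered identifiers of the selected controls.
#' @slot percentDifference named numeric, percent difference per selected
#'   control (ordered as `controls`).
#' @slot meanPercentDifference mean percent difference over the selection.
#' @slot flagged `TRUE` when `meanPercentDifference` exceeds the threshold.
#' @slot flagThreshold the threshold used (percent).
#' @export
setClass("ReferenceSet",
  representation(sample = "character", controls = "character",
                 percentDifference = "numeric",
                 meanPercentDifference = "numeric",
                 flagged = "logical", flagThreshold = "numeric"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@controls))
    msg <- c(msg, "controls must be pairwise distinct")
  if (object@sample %in% object@controls)
    msg <- c(msg, "the test sample cannot be its own control")
  if (length(object@percentDifference) != length(object@controls))
    msg <- c(msg, "one percent difference per control is required")
  if (length(object@meanPercentDifference) == 1 &&
      is.finite(object@meanPercentDifference) &&
      object@meanPercentDifference < 0)
    msg <- c(msg, "mean percent difference must be >= 0")
  if (!identical(object@flagged,
                 object@meanPercentDifference > object@flagThreshold))
    msg <- c(msg, "flagged must equal meanPercentDifference > flagThreshold")
  if (length(msg)) msg else TRUE
})

#' Matching configuration
#'
#' @slot k number of matched reference controls to select (default 30).
#' @slot poolMin minimum advisable pool size (default 100); selection
#'   proceeds for any pool of size >= `k`, but a smaller pool than `poolMin`
#'   is reported in the run metadata.
#' @slot flagThreshold percent difference above which a sample is flagged as
#'   poorly matched (default 20).
#' @seealso [matchConfig()]
#' @export
setClass("MatchConfig",
  representation(k = "integer", poolMin = "integer",
                 flagThreshold = "numeric"))

setValidity("MatchConfig", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (object@flagThreshold <= 0) msg <- c(msg, "flagThreshold must be > 0")
  if (length(msg)) msg else TRUE
})

#' Caller configuration: state model and filtration thresholds
#'
#' @slot delRatioMax maximum mean ratio for a deletion to pass filtration
#'   (default 0.7).
#' @slot delZMax maximum mean z-score for a deletion to pass (default -5.0).
#' @slot dupRatioMin minimum mean ratio for a duplication to pass
#'   (default 1.30).
#' @slot dupZMin minimum mean z-score for a duplication to pass (default 5.0).
#' @slot statePriors prior probabilities over the four copy-number states
#'   `diploid`, `het_del`, `hom_del`, `dup`; must sum to 1.
#' @slot stateMeans expected coverage ratio per state (1, 0.5, 0.02, 1.5).
#'   The homozygous-deletion mean is kept slightly above zero so its
#'   likelihood stays proper at nonzero noise.
#' @slot emissionSd ratio spread of the Gaussian emission (default 0.08).
#' @slot vafWeight likelihood multiplier applied when VAF evidence speaks for
#'   a duplication or against a deletion (default 4).
#' @seealso [callerConfig()], [assignStates()], [filterEvents()]
#' @export
setClass("CallerConfig",
  representation(delRatioMax = "numeric", delZMax = "numeric",
                 dupRatioMin = "numeric", dupZMin = "numeric",
                 statePriors = "numeric", stateMeans = "numeric",
                 emissionSd = "numeric", vafWeight = "numeric"))

setValidity("CallerConfig", function(object) {
  msg <- character()
  states <- c("diploid", "het_del", "hom_del", "dup")
  if (!identical(names(object@statePriors), states))
    msg <- c(msg, "statePriors must be named diploid, het_del, hom_del, dup")
  else if (abs(sum(object@statePriors) - 1) > 1e-9)
    msg <- c(msg, "statePriors must sum to 1")
  if (!identical(names(object@stateMeans), states))
    msg <- c(msg, "stateMeans must be named diploid, het_del, hom_del, dup")
  if (object@emissionSd <= 0) msg <- c(msg, "emissionSd must be > 0")
  if (object@vafWeight < 1) msg <- c(msg, "vafWeight must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for a synthetic panel cohort
#'
#' Describes the statistical regime the synthetic cohort emulates: a
#' high-coverage targeted panel (~300x mean DOC) with overdispersed count
#' noise, per-sample library-size variation, a smooth GC-content bias, and
#' CNVs implanted at copy numbers 0, 1 or 3 over contiguous target spans.
#'
#' @slot nSamples number of samples (>= 2).
#' @slot meanDepth cohort mean depth of coverage, reads/base (default 300).
#' @slot dispersion negative-binomial overdispersion of per-target total
#'   coverage (variance = mu + dispersion * mu^2; Poisson as it tends to 0).
#' @slot gcBiasStrength strength of the multiplicative GC factor
#'   `exp(-strength * (gc - 0.45)^2 / (2 * 0.1^2))`; 0 disables it.
#' @slot gcJitterSd per-sample lognormal jitter of the GC strength
#'   (default 0: a shared GC response).
#' @slot librarySizeSd sd of per-sample log library-size factors.
#' @slot snpDensity expected heterozygous SNPs per target (Poisson).
#' @slot implants data.frame with columns `sample`, `copy_number` (0, 1 or
#'   3), `first_label`, `last_label`.
#' @slot sampleIds sample identifiers (length `nSamples`).
#' @slot seed integer seed; identical seeds give bit-identical output.
#' @seealso [simulationConfig()], [simulateCohort()], [table2Cohort()]
#' @export
setClass("SimulationConfig",
  representation(nSamples = "integer", meanDepth = "numeric",
                 dispersion = "numeric", gcBiasStrength = "numeric",
                 gcJitterSd = "numeric", librarySizeSd = "numeric",
                 snpDensity = "numeric", implants = "data.frame",
                 sampleIds = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@librarySizeSd < 0) msg <- c(msg, "librarySizeSd must be >= 0")
  if (object@gcBiasStrength < 0) msg <- c(msg, "gcBiasStrength must be >= 0")
  if (length(object@sampleIds) != object@nSamples)
    msg <- c(msg, "sampleIds must have length nSamples")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  imp <- object@implants
  need <- c("sample", "copy_number", "first_label", "last_label")
  if (!all(need %in% colnames(imp)))
    msg <- c(msg, paste0("implants needs columns ",
                         paste(need, collapse = ", ")))
  else {
    if (!all(imp$copy_number %in% c(0L, 1L, 3L)))
      msg <- c(msg, "implanted copy numbers must be 0, 1 or 3")
    if (!all(imp$sample %in% object@sampleIds))
      msg <- c(msg, "implant sample not among sampleIds")
  }
  if (length(msg)) msg else TRUE
})

#' 2x2 contingency table of CNV call concordance
#'
#' Per-sample agreement between a test call set and a reference call set
#' (or the simulated truth): true/false positives and negatives plus the
#' derived sensitivity and specificity in percent (`NA` when the respective
#' denominator is zero).
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @slot sensitivity `100 * tp / (tp + fn)` (percent), `NA` if `tp + fn == 0`.
#' @slot specificity `100 * tn / (tn + fp)` (percent), `NA` if `tn + fp == 0`.
#' @seealso [contingency()], [chiSquare()]
#' @export
setClass("ContingencyTable",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer", sensitivity = "numeric",
                 specificity = "numeric"))

setValidity("ContingencyTable", function(object) {
  msg <- character()
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@tp + object@fn > 0) {
    want <- 100 * object@tp / (object@tp + object@fn)
    if (abs(object@sensitivity - want) > 1e-9)
      msg <- c(msg, "sensitivity inconsistent with tp/(tp+fn)")
  }
  if (object@tn + object@fp > 0) {
    want <- 100 * object@tn / (object@tn + object@fp)
    if (abs(object@specificity - want) > 1e-9)
      msg <- c(msg, "specificity inconsistent with tn/(tn+fp)")
  }
  if (length(msg)) msg else TRUE
})
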