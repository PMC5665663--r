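## Per-target evidence metrics against the matched reference set:
## ratio  = sample coverage / mean reference coverage   (~1 diploid,
##          ~0.5 heterozygous deletion, ~1.5 duplication)
## z      = (sample - reference mean) / reference sd    (n-1 denominator)
## plus a categorical summary of the VAF evidence in the target.

#' Coverage ratio for one target
#'
#' @param sampleDepth corrected depth of the test sample at the target.
#' @param refDepths corrected depths of the matched controls at the target
#'   (length >= 2).
#' @return `sampleDepth / mean(refDepths)`; `NA` (target uninformative)
#'   when the reference mean is zero.
#' @examples
#' computeRatio(150, c(300, 310, 290))  # ~0.5, the het-deletion regime
#' @export
computeRatio <- function(sampleDepth, refDepths) {
  if (length(refDepths) < 2L) stop("need >= 2 reference depths")
  m <- mean(refDepths)
  if (m <= 0) return(NA_real_)
  sampleDepth / m
}

#' Coverage z-score for one target
#'
#' Number of reference-control standard deviations separating the sample's
#' corrected depth from the reference mean. The test sample never enters
#' the reference statistics.
#'
#' @param sampleDepth corrected depth of the test sample at the target.
#' @param refDepths corrected depths of the matched controls (length >= 3).
#' @return `(sampleDepth - mean(refDepths)) / sd(refDepths)`; `NA` when the
#'   reference sd is zero (target uninformative).
#' @examples
#' computeZ(80, c(90, 100, 110))  # -2
#' @export
computeZ <- function(sampleDepth, refDepths) {
  if (length(refDepths) < 3L) stop("need >= 3 reference depths")
  s <- sd(refDepths)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (sampleDepth - mean(refDepths)) / s
}

#' Classify the VAF evidence within one target
#'
#' A heterozygous SNP near 0.5 means both haplotypes are present, which
#' argues against any deletion. Fractions near 1/3 or 2/3 are the allele
#' balance of a heterozygous site on a triploid segment, supporting a
#' duplication. The bands (0.40-0.60 for "het", 0.25-0.40 and 0.60-0.75
#' for "duplication-like") separate 1/2 from 1/3 and 2/3 under binomial
#' noise at site depths of 20+ reads.
#'
#' @param altFractions numeric vector of alt-allele fractions observed in
#'   the target (possibly empty).
#' @return `"against_deletion"`, `"supports_duplication"`, or `"neutral"`.
#' @export
vafClass <- function(altFractions) {
  af <- altFractions[!is.na(altFractions)]
  if (!length(af)) return("neutral")
  if (any(af >= 0.40 & af <= 0.60)) return("against_deletion")
  if (any((af >= 0.25 & af < 0.40) | (af > 0.60 & af <= 0.75)))
    return("supports_duplication")
  "neutral"
}

#' Per-target metrics for one sample against its matched references
#'
#' Applies [gcCorrect()] using the matched controls, computes
#' [computeRatio()] and [computeZ()] per target, attaches
#' [mappabilityWeights()] and the per-target [vafClass()]. A second
#' normalization pass then re-anchors the sample on its diploid-looking
#' targets (ratio within 0.15 of 1, requiring at least a third of the
#' panel): on a small single-gene panel a multi-target CNV biases the
#' sample's library-size factor toward itself, and the re-anchoring
#' restores ratios of ~0.5 / ~1.0 / ~1.5 for CN 1/2/3.
#'
#' @param cov [CoverageExperiment] with the test sample.
#' @param pool [CoverageExperiment] with the control pool.
#' @param refs [ReferenceSet-class] for the sample (see
#'   [selectReferences()]).
#' @param vafs VAF observations data.frame ([extractVafs()] layout) —
#'   rows for other samples are ignored; may be `NULL`.
#' @param weightOverrides optional named weights (see
#'   [mappabilityWeights()]).
#' @param gcBinWidth GC bin width for the correction (default 0.05).
#' @param cvThreshold control-CV threshold for down-weighting (default 0.3).
#' @return data.frame with one row per target: `gene`, `label`, `index`,
#'   `gc`, `ratio`, `z`, `n_refs`, `weight`, `vaf_class`. Targets with
#'   weight 0 or undefined metrics carry `NA` and are skipped downstream.
#' @export
targetMetrics <- function(cov, pool, refs, vafs = NULL,
                          weightOverrides = NULL, gcBinWidth = 0.05,
                          cvThreshold = 0.3) {
  panel <- rowRanges(cov)
  sid <- refs@sample
  d <- docMatrix(cov)
  p <- docMatrix(pool)
  miss <- setdiff(refs@controls, colnames(p))
  if (length(miss))
    stop("matched control(s) absent from the pool: ",
         paste(miss, collapse = ", "))
  combined <- cbind(d[, sid, drop = FALSE],
                    p[, refs@controls, drop = FALSE])
  sf <- coverageSizeFactors(combined)
  norm <- sweep(combined, 2, sf, "/")
  gcc <- gcCorrect(norm[, 1L], norm[, -1L, drop = FALSE],
                   mcols(panel)$gc, binWidth = gcBinWidth)
  w <- mappabilityWeights(gcc$controlCorrected, cvThreshold = cvThreshold,
                          overrides = weightOverrides)
  nT <- length(panel)
  computeAll <- function(testVec) {
    ratio <- z <- rep(NA_real_, nT)
    for (t in seq_len(nT)) {
      if (w[t] == 0) next
      ratio[t] <- computeRatio(testVec[t], gcc$controlCorrected[t, ])
      z[t] <- computeZ(testVec[t], gcc$controlCorrected[t, ])
    }
    list(ratio = ratio, z = z)
  }
  m <- computeAll(gcc$corrected)
  # Second pass: re-anchor on diploid-looking targets. On a small panel a
  # multi-target CNV drags the median-of-ratios size factor toward itself,
  # deflating (deletion) or inflating (duplication) every ratio; the
  # median ratio over targets near 1 recovers the diploid baseline.
  dipLike <- is.finite(m$ratio) & abs(m$ratio - 1) <= 0.15
  if (sum(dipLike) >= max(5L, nT %/% 3L)) {
    anchor <- median(m$ratio[dipLike])
    if (is.finite(anchor) && anchor > 0)
      m <- computeAll(gcc$corrected / anchor)
  }
  ratio <- m$ratio; z <- m$z
  vclass <- rep("neutral", nT)
  if (!is.null(vafs) && nrow(vafs)) {
    vs <- vafs[vafs$sample == sid, , drop = FALSE]
    if (nrow(vs)) {
      key <- paste(vs$gene, vs$label, sep = ":")
      for (t in seq_len(nT)) {
        hit <- key == names(panel)[t]
        if (any(hit)) vclass[t] <- vafClass(vs$alt_fraction[hit])
      }
    }
  }
  data.frame(gene = mcols(panel)$gene, label = mcols(panel)$label,
             index = mcols(panel)$index, gc = mcols(panel)$gc,
             ratio = ratio, z = z, n_refs = length(refs@controls),
             weight = as.numeric(w), vaf_class = vclass,
             row.names = NULL)
}
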