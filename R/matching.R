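#' Matching configuration
#'
#' @param k number of matched reference controls (default 30).
#' @param poolMin advisable minimum control pool size (default 100).
#' @param flagThreshold mean percent difference (in %) above which a test
#'   sample is flagged as poorly matched (default 20).
#' @return a [MatchConfig-class] object.
#' @export
matchConfig <- function(k = 30, poolMin = 100, flagThreshold = 20) {
  new("MatchConfig", k = as.integer(k), poolMin = as.integer(poolMin),
      flagThreshold = as.numeric(flagThreshold))
}

#' Symmetric percent difference between two coverage profiles
#'
#' Mean over targets of `|a - b| / ((a + b) / 2) * 100`. Symmetric in its
#' arguments, zero iff the vectors are identical, and scale-dependent only
#' through the per-target relative differences — both profiles should be
#' library-size normalized first (as [selectReferences()] does). Targets
#' where both depths are zero carry no information and are excluded.
#'
#' @param a,b numeric depth vectors of equal length.
#' @return percent difference (numeric scalar).
#' @examples
#' percentDifference(c(100, 200), c(100, 100))  # mean(0, 66.67) = 33.33
#' @export
percentDifference <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (!length(a)) stop("empty coverage vectors")
  if (any(a < 0) || any(b < 0)) stop("depths must be non-negative")
  denom <- (a + b) / 2
  keep <- denom > 0
  if (!any(keep)) stop("all targets have zero depth in both profiles")
  mean(abs(a[keep] - b[keep]) / denom[keep]) * 100
}

#' Select matched reference controls for a test sample
#'
#' Each candidate control is library-size normalized to the test sample by
#' its pairwise median depth ratio (median-of-ratios against the test
#' profile), the [percentDifference()] between the test profile and the
#' scaled control is computed, and the `k` controls with the smallest
#' difference are kept. The pairwise normalization makes each control's
#' distance depend only on that pair, so adding or removing unrelated pool
#' members never perturbs the ranking of the rest. Ties are broken by pool
#' order, so selection is deterministic. The sample is flagged when the
#' mean percent difference over the selected controls exceeds
#' `cfg@flagThreshold` — the signature of a sample whose coverage profile
#' no control matches well.
#'
#' @param cov [CoverageExperiment] containing the test sample.
#' @param pool [CoverageExperiment] of candidate controls (the test sample
#'   is excluded if present).
#' @param sampleId test sample identifier (a column of `cov`).
#' @param cfg a [matchConfig()].
#' @return a [ReferenceSet-class].
#' @export
selectReferences <- function(cov, pool, sampleId, cfg = matchConfig()) {
  d <- docMatrix(cov)
  if (!sampleId %in% colnames(d))
    stop("sample '", sampleId, "' not found in the coverage matrix")
  p <- docMatrix(pool)
  p <- p[, setdiff(colnames(p), sampleId), drop = FALSE]
  if (ncol(p) < cfg@k)
    stop("control pool has ", ncol(p), " samples but k = ", cfg@k,
         " matched references are required")
  test <- d[, sampleId]
  pd <- vapply(seq_len(ncol(p)), function(j) {
    ctrl <- p[, j]
    both <- test > 0 & ctrl > 0
    if (!any(both))
      stop("control ", colnames(p)[j], " shares no covered target with ",
           sampleId)
    f <- median(ctrl[both] / test[both])
    percentDifference(test, ctrl / f)
  }, numeric(1))
  names(pd) <- colnames(p)
  sel <- order(pd)[seq_len(cfg@k)]   # stable: ties keep pool order
  mpd <- mean(pd[sel])
  new("ReferenceSet", sample = sampleId, controls = colnames(p)[sel],
      percentDifference = pd[sel], meanPercentDifference = mpd,
      flagged = mpd > cfg@flagThreshold, flagThreshold = cfg@flagThreshold)
}
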