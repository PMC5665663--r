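## Cross-sample normalization: library-size factors, GC-bias correction
## estimated from matched reference controls, and variability-based target
## weights standing in for a mappability track.

#' Median-of-ratios library-size factors
#'
#' For each target, a pseudo-reference is built as the geometric mean of its
#' depth across samples; a sample's factor is the median over targets of the
#' ratio of its depth to the pseudo-reference, rescaled so the factors have
#' median 1. Robust to a CNV in any one sample (unlike total-count
#' scaling): a deletion shifts a minority of a sample's ratios, not its
#' median.
#'
#' @param depth numeric matrix, targets x samples (or a
#'   [CoverageExperiment]).
#' @return named numeric vector of size factors (median 1).
#' @export
coverageSizeFactors <- function(depth) {
  if (is(depth, "CoverageExperiment")) depth <- docMatrix(depth)
  depth <- as.matrix(depth)
  if (ncol(depth) < 2L) stop("size factors need at least 2 samples")
  zero <- colSums(depth) == 0
  if (any(zero))
    stop("sample(s) with all-zero coverage: ",
         paste(colnames(depth)[zero], collapse = ", "))
  pos <- rowSums(depth > 0) == ncol(depth)  # DESeq convention: all-positive
  if (!any(pos))
    stop("no target is covered in every sample; size factors undefined")
  logref <- rowMeans(log(depth[pos, , drop = FALSE]))
  f <- apply(depth[pos, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logref)))
  f / median(f)
}

## GC-bin correction factors estimated from control depths.
## Factor per target = (median control depth in the target's GC bin) /
## (global median control depth); bins narrower than 2 targets fall back
## to 1 (no correction).
.gcBinFactors <- function(controlDepth, gc, binWidth = 0.05) {
  bin <- floor(gc / binWidth)
  global <- median(controlDepth)
  if (!is.finite(global) || global <= 0)
    return(rep(1, length(gc)))
  fac <- rep(1, length(gc))
  for (b in unique(bin)) {
    sel <- which(bin == b)
    if (length(sel) < 2L) next       # sparse bin: no correction
    fac[sel] <- median(controlDepth[sel]) / global
  }
  fac
}

#' GC-content bias correction
#'
#' Estimates a per-GC-bin multiplicative correction from the matched
#' reference controls and applies it to the test sample and the controls
#' alike: targets are grouped into GC bins of width `binWidth`, each bin's
#' factor is the ratio of the bin's median control depth to the global
#' median control depth, and depths are divided by their target's factor.
#' Bins holding fewer than two targets get no correction. After division
#' each sample is rescaled so its median depth is unchanged — the
#' correction reshapes the profile across GC, never the overall depth.
#'
#' Inputs should already be library-size normalized (see
#' [coverageSizeFactors()]).
#'
#' @param testDepth numeric vector of the test sample's normalized depths
#'   (one per target), or a targets x samples matrix.
#' @param controlDepth targets x controls matrix of normalized control
#'   depths from which the correction is estimated.
#' @param gc per-target GC fractions.
#' @param binWidth GC bin width (default 0.05).
#' @return list with `corrected` (same shape as `testDepth`),
#'   `controlCorrected` (matrix), and `factors` (per-target correction).
#' @export
gcCorrect <- function(testDepth, controlDepth, gc, binWidth = 0.05) {
  controlDepth <- as.matrix(controlDepth)
  if (nrow(controlDepth) != length(gc))
    stop("controlDepth rows must match the number of targets")
  fac <- .gcBinFactors(rowMeans(controlDepth), gc, binWidth)
  rescale <- function(pre, post) {  # conserve the sample's median depth
    m <- median(post)
    if (is.finite(m) && m > 0) post * (median(pre) / m) else post
  }
  corr <- if (is.matrix(testDepth)) {
    post <- sweep(testDepth, 1, fac, "/")
    for (j in seq_len(ncol(post)))
      post[, j] <- rescale(testDepth[, j], post[, j])
    post
  } else rescale(testDepth, testDepth / fac)
  ctrlPost <- sweep(controlDepth, 1, fac, "/")
  for (j in seq_len(ncol(ctrlPost)))
    ctrlPost[, j] <- rescale(controlDepth[, j], ctrlPost[, j])
  list(corrected = corr, controlCorrected = ctrlPost, factors = fac)
}

#' Target weights from reference-control variability
#'
#' Targets that behave erratically across the matched controls (capture
#' dropout, ambiguous mapping) are down-weighted: a target whose control
#' coefficient of variation exceeds `cvThreshold` gets weight 0.5, all
#' others weight 1. A weight of 0 — settable only through `overrides` —
#' excludes a target from state evidence entirely.
#'
#' @param controlDepth targets x controls matrix of corrected control
#'   depths.
#' @param cvThreshold coefficient-of-variation threshold (default 0.3).
#' @param overrides optional named numeric vector (target name -> weight in
#'   `[0, 1]`) taking precedence over the computed weights.
#' @return numeric vector of weights in `[0, 1]`, named by target when the
#'   matrix has rownames.
#' @export
mappabilityWeights <- function(controlDepth, cvThreshold = 0.3,
                               overrides = NULL) {
  controlDepth <- as.matrix(controlDepth)
  mu <- rowMeans(controlDepth)
  sdv <- apply(controlDepth, 1, sd)
  cv <- ifelse(mu > 0, sdv / mu, Inf)
  w <- ifelse(cv > cvThreshold, 0.5, 1)
  names(w) <- rownames(controlDepth)
  if (!is.null(overrides)) {
    if (any(overrides < 0 | overrides > 1))
      stop("weight overrides must lie in [0, 1]")
    hit <- intersect(names(overrides), names(w))
    w[hit] <- overrides[hit]
  }
  w
}

#' Read a target weight override file
#'
#' Two-column TSV: target name (`gene:label`) and weight in `[0, 1]`.
#'
#' @param path TSV path.
#' @param panel panel `GRanges`; unknown targets raise an error.
#' @return named numeric vector usable as `overrides` in
#'   [mappabilityWeights()].
#' @export
readTargetWeights <- function(path, panel) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("weight file needs two columns: target, weight")
  w <- as.numeric(df[[2L]])
  names(w) <- df[[1L]]
  bad <- setdiff(names(w), names(panel))
  if (length(bad))
    stop("weight file names unknown target(s): ",
         paste(bad, collapse = ", "))
  w
}
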