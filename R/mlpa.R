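## MLPA comparator: Coffalyser-style fragment ratio analysis. Probe signals
## are normalized within each sample against its reference probes, then
## across samples against the normal controls in the same run; ratios
## < 0.75 flag copy number loss and > 1.33 flag gain, each confirmed by a
## Welch two-sample t-test against the control profiles (P < 0.05).

#' Normalize MLPA probe signals
#'
#' Quality control first: a sample whose mean control-fragment signal falls
#' below `qcFloor` times the run median is excluded (insufficient DNA or
#' failed ligation). Then, per sample and replicate, every gene/flank probe
#' signal is divided by the mean of that replicate's reference-probe
#' signals (intra-sample step, removing the sample's overall signal
#' level); finally each probe's value is divided by the mean of the same
#' quantity over the run's control samples (inter-sample step), so a
#' diploid probe sits near ratio 1.
#'
#' @param run an MLPA run as produced by [simulateMlpaRun()] (list with
#'   `signals`, `design`, `controls`) or an equivalent structure read from
#'   TSV.
#' @param qcFloor control-fragment QC floor as a fraction of the run
#'   median (default 0.4).
#' @return list with `ratios` (long data.frame: `sample`, `role`,
#'   `replicate`, `probe`, `label`, `ratio`), `perSample` (sample x probe
#'   matrix of replicate-mean ratios), `controls`, and `excluded`
#'   (data.frame of QC-failed samples with reasons).
#' @export
mlpaNormalize <- function(run, qcFloor = 0.4) {
  sig <- run$signals; design <- run$design
  ctrlFrag <- design$probe[design$role == "control_fragment"]
  refProbes <- design$probe[design$role == "reference"]
  if (!length(refProbes)) stop("run design has no reference probes")
  if (!length(run$controls)) stop("run has no control samples")
  qc <- tapply(sig$signal[sig$probe %in% ctrlFrag],
               sig$sample[sig$probe %in% ctrlFrag], mean)
  floorVal <- qcFloor * median(qc)
  failed <- names(qc)[qc < floorVal]
  excluded <- data.frame(sample = failed,
                         reason = rep("control_fragment_qc_failure",
                                      length(failed)))
  sig <- sig[!sig$sample %in% failed, , drop = FALSE]
  controls <- setdiff(run$controls, failed)
  if (!length(controls))
    stop("all control samples failed control-fragment QC")
  target <- design$probe[design$role %in% c("gene", "flank")]
  key <- paste(sig$sample, sig$replicate)
  refMean <- tapply(sig$signal[sig$probe %in% refProbes],
                    key[sig$probe %in% refProbes], mean)
  gs <- sig[sig$probe %in% target, , drop = FALSE]
  gs$intra <- gs$signal / as.numeric(refMean[paste(gs$sample,
                                                   gs$replicate)])
  ctrlRows <- gs$sample %in% controls
  ctrlMean <- tapply(gs$intra[ctrlRows], gs$probe[ctrlRows], mean)
  gs$ratio <- gs$intra / as.numeric(ctrlMean[gs$probe])
  gs$label <- design$label[match(gs$probe, design$probe)]
  ratios <- gs[, c("sample", "role", "replicate", "probe", "label",
                   "ratio")]
  rownames(ratios) <- NULL
  perSample <- tapply(ratios$ratio, list(ratios$sample, ratios$probe),
                      mean)
  list(ratios = ratios, perSample = perSample, controls = controls,
       excluded = excluded)
}

#' Classify MLPA probe ratios into loss / normal / gain
#'
#' A probe is flagged as copy-number loss when its replicate-mean ratio is
#' below `lossMax` (default 0.75) and as gain when above `gainMin`
#' (default 1.33), in each case only if a Welch two-sample t-test of the
#' sample's replicate ratios against the control samples' ratios for that
#' probe reaches `alpha` (default 0.05). With a single control sample the
#' test is impossible and classification falls back to the ratio
#' thresholds alone (noted in the result).
#'
#' @param norm output of [mlpaNormalize()].
#' @param lossMax,gainMin ratio thresholds.
#' @param alpha t-test significance level.
#' @return data.frame with one row per study sample x gene/flank probe:
#'   `sample`, `probe`, `label`, `ratio`, `p_value` (`NA` when ratio-only),
#'   `class` (`loss` / `normal` / `gain`), and attribute `ratio_only`
#'   (logical scalar).
#' @export
mlpaClassify <- function(norm, lossMax = 0.75, gainMin = 1.33,
                         alpha = 0.05) {
  ratios <- norm$ratios
  controls <- norm$controls
  ratioOnly <- length(controls) < 2L
  study <- unique(ratios$sample[ratios$role == "study"])
  probes <- unique(ratios$probe)
  out <- vector("list", length(study) * length(probes))
  k <- 0L
  for (sid in study) {
    for (pr in probes) {
      mine <- ratios$ratio[ratios$sample == sid & ratios$probe == pr]
      ctrl <- ratios$ratio[ratios$sample %in% controls &
                             ratios$probe == pr]
      r <- mean(mine)
      p <- NA_real_
      if (!ratioOnly && length(mine) >= 2L && length(ctrl) >= 2L)
        p <- tryCatch(t.test(mine, ctrl)$p.value,
                      error = function(e) NA_real_)
      crossed <- if (r < lossMax) "loss"
                 else if (r > gainMin) "gain" else "normal"
      cls <- crossed
      if (crossed != "normal" && !ratioOnly &&
          (is.na(p) || p >= alpha)) cls <- "normal"
      k <- k + 1L
      out[[k]] <- data.frame(sample = sid, probe = pr,
                             label = ratios$label[ratios$probe == pr][1],
                             ratio = r, p_value = p, class = cls)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ratio_only") <- ratioOnly
  res
}

#' Per-sample CNV status from MLPA probe classes
#'
#' @param classified output of [mlpaClassify()].
#' @param geneOnly restrict to gene probes, ignoring the flanking probe
#'   (default `TRUE`).
#' @return named logical vector: `TRUE` when any probe of the sample is
#'   classified loss or gain.
#' @export
mlpaSampleStatus <- function(classified, geneOnly = TRUE) {
  df <- classified
  if (geneOnly) df <- df[!is.na(df$label), , drop = FALSE]
  pos <- tapply(df$class != "normal", df$sample, any)
  setNames(as.logical(pos), names(pos))
}
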