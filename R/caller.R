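#' Caller configuration
#'
#' Defaults encode the published filtration gate (deletions: mean ratio
#' <= 0.7 and mean z <= -5.0; duplications: mean ratio >= 1.30 and mean
#' z >= 5.0) and a four-state naive-Bayes emission model over the coverage
#' ratio with means 1 (diploid), 0.5 (heterozygous deletion), 0.02
#' (homozygous deletion) and 1.5 (duplication).
#'
#' @param delRatioMax,delZMax,dupRatioMin,dupZMin filtration thresholds.
#' @param statePriors named prior probabilities (sum 1) over `diploid`,
#'   `het_del`, `hom_del`, `dup`.
#' @param stateMeans named expected ratios per state.
#' @param emissionSd Gaussian ratio spread (default 0.08).
#' @param vafWeight VAF evidence likelihood multiplier (default 4).
#' @return a [CallerConfig-class].
#' @export
callerConfig <- function(delRatioMax = 0.7, delZMax = -5.0,
                         dupRatioMin = 1.30, dupZMin = 5.0,
                         statePriors = c(diploid = 0.97, het_del = 0.015,
                                         hom_del = 0.0025, dup = 0.0125),
                         stateMeans = c(diploid = 1.0, het_del = 0.5,
                                        hom_del = 0.02, dup = 1.5),
                         emissionSd = 0.08, vafWeight = 4) {
  new("CallerConfig", delRatioMax = delRatioMax, delZMax = delZMax,
      dupRatioMin = dupRatioMin, dupZMin = dupZMin,
      statePriors = statePriors, stateMeans = stateMeans,
      emissionSd = emissionSd, vafWeight = vafWeight)
}

.states <- c("diploid", "het_del", "hom_del", "dup")

#' Assign per-target copy-number state posteriors
#'
#' For each informative target (finite ratio, weight > 0) the posterior
#' over `diploid` / `het_del` / `hom_del` / `dup` is proportional to
#' `prior * Normal(ratio | mu_state, emissionSd)^weight * vaf_term`, where
#' the VAF term divides the two deletion states by `vafWeight` when the
#' target's VAF evidence argues against a deletion, and multiplies the
#' duplication state by `vafWeight` when it supports one. Down-weighted
#' targets (weight 0.5) contribute flattened likelihoods; weight-0 targets
#' are skipped.
#'
#' @param metrics per-target metrics from [targetMetrics()].
#' @param cfg a [callerConfig()].
#' @return data.frame with one row per informative target: `gene`,
#'   `label`, `index`, `ratio`, `z`, `vaf_class`, posterior columns
#'   `p_diploid`, `p_het_del`, `p_hom_del`, `p_dup` (each row sums to 1)
#'   and the argmax `state`.
#' @export
assignStates <- function(metrics, cfg = callerConfig()) {
  keep <- is.finite(metrics$ratio) & metrics$weight > 0
  m <- metrics[keep, , drop = FALSE]
  n <- nrow(m)
  post <- matrix(NA_real_, n, 4L, dimnames = list(NULL, .states))
  for (i in seq_len(n)) {
    ll <- dnorm(m$ratio[i], mean = cfg@stateMeans,
                sd = cfg@emissionSd, log = TRUE) * m$weight[i]
    lp <- ll + log(cfg@statePriors)
    if (m$vaf_class[i] == "against_deletion")
      lp[c("het_del", "hom_del")] <-
        lp[c("het_del", "hom_del")] - log(cfg@vafWeight)
    else if (m$vaf_class[i] == "supports_duplication")
      lp["dup"] <- lp["dup"] + log(cfg@vafWeight)
    lp <- lp - max(lp)
    post[i, ] <- exp(lp) / sum(exp(lp))
  }
  out <- data.frame(gene = m$gene, label = m$label, index = m$index,
                    ratio = m$ratio, z = m$z, vaf_class = m$vaf_class,
                    p_diploid = post[, "diploid"],
                    p_het_del = post[, "het_del"],
                    p_hom_del = post[, "hom_del"],
                    p_dup = post[, "dup"],
                    state = .states[max.col(post, ties.method = "first")],
                    row.names = NULL)
  out
}

#' Merge contiguous same-state targets into CNV events
#'
#' Maximal runs of consecutive targets (panel indices differing by exactly
#' 1, within one gene) sharing a non-diploid state become one event; a
#' diploid, discordant or skipped target always breaks a run — gaps are
#' never bridged. Event-level `mean_ratio` and `mean_z` are arithmetic
#' means over the run's targets, the convention used for reporting
#' multi-target events.
#'
#' @param states output of [assignStates()].
#' @param sample sample identifier recorded in the events.
#' @return calls data.frame (zero rows when the sample is all-diploid)
#'   with an additional `per_target` list column holding each event's
#'   per-target `(label, ratio, z, vaf_class)`.
#' @export
segmentStates <- function(states, sample = "sample") {
  events <- .emptyCalls()
  events$per_target <- list()
  if (!nrow(states)) return(events)
  states <- states[order(states$gene, states$index), , drop = FALSE]
  newrun <- c(TRUE, states$gene[-1] != states$gene[-nrow(states)] |
                    states$state[-1] != states$state[-nrow(states)] |
                    diff(states$index) != 1L)
  run <- cumsum(newrun)
  rows <- list(); pt <- list()
  for (r in unique(run)) {
    sel <- which(run == r)
    st <- states$state[sel[1]]
    if (st == "diploid") next
    vcl <- states$vaf_class[sel]
    support <-
      if (st == "dup" && any(vcl == "supports_duplication")) "supports"
      else if (st != "dup" && any(vcl == "against_deletion")) "against"
      else "neutral"
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample, gene = states$gene[sel[1]], type = st,
      first_label = states$label[sel[1]],
      last_label = states$label[sel[length(sel)]],
      n_targets = length(sel),
      mean_ratio = mean(states$ratio[sel]),
      mean_z = mean(states$z[sel]),
      vaf_support = support, passes_filter = NA,
      filter_reason = NA_character_)
    pt[[length(pt) + 1L]] <- states[sel, c("label", "ratio", "z",
                                           "vaf_class")]
  }
  if (!length(rows)) return(events)
  out <- do.call(rbind, rows)
  out$per_target <- pt
  rownames(out) <- NULL
  out
}

#' Apply ratio / z-score filtration to CNV events
#'
#' Mutually inclusive thresholds: a deletion (het or hom) passes iff
#' `mean_ratio <= delRatioMax` **and** `mean_z <= delZMax`; a duplication
#' passes iff `mean_ratio >= dupRatioMin` **and** `mean_z >= dupZMin`.
#' A deletion event containing VAF evidence against deletion
#' (`vaf_support == "against"`) is demoted to fail regardless of its
#' metrics, with the reason recorded.
#'
#' @param events calls data.frame (needs `type`, `mean_ratio`, `mean_z`;
#'   `vaf_support` honoured when present).
#' @param cfg a [callerConfig()].
#' @return `events` with `passes_filter` and `filter_reason` filled in.
#' @export
filterEvents <- function(events, cfg = callerConfig()) {
  if (!nrow(events)) {
    events$passes_filter <- logical(0)
    events$filter_reason <- character(0)
    return(events)
  }
  pass <- logical(nrow(events))
  reason <- rep(NA_character_, nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$type == "dup") {
      okr <- e$mean_ratio >= cfg@dupRatioMin
      okz <- e$mean_z >= cfg@dupZMin
      pass[i] <- okr && okz
      if (!pass[i])
        reason[i] <- paste(c(if (!okr) "ratio_below_dup_min",
                             if (!okz) "z_below_dup_min"), collapse = ";")
    } else {
      okr <- e$mean_ratio <= cfg@delRatioMax
      okz <- e$mean_z <= cfg@delZMax
      pass[i] <- okr && okz
      if (!pass[i])
        reason[i] <- paste(c(if (!okr) "ratio_above_del_max",
                             if (!okz) "z_above_del_max"), collapse = ";")
      if (pass[i] && !is.null(events$vaf_support) &&
          isTRUE(e$vaf_support == "against")) {
        pass[i] <- FALSE
        reason[i] <- "vaf_contradiction"
      }
    }
  }
  events$passes_filter <- pass
  events$filter_reason <- reason
  events
}

#' Call CNVs for one sample
#'
#' End-to-end composition for a single test sample: matched reference
#' selection, normalization and GC correction, per-target metrics, state
#' assignment, segmentation and filtration.
#'
#' @param cov [CoverageExperiment] containing the test sample.
#' @param pool [CoverageExperiment] control pool.
#' @param sampleId test sample identifier.
#' @param vafs optional VAF observations ([extractVafs()] layout).
#' @param matchCfg a [matchConfig()].
#' @param callerCfg a [callerConfig()].
#' @param allEvents return failed events too (default `FALSE`).
#' @param weightOverrides optional named target weights.
#' @return list with `events` (calls data.frame), `metrics`, `states`,
#'   and `referenceSet`.
#' @export
callSample <- function(cov, pool, sampleId, vafs = NULL,
                       matchCfg = matchConfig(),
                       callerCfg = callerConfig(), allEvents = FALSE,
                       weightOverrides = NULL) {
  refs <- selectReferences(cov, pool, sampleId, matchCfg)
  metrics <- targetMetrics(cov, pool, refs, vafs,
                           weightOverrides = weightOverrides)
  states <- assignStates(metrics, callerCfg)
  events <- segmentStates(states, sample = sampleId)
  events <- filterEvents(events, callerCfg)
  if (!allEvents) events <- events[events$passes_filter, , drop = FALSE]
  list(events = events, metrics = metrics, states = states,
       referenceSet = refs)
}

#' Call CNVs across a cohort
#'
#' Runs [callSample()] for every sample of `cov` against the shared control
#' pool and binds the resulting events.
#'
#' @inheritParams callSample
#' @param gene optional gene symbol; events are restricted to it.
#' @return list with `calls` (events of all samples, without the
#'   `per_target` column) and `flags` (per-sample mean percent difference
#'   and matching flag).
#' @export
callCohort <- function(cov, pool, vafs = NULL, matchCfg = matchConfig(),
                       callerCfg = callerConfig(), gene = NULL,
                       allEvents = FALSE, weightOverrides = NULL) {
  samples <- colnames(cov)
  calls <- list(); flags <- list()
  for (sid in samples) {
    res <- callSample(cov, pool, sid, vafs, matchCfg, callerCfg,
                      allEvents = allEvents,
                      weightOverrides = weightOverrides)
    ev <- res$events
    ev$per_target <- NULL
    if (!is.null(gene)) ev <- ev[ev$gene == gene, , drop = FALSE]
    calls[[sid]] <- ev
    flags[[sid]] <- data.frame(
      sample = sid,
      mean_percent_difference = res$referenceSet@meanPercentDifference,
      flagged = res$referenceSet@flagged)
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls)) calls <- .emptyCalls()
  rownames(calls) <- NULL
  flags <- do.call(rbind, flags)
  rownames(flags) <- NULL
  list(calls = calls, flags = flags)
}

#' Per-sample CNV status from a call table
#'
#' @param calls calls data.frame.
#' @param samples the full sample universe (so CNV-free samples appear).
#' @param gene optional gene restriction.
#' @return named logical vector: `TRUE` when the sample has at least one
#'   passing event.
#' @export
sampleStatus <- function(calls, samples, gene = NULL) {
  ev <- calls
  if (!is.null(gene) && nrow(ev)) ev <- ev[ev$gene == gene, , drop = FALSE]
  if (nrow(ev) && "passes_filter" %in% colnames(ev))
    ev <- ev[is.na(ev$passes_filter) | ev$passes_filter, , drop = FALSE]
  setNames(samples %in% ev$sample, samples)
}
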