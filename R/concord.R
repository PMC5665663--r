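## Diagnostic concordance between two per-sample call sets: 2x2
## contingency with sensitivity/specificity, Pearson chi-square, and
## summary statistics over a call table.

#' 2x2 contingency of test calls against reference calls
#'
#' Both arguments are named logical vectors over the *same* sample
#' universe (`TRUE` = sample carries at least one passing CNV). The
#' reference set defines truth: `tp` counts samples positive in both.
#'
#' @param test named logical vector of test-method status.
#' @param reference named logical vector of reference-method (or truth)
#'   status.
#' @return a [ContingencyTable-class].
#' @examples
#' s <- c(a = TRUE, b = FALSE, c = FALSE)
#' contingency(s, s)      # perfect concordance
#' @export
contingency <- function(test, reference) {
  if (is.null(names(test)) || is.null(names(reference)))
    stop("both call sets must be named by sample")
  extraT <- setdiff(names(test), names(reference))
  extraR <- setdiff(names(reference), names(test))
  if (length(extraT) || length(extraR))
    stop("sample universes differ; only in test: ",
         paste(extraT, collapse = ", "), "; only in reference: ",
         paste(extraR, collapse = ", "))
  test <- test[names(reference)]
  tp <- sum(test & reference); fp <- sum(test & !reference)
  fn <- sum(!test & reference); tn <- sum(!test & !reference)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  new("ContingencyTable", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), sensitivity = sens,
      specificity = spec)
}

#' Construct a ContingencyTable from raw counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return a [ContingencyTable-class].
#' @examples
#' contingencyFromCounts(38, 0, 0, 350)
#' @export
contingencyFromCounts <- function(tp, fp, fn, tn) {
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  new("ContingencyTable", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), sensitivity = sens,
      specificity = spec)
}

#' Pearson chi-square on a 2x2 contingency table
#'
#' Without continuity correction by default. When any marginal is zero
#' the statistic is undefined; the result is returned as inapplicable
#' rather than an error.
#'
#' @param table a [ContingencyTable-class].
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p_value`, `df` and `applicable`.
#' @export
chiSquare <- function(table, correct = FALSE) {
  m <- matrix(c(table@tp, table@fn, table@fp, table@tn), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L,
                applicable = FALSE))
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), applicable = TRUE)
}

#' Summary counts over a CNV call table
#'
#' Reproduces the cohort-level descriptive statistics of a whole-exon CNV
#' screen: CNV-positive sample count and rate, heterozygous-deletion count
#' and percentage, multi-exon heterozygous deletions (spanning two or more
#' *numbered* exons — the promoter target does not count as an exon),
#' duplication count, per-target event counts, and the exons never
#' affected.
#'
#' @param calls calls data.frame (e.g. [loadTable2Fixture()] or
#'   [callCohort()] output); failed events are ignored when a
#'   `passes_filter` column is present.
#' @param cohortSize total number of screened samples used for the
#'   positive rate (default 388).
#' @param panel panel `GRanges` defining label order (default
#'   [ldlrPanel()]).
#' @param gene gene symbol (default `"LDLR"`).
#' @return list of summary statistics (see examples).
#' @examples
#' s <- summarizeCalls(loadTable2Fixture())
#' s$n_positive          # 38
#' s$n_het_del           # 35
#' s$n_multi_exon_het_del  # 13
#' @export
summarizeCalls <- function(calls, cohortSize = 388, panel = ldlrPanel(),
                           gene = "LDLR") {
  ev <- calls[calls$gene == gene, , drop = FALSE]
  if ("passes_filter" %in% colnames(ev))
    ev <- ev[is.na(ev$passes_filter) | ev$passes_filter, , drop = FALSE]
  spans <- lapply(seq_len(nrow(ev)), function(i)
    .spanLabels(panel, gene, ev$first_label[i], ev$last_label[i]))
  nExons <- vapply(spans, function(s) sum(s != "promoter"), integer(1))
  het <- ev$type == "het_del"
  positives <- unique(ev$sample)
  perRegion <- table(factor(unlist(spans),
                            levels = mcols(panel)$label[
                              mcols(panel)$gene == gene]))
  exonLabels <- grep("^exon", names(perRegion), value = TRUE)
  unaffected <- exonLabels[perRegion[exonLabels] == 0]
  promEx1 <- sum(ev$first_label == "promoter" & ev$last_label == "exon1" &
                   het)
  list(n_positive = length(positives),
       positive_rate_percent = 100 * length(positives) / cohortSize,
       n_het_del = sum(het),
       het_del_percent = if (nrow(ev)) 100 * sum(het) / nrow(ev)
                         else NA_real_,
       n_multi_exon_het_del = sum(het & nExons >= 2L),
       n_dup = sum(ev$type == "dup"),
       n_hom_del = sum(ev$type == "hom_del"),
       n_promoter_exon1_del = promEx1,
       per_region_events = perRegion,
       unaffected_exons = unaffected)
}

#' Reproduce the MLPA-vs-NGS concordance experiment on simulated data
#'
#' Self-contained twin of the published validation: simulates the
#' 388-sample cohort carrying the 38 fixture CNVs plus a CNV-negative
#' control pool, runs the full depth-of-coverage caller on every sample,
#' and tallies the per-sample 2x2 contingency against the implanted truth.
#'
#' @param seed integer seed driving both simulations.
#' @param poolSize control pool size (default 100).
#' @param quick simulate only the 38 carriers plus one negative sample
#'   (schema check / smoke test; default `FALSE`).
#' @param matchCfg,callerCfg configuration overrides.
#' @return list with `contingency` (a [ContingencyTable-class]),
#'   `chi_square`, `calls`, `flags`, `truth`, `summary` (on the passing
#'   calls), `fixture_summary` (on the packaged fixture) and `thresholds`.
#' @export
reproduceConcordance <- function(seed = 1, poolSize = 100, quick = FALSE,
                                 matchCfg = matchConfig(),
                                 callerCfg = callerConfig()) {
  cfg <- table2Cohort(seed = seed, nNegative = if (quick) 1 else 350)
  sim <- simulateCohort(cfg)
  poolCfg <- simulationConfig(nSamples = poolSize,
                              sampleIds = sprintf("CTRL%03d",
                                                  seq_len(poolSize)),
                              seed = seed + 1000L)
  pool <- simulateCohort(poolCfg)$coverage
  res <- callCohort(sim$coverage, pool, sim$vafs, matchCfg, callerCfg,
                    gene = "LDLR")
  samples <- colnames(sim$coverage)
  called <- sampleStatus(res$calls, samples, gene = "LDLR")
  truthStatus <- setNames(samples %in% sim$truth$sample, samples)
  ct <- contingency(called, truthStatus)
  list(contingency = ct, chi_square = chiSquare(ct), calls = res$calls,
       flags = res$flags, truth = sim$truth,
       summary = summarizeCalls(res$calls, cohortSize = length(samples)),
       fixture_summary = summarizeCalls(loadTable2Fixture()),
       thresholds = c(del_ratio_max = callerCfg@delRatioMax,
                      del_z_max = callerCfg@delZMax,
                      dup_ratio_min = callerCfg@dupRatioMin,
                      dup_z_min = callerCfg@dupZMin),
       seed = seed)
}
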