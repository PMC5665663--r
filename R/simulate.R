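## Synthetic cohort generator. Emulates the data regime of a high-coverage
## targeted panel: ~300x mean DOC, negative-binomial count noise, lognormal
## library-size variation, a smooth unimodal GC bias peaking at GC 0.45,
## implanted CNVs (copy number 0/1/3 over contiguous target spans), and
## heterozygous-SNP VAFs consistent with the copy state (0.5 diploid, 0/1
## under het deletion, 1/3 or 2/3 under duplication).

#' Build a simulation configuration
#'
#' @param nSamples number of samples (>= 2).
#' @param meanDepth cohort mean depth of coverage (default 300 reads/base).
#' @param dispersion negative-binomial overdispersion of per-target total
#'   coverage: variance = mu + dispersion * mu^2 (default 0.004, ~6%%
#'   coefficient of variation at panel depths; 0 gives Poisson).
#' @param gcBiasStrength GC bias strength (default 0.3; 0 disables).
#' @param gcJitterSd per-sample lognormal jitter of the GC strength
#'   (default 0).
#' @param librarySizeSd sd of per-sample log library factors (default 0.1).
#' @param snpDensity expected heterozygous SNPs per target (default 1).
#' @param implants data.frame with columns `sample`, `copy_number`
#'   (0, 1 or 3), `first_label`, `last_label`; empty for an all-diploid
#'   cohort.
#' @param sampleIds sample identifiers (default `S001`, `S002`, ...).
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nSamples, meanDepth = 300, dispersion = 0.004,
                             gcBiasStrength = 0.3, gcJitterSd = 0,
                             librarySizeSd = 0.1, snpDensity = 1,
                             implants = NULL, sampleIds = NULL, seed = 1) {
  nSamples <- as.integer(nSamples)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%03d", seq_len(max(nSamples, 0L)))
  if (is.null(implants))
    implants <- data.frame(sample = character(), copy_number = integer(),
                           first_label = character(),
                           last_label = character())
  new("SimulationConfig", nSamples = nSamples, meanDepth = meanDepth,
      dispersion = dispersion, gcBiasStrength = gcBiasStrength,
      gcJitterSd = gcJitterSd, librarySizeSd = librarySizeSd,
      snpDensity = snpDensity, implants = implants,
      sampleIds = sampleIds, seed = as.integer(seed))
}

.gcFactor <- function(gc, strength) exp(-strength * (gc - 0.45)^2 /
                                          (2 * 0.1^2))

## Per-sample x per-target copy number matrix implied by the implants.
.copyNumberMatrix <- function(config, panel) {
  cn <- matrix(2L, nrow = length(panel), ncol = config@nSamples,
               dimnames = list(names(panel), config@sampleIds))
  imp <- config@implants
  for (i in seq_len(nrow(imp))) {
    g <- "LDLR"
    if ("gene" %in% colnames(imp)) g <- imp$gene[i]
    labs <- .spanLabels(panel, g, imp$first_label[i], imp$last_label[i])
    cn[paste(g, labs, sep = ":"), imp$sample[i]] <- imp$copy_number[i]
  }
  cn
}

#' Simulate a panel cohort with implanted CNVs
#'
#' Per-target total base coverage is drawn negative-binomially around
#' `meanDepth * libraryFactor(sample) * gcFactor(target) * copyNumber / 2 *
#' targetWidth` and divided by the target width to give mean DOC.
#' Heterozygous-SNP VAF observations are drawn binomially at the realized
#' target depth with expectation 0.5 (diploid), 0 or 1 (het deletion; the
#' surviving haplotype is hemizygous) or 1/3 / 2/3 (duplication); no sites
#' are emitted on homozygously deleted targets. Identical seeds give
#' bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @param panel panel `GRanges` (default [ldlrPanel()]).
#' @return list with `coverage` (a [CoverageExperiment]), `vafs`
#'   (data.frame in the [extractVafs()] layout), `truth` (data.frame
#'   `sample`, `copy_number`, `first_label`, `last_label`) and `config`.
#' @export
simulateCohort <- function(config, panel = ldlrPanel()) {
  validObject(config)
  nT <- length(panel); nS <- config@nSamples
  gc <- mcols(panel)$gc
  L <- width(panel)
  cn <- .copyNumberMatrix(config, panel)
  res <- withr::with_seed(config@seed, {
    lib <- exp(rnorm(nS, 0, config@librarySizeSd))
    strength <- config@gcBiasStrength *
      exp(rnorm(nS, 0, config@gcJitterSd))
    depth <- matrix(0, nT, nS, dimnames = dimnames(cn))
    for (s in seq_len(nS)) {
      mu <- config@meanDepth * lib[s] * .gcFactor(gc, strength[s]) *
        (cn[, s] / 2) * L
      tot <- if (config@dispersion > 0)
        rnbinom(nT, mu = mu, size = 1 / config@dispersion)
      else rpois(nT, mu)
      depth[, s] <- tot / L
    }
    vafs <- list()
    for (s in seq_len(nS)) {
      for (t in seq_len(nT)) {
        if (cn[t, s] == 0L) next
        nsnp <- rpois(1, config@snpDensity)
        if (nsnp == 0L) next
        siteDepth <- as.integer(round(depth[t, s]))
        if (siteDepth < 1L) next
        pos <- sort(sample.int(width(panel)[t], min(nsnp, width(panel)[t]))) +
          start(panel)[t] - 1L
        for (p in pos) {
          f <- switch(as.character(cn[t, s]),
                      "1" = sample(c(0, 1), 1),
                      "2" = 0.5,
                      "3" = sample(c(1 / 3, 2 / 3), 1))
          alt <- rbinom(1, siteDepth, f)
          vafs[[length(vafs) + 1L]] <- data.frame(
            sample = config@sampleIds[s],
            gene = mcols(panel)$gene[t],
            target_index = mcols(panel)$index[t],
            label = mcols(panel)$label[t],
            position = p, depth = siteDepth,
            alt_fraction = alt / siteDepth)
        }
      }
    }
    vafs <- if (length(vafs)) do.call(rbind, vafs)
    else data.frame(sample = character(), gene = character(),
                    target_index = integer(), label = character(),
                    position = integer(), depth = integer(),
                    alt_fraction = numeric())
    list(depth = depth, vafs = vafs)
  })
  truth <- config@implants
  truth <- truth[, intersect(c("sample", "copy_number", "first_label",
                               "last_label"), colnames(truth)),
                 drop = FALSE]
  list(coverage = CoverageExperiment(res$depth, panel), vafs = res$vafs,
       truth = truth, config = config)
}

#' Simulation configuration reproducing the published 388-sample cohort
#'
#' 388 samples of which 38 carry exactly the event types and spans of the
#' packaged fixture ([loadTable2Fixture()]; heterozygous deletions
#' implanted at copy number 1, duplications at copy number 3) and 350 are
#' diploid, at the panel's 300x regime and default noise.
#'
#' @param seed integer seed.
#' @param nNegative number of CNV-free samples (default 350).
#' @return a [SimulationConfig-class] with 38 implants.
#' @export
table2Cohort <- function(seed = 1, nNegative = 350) {
  fx <- loadTable2Fixture()
  implants <- data.frame(sample = fx$sample,
                         copy_number = ifelse(fx$type == "dup", 3L, 1L),
                         first_label = fx$first_label,
                         last_label = fx$last_label)
  ids <- c(fx$sample, sprintf("NEG%03d", seq_len(nNegative)))
  simulationConfig(nSamples = length(ids), implants = implants,
                   sampleIds = ids, seed = seed)
}

## --- MLPA run simulation ---------------------------------------------------

#' MLPA probe design used by the simulator
#'
#' 20 gene probes for LDLR (promoter, exons 1-18, and a second exon-15
#' probe), one upstream flanking probe, 12 reference probes on other
#' chromosomes and 9 control fragments (DNA-quantity / ligation QC).
#'
#' @return data.frame with columns `probe`, `role` (`gene`, `flank`,
#'   `reference`, `control_fragment`) and `label` (panel target label for
#'   gene probes, `NA` otherwise).
#' @export
mlpaDesign <- function() {
  gene <- data.frame(
    probe = c("LDLR-promoter", paste0("LDLR-exon", 1:18), "LDLR-exon15b"),
    role = "gene",
    label = c("promoter", paste0("exon", 1:18), "exon15"))
  rbind(gene,
        data.frame(probe = "SMARCA4-upstream", role = "flank",
                   label = NA_character_),
        data.frame(probe = sprintf("REF%02d", 1:12), role = "reference",
                   label = NA_character_),
        data.frame(probe = sprintf("CTRLFRAG%d", 1:9),
                   role = "control_fragment", label = NA_character_))
}

#' Simulate an MLPA run over a study cohort
#'
#' Generates probe signal intensities for the study samples plus one normal
#' control sample per seven study samples (rounded up, minimum one).
#' Signals are `probeLevel * sampleFactor * replicateNoise`, with gene
#' probes of CNV carriers additionally scaled by `copyNumber / 2` on the
#' affected targets; reference probes and control fragments are unaffected
#' by LDLR copy state.
#'
#' @param config a [simulationConfig()] supplying the study sample ids and
#'   seed.
#' @param truth implanted truth (data.frame `sample`, `copy_number`,
#'   `first_label`, `last_label`), e.g. from [simulateCohort()].
#' @param panel panel `GRanges` defining span labels (default
#'   [ldlrPanel()]).
#' @param nReplicates measurement replicates per sample (default 3).
#' @param signalSd lognormal replicate noise sd (default 0.04).
#' @param sampleSd lognormal per-sample signal factor sd (default 0.1).
#' @return list with `signals` (long data.frame: `sample`, `role`
#'   (`study`/`control`), `replicate`, `probe`, `signal`), `design`
#'   ([mlpaDesign()]) and `controls` (control sample ids).
#' @export
simulateMlpaRun <- function(config, truth, panel = ldlrPanel(),
                            nReplicates = 3, signalSd = 0.04,
                            sampleSd = 0.1) {
  design <- mlpaDesign()
  study <- config@sampleIds
  nControls <- max(1L, as.integer(ceiling(length(study) / 7)))
  controls <- sprintf("MLPACTRL%02d", seq_len(nControls))
  cnProbe <- matrix(2, nrow(design), length(study),
                    dimnames = list(design$probe, study))
  for (i in seq_len(nrow(truth))) {
    labs <- .spanLabels(panel, "LDLR", truth$first_label[i],
                        truth$last_label[i])
    hit <- design$role == "gene" & design$label %in% labs
    cnProbe[hit, truth$sample[i]] <- truth$copy_number[i]
  }
  withr::with_seed(config@seed + 7L, {
    level <- exp(rnorm(nrow(design), log(1000), 0.3))
    level[design$role == "control_fragment"] <-
      exp(rnorm(sum(design$role == "control_fragment"), log(500), 0.2))
    names(level) <- design$probe
    allSamples <- c(study, controls)
    roles <- c(rep("study", length(study)),
               rep("control", length(controls)))
    sampleFac <- exp(rnorm(length(allSamples), 0, sampleSd))
    rows <- vector("list", length(allSamples) * nReplicates)
    k <- 0L
    for (s in seq_along(allSamples)) {
      sid <- allSamples[s]
      cnfac <- if (roles[s] == "study") cnProbe[, sid] / 2
               else rep(1, nrow(design))
      cnfac[design$role != "gene"] <- 1
      for (r in seq_len(nReplicates)) {
        noise <- exp(rnorm(nrow(design), 0, signalSd))
        k <- k + 1L
        rows[[k]] <- data.frame(sample = sid, role = roles[s],
                                replicate = r, probe = design$probe,
                                signal = level * sampleFac[s] * cnfac *
                                  noise)
      }
    }
    signals <- do.call(rbind, rows)
    rownames(signals) <- NULL
    list(signals = signals, design = design, controls = controls)
  })
}
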