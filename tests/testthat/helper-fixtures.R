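# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# A 19-target LDLR panel (promoter + exons 1-18).
testPanel <- function() ldlrPanel()

# Flat coverage matrix: every sample at `depth` on every target.
flatCoverage <- function(nSamples, depth = 300,
                         ids = sprintf("S%03d", seq_len(nSamples)),
                         panel = testPanel()) {
  m <- matrix(depth, nrow = length(panel), ncol = nSamples,
              dimnames = list(names(panel), ids))
  CoverageExperiment(m, panel)
}

# Simulated diploid control pool.
simPool <- function(n = 40, seed = 99, ...) {
  cfg <- simulationConfig(nSamples = n,
                          sampleIds = sprintf("CTRL%03d", seq_len(n)),
                          seed = seed, ...)
  simulateCohort(cfg)$coverage
}

# A small cohort with one implanted event in sample S001.
simCarrier <- function(first, last, cn = 1L, seed = 11, nSamples = 4, ...) {
  imp <- data.frame(sample = "S001", copy_number = as.integer(cn),
                    first_label = first, last_label = last)
  simulateCohort(simulationConfig(nSamples = nSamples, implants = imp,
                                  seed = seed, ...))
}

# Independent re-implementation of the matching distance: scale the
# control to the test profile by the median depth ratio, then take the
# mean symmetric absolute percent difference. Used as a brute-force oracle.
pairwisePdOracle <- function(test, ctrl) {
  both <- test > 0 & ctrl > 0
  scaled <- ctrl / median(ctrl[both] / test[both])
  keep <- (test + scaled) > 0
  mean(abs(test[keep] - scaled[keep]) /
         ((test[keep] + scaled[keep]) / 2)) * 100
}

# BED text for the test panel, written to a temp file.
writeTestBed <- function(panel = testPanel()) {
  path <- tempfile(fileext = ".bed")
  writePanelBed(panel, path)
  path
}
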