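test_that("identical seeds reproduce the cohort bit-identically", {
  cfg <- simulationConfig(5, seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(docMatrix(a$coverage), docMatrix(b$coverage))
  expect_identical(a$vafs, b$vafs)
  c <- simulateCohort(simulationConfig(5, seed = 8))
  expect_false(identical(docMatrix(a$coverage), docMatrix(c$coverage)))
})

test_that("empirical depth converges to meanDepth x library x GC factor", {
  # many diploid samples, no library/GC variation: mean per target ~ 300
  cfg <- simulationConfig(400, librarySizeSd = 0, gcBiasStrength = 0,
                          snpDensity = 0, seed = 31)
  d <- docMatrix(simulateCohort(cfg)$coverage)
  expect_true(all(abs(rowMeans(d) / 300 - 1) < 0.02))
})

test_that("implanted copy numbers scale expected depth by CN/2", {
  imp <- data.frame(sample = rep("S001", 2), copy_number = c(1L, 3L),
                    first_label = c("exon2", "exon13"),
                    last_label = c("exon6", "exon14"))
  cfg <- simulationConfig(60, implants = imp, librarySizeSd = 0,
                          gcBiasStrength = 0, snpDensity = 0, seed = 13)
  sim <- simulateCohort(cfg)
  d <- docMatrix(sim$coverage)
  panel <- rowRanges(sim$coverage)
  dipMean <- rowMeans(d[, -1])
  ratio <- d[, "S001"] / dipMean
  delT <- paste0("LDLR:exon", 2:6)
  dupT <- paste0("LDLR:exon", 13:14)
  dipT <- setdiff(rownames(d), c(delT, dupT))
  expect_lt(abs(mean(ratio[delT]) - 0.5), 0.1)
  expect_lt(abs(mean(ratio[dupT]) - 1.5), 0.1)
  expect_lt(abs(mean(ratio[dipT]) - 1.0), 0.1)
})

test_that("an implant with an unknown label fails", {
  imp <- data.frame(sample = "S001", copy_number = 1L,
                    first_label = "exon19", last_label = "exon19")
  expect_error(simulateCohort(simulationConfig(3, implants = imp)),
               "exon19")
})

test_that("VAF distributions reflect copy state", {
  imp <- data.frame(sample = c("S001", "S002"), copy_number = c(1L, 3L),
                    first_label = c("exon2", "exon2"),
                    last_label = c("exon6", "exon6"))
  cfg <- simulationConfig(4, implants = imp, snpDensity = 8, seed = 17)
  v <- simulateCohort(cfg)$vafs
  delV <- v[v$sample == "S001" & v$label %in% paste0("exon", 2:6), ]
  dupV <- v[v$sample == "S002" & v$label %in% paste0("exon", 2:6), ]
  dipV <- v[v$sample == "S003", ]
  expect_true(all(delV$alt_fraction < 0.1 | delV$alt_fraction > 0.9))
  expect_true(all(abs(dupV$alt_fraction - 1 / 3) < 0.12 |
                    abs(dupV$alt_fraction - 2 / 3) < 0.12))
  expect_true(mean(abs(dipV$alt_fraction - 0.5) < 0.15) > 0.95)
  expect_true(all(v$alt_fraction >= 0 & v$alt_fraction <= 1))
})

test_that("homozygous deletions emit no variant sites and zero depth", {
  imp <- data.frame(sample = "S001", copy_number = 0L,
                    first_label = "exon3", last_label = "exon4")
  sim <- simulateCohort(simulationConfig(3, implants = imp,
                                         snpDensity = 5, seed = 19))
  hom <- sim$vafs$sample == "S001" &
    sim$vafs$label %in% c("exon3", "exon4")
  expect_false(any(hom))
  expect_true(all(docMatrix(sim$coverage)[c("LDLR:exon3", "LDLR:exon4"),
                                          "S001"] == 0))
})

test_that("the table2 cohort preset mirrors the published design", {
  cfg <- table2Cohort(seed = 3)
  expect_identical(cfg@nSamples, 388L)
  expect_identical(nrow(cfg@implants), 38L)
  expect_identical(sum(!cfg@sampleIds %in% cfg@implants$sample), 350L)
  promEx1 <- cfg@implants$first_label == "promoter" &
    cfg@implants$last_label == "exon1"
  expect_identical(sum(promEx1), 22L)
  expect_identical(sum(cfg@implants$copy_number == 3L), 3L)
  expect_identical(sum(cfg@implants$copy_number == 1L), 35L)
})

test_that("MLPA run includes one control per seven study samples", {
  cfg <- simulationConfig(14, seed = 23)
  sim <- simulateCohort(cfg)
  run <- simulateMlpaRun(cfg, sim$truth)
  expect_length(run$controls, 2L)
  run8 <- simulateMlpaRun(simulationConfig(8, seed = 23), sim$truth[0, ])
  expect_length(run8$controls, 2L)  # ceiling(8 / 7)
  expect_identical(nrow(run$design), 42L)  # 20 gene + flank + 12 ref + 9 qc
  expect_identical(sum(run$design$role == "gene"), 20L)
  expect_identical(sum(run$design$role == "reference"), 12L)
  expect_identical(sum(run$design$role == "control_fragment"), 9L)
})

test_that("MLPA signals scale with implanted copy number", {
  imp <- data.frame(sample = "S001", copy_number = 1L,
                    first_label = "promoter", last_label = "exon1")
  cfg <- simulationConfig(7, implants = imp, seed = 29)
  run <- simulateMlpaRun(cfg, imp)
  norm <- mlpaNormalize(run)
  ps <- norm$perSample
  affected <- c("LDLR-promoter", "LDLR-exon1")
  expect_true(all(abs(ps["S001", affected] - 0.5) < 0.1))
  other <- setdiff(colnames(ps), affected)
  expect_true(all(abs(ps["S002", ] - 1) < 0.15))
  expect_true(all(abs(ps["S001", other] - 1) < 0.15))
})
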