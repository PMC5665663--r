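mkMetrics <- function(ratio, z = rep(0, length(ratio)),
                      vaf = rep("neutral", length(ratio)),
                      labels = paste0("exon", seq_along(ratio)),
                      index = seq_along(ratio) - 1L,
                      weight = rep(1, length(ratio))) {
  data.frame(gene = "LDLR", label = labels, index = index,
             gc = 0.45, ratio = ratio, z = z, n_refs = 30L,
             weight = weight, vaf_class = vaf)
}

test_that("posteriors sum to one and clear cases get the right state", {
  st <- assignStates(mkMetrics(c(1.0, 0.52, 0.03, 1.5),
                               z = c(0, -8.7, -20, 7)))
  sums <- rowSums(st[, c("p_diploid", "p_het_del", "p_hom_del", "p_dup")])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_identical(st$state, c("diploid", "het_del", "hom_del", "dup"))
})

test_that("VAF evidence shifts borderline posteriors", {
  base <- mkMetrics(0.72)          # between diploid and het_del
  neutral <- assignStates(base)
  against <- assignStates(mkMetrics(0.72, vaf = "against_deletion"))
  expect_lt(against$p_het_del, neutral$p_het_del)
  supports <- assignStates(mkMetrics(1.38, vaf = "supports_duplication"))
  neutral2 <- assignStates(mkMetrics(1.38))
  expect_gt(supports$p_dup, neutral2$p_dup)
})

test_that("segmentation merges contiguous states and never bridges", {
  # het_del on exons 1-2, diploid on 3, het_del on 4: two events
  st <- assignStates(mkMetrics(c(0.5, 0.5, 1.0, 0.5), z = c(-8, -8, 0, -8)))
  ev <- segmentStates(st, sample = "X")
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$first_label, c("exon1", "exon4"))
  expect_identical(ev$last_label, c("exon2", "exon4"))
  expect_identical(ev$n_targets, c(2L, 1L))

  # an index gap (weight-0 target removed) also breaks the run
  m <- mkMetrics(c(0.5, 0.5), labels = c("exon1", "exon3"),
                 index = c(0L, 2L))
  ev2 <- segmentStates(assignStates(m), sample = "X")
  expect_identical(nrow(ev2), 2L)

  # discordant non-diploid states stay separate events
  m3 <- mkMetrics(c(0.5, 1.5), z = c(-8, 8))
  ev3 <- segmentStates(assignStates(m3), sample = "X")
  expect_identical(nrow(ev3), 2L)
  expect_identical(sort(ev3$type), c("dup", "het_del"))
})

test_that("event means equal the arithmetic mean of per-target values", {
  st <- assignStates(mkMetrics(c(0.48, 0.55, 0.51), z = c(-9, -7, -8)))
  ev <- segmentStates(st, sample = "X")
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$mean_ratio, mean(c(0.48, 0.55, 0.51)), tolerance = 1e-9)
  expect_equal(ev$mean_z, mean(c(-9, -7, -8)), tolerance = 1e-9)
  expect_identical(nrow(ev$per_target[[1]]), 3L)
})

test_that("filtration applies the mutually inclusive thresholds", {
  ev <- data.frame(sample = "X", gene = "LDLR",
                   type = c("het_del", "dup", "het_del", "het_del", "dup"),
                   first_label = "exon1", last_label = "exon1",
                   n_targets = 1L,
                   mean_ratio = c(0.62, 1.47, 0.72, 0.70, 1.29),
                   mean_z = c(-6.1, 7.3, -6.0, -5.0, 9.0),
                   vaf_support = "neutral", passes_filter = NA,
                   filter_reason = NA_character_)
  out <- filterEvents(ev)
  expect_identical(out$passes_filter, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$filter_reason[3], "ratio_above_del_max")
  expect_identical(out$filter_reason[5], "ratio_below_dup_min")
})

test_that("VAF contradiction demotes a deletion event", {
  ev <- data.frame(sample = "X", gene = "LDLR", type = "het_del",
                   first_label = "exon1", last_label = "exon1",
                   n_targets = 1L, mean_ratio = 0.5, mean_z = -9,
                   vaf_support = "against", passes_filter = NA,
                   filter_reason = NA_character_)
  out <- filterEvents(ev)
  expect_false(out$passes_filter)
  expect_identical(out$filter_reason, "vaf_contradiction")
})

test_that("filtration is monotone in the event mean ratio", {
  set.seed(127)
  for (i in 1:50) {
    r <- runif(1, 0.2, 0.9); z <- runif(1, -15, -5)
    mk <- function(rr, ty = "het_del") data.frame(
      sample = "X", gene = "LDLR", type = ty, first_label = "exon1",
      last_label = "exon1", n_targets = 1L, mean_ratio = rr, mean_z = z,
      vaf_support = "neutral", passes_filter = NA,
      filter_reason = NA_character_)
    if (filterEvents(mk(r))$passes_filter)
      expect_true(filterEvents(mk(r * 0.8))$passes_filter)
    rd <- runif(1, 1.0, 1.9); zd <- runif(1, 5, 15)
    mkd <- function(rr) {
      d <- mk(rr, "dup"); d$mean_z <- zd; d
    }
    if (filterEvents(mkd(rd))$passes_filter)
      expect_true(filterEvents(mkd(rd * 1.2))$passes_filter)
  }
})

test_that("a simulated diploid sample yields zero events", {
  pool <- simPool(n = 35, seed = 131)
  sim <- simulateCohort(simulationConfig(3, seed = 132))
  res <- callSample(sim$coverage, pool, "S002", sim$vafs)
  expect_identical(nrow(res$events), 0L)
})

test_that("a 5-exon het deletion is called as one exact passing event", {
  pool <- simPool(n = 35, seed = 137)
  sim <- simCarrier("exon2", "exon6", cn = 1L, seed = 138)
  res <- callSample(sim$coverage, pool, "S001", sim$vafs)
  ev <- res$events
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "het_del")
  expect_identical(ev$first_label, "exon2")
  expect_identical(ev$last_label, "exon6")
  expect_true(ev$passes_filter)
  expect_lte(ev$mean_ratio, 0.7)
  expect_lte(ev$mean_z, -5)
})

test_that("a homozygous deletion is recognized from near-zero coverage", {
  pool <- simPool(n = 35, seed = 139)
  sim <- simCarrier("exon4", "exon4", cn = 0L, seed = 140)
  res <- callSample(sim$coverage, pool, "S001", sim$vafs)
  ev <- res$events
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "hom_del")
  expect_identical(ev$first_label, "exon4")
})

test_that("a single-exon duplication is called and passes", {
  pool <- simPool(n = 35, seed = 141)
  sim <- simCarrier("exon7", "exon7", cn = 3L, seed = 142,
                    snpDensity = 4)
  res <- callSample(sim$coverage, pool, "S001", sim$vafs)
  ev <- res$events
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "dup")
  expect_identical(ev$first_label, "exon7")
  expect_true(ev$passes_filter)
  expect_gte(ev$mean_ratio, 1.3)
  expect_gte(ev$mean_z, 5)
})
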