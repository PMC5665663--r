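test_that("a 19-target LDLR BED round-trips with ordered indices", {
  panel <- testPanel()
  expect_length(panel, 19L)
  expect_identical(mcols(panel)$index, 0:18)
  expect_identical(mcols(panel)$label[1:2], c("promoter", "exon1"))
  expect_true(all(diff(start(panel)) > 0))

  reread <- readPanel(writeTestBed(panel))
  expect_identical(as.character(seqnames(reread)),
                   as.character(seqnames(panel)))
  expect_identical(start(reread), start(panel))
  expect_identical(end(reread), end(panel))
  expect_identical(mcols(reread)$label, mcols(panel)$label)
  expect_equal(mcols(reread)$gc, mcols(panel)$gc)
})

test_that("BED coordinates are 0-based half-open on ingestion", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr19\t11200038\t11200138\tLDLR:exon1\t0.5", path)
  p <- readPanel(path)
  expect_identical(start(p), 11200039L)  # GRanges 1-based
  expect_identical(end(p), 11200138L)
  expect_identical(width(p), 100L)
})

test_that("an empty BED yields an empty panel without error", {
  path <- tempfile(fileext = ".bed")
  writeLines(character(), path)
  expect_length(readPanel(path), 0L)
})

test_that("malformed BED lines fail with the offending line number", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr19\t100\t200\tLDLR:exon1\t0.5",
               "chr19\t300\t250\tLDLR:exon2\t0.5"), path)
  expect_error(readPanel(path), "line 2")
  writeLines(c("# comment", "chr19\t100\t200\tnoname"), path)
  expect_error(readPanel(path), "line 2.*gene:label")
  writeLines(c("chr19\t100\t200\tLDLR:exon1",
               "chr19\t300\t400\tLDLR:exon1"), path)
  expect_error(readPanel(path), "duplicate target label")
})

test_that("GC can be computed from a reference sequence", {
  path <- tempfile(fileext = ".bed")
  writeLines("chrT\t0\t10\tG1:exon1", path)
  seqs <- c(chrT = "GGGGGCCAAA")  # 7/10 GC
  p <- readPanel(path, refSeqs = seqs)
  expect_equal(mcols(p)$gc, 0.7)
})

test_that("coverage TSV round-trips bit-identically and validates", {
  panel <- testPanel()
  sim <- simulateCohort(simulationConfig(3, seed = 5))
  path <- tempfile(fileext = ".tsv")
  writeCoverage(sim$coverage, path)
  back <- readCoverage(path, panel)
  expect_identical(docMatrix(back), docMatrix(sim$coverage))
  expect_identical(colnames(back), colnames(sim$coverage))

  flat <- readCoverage(writeCoverage(flatCoverage(3), path), panel)
  expect_true(all(docMatrix(flat) == 300))
})

test_that("coverage reader rejects header/panel mismatch and bad cells", {
  panel <- testPanel()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tLDLR:nosuch", "S1\t300"), path)
  expect_error(readCoverage(path, panel), "nosuch")
  hdr <- paste(c("sample", names(panel)), collapse = "\t")
  writeLines(c(hdr, paste(c("S1", rep("300", 18), "-4"),
                          collapse = "\t")), path)
  expect_error(readCoverage(path, panel), "non-negative")
})

test_that("VAF extraction keeps in-target biallelic SNVs above min depth", {
  panel <- testPanel()
  # site inside exon4 (50/50), one with dup-like balance, one shallow,
  # one outside any target
  e4 <- start(panel)[mcols(panel)$label == "exon4"] + 5L
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"),
           paste("chr19", e4, ".", "A", "G", ".", "PASS", ".", "GT:AD",
                 "0/1:50,50", sep = "\t"),
           paste("chr19", e4 + 1L, ".", "A", "G", ".", "PASS", ".",
                 "GT:AD", "0/1:50,25", sep = "\t"),
           paste("chr19", e4 + 2L, ".", "A", "G", ".", "PASS", ".",
                 "GT:AD", "0/1:5,5", sep = "\t"),
           paste("chr19", 99L, ".", "A", "G", ".", "PASS", ".", "GT:AD",
                 "0/1:40,40", sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  v <- extractVafs(path, panel)
  expect_identical(nrow(v), 2L)   # shallow and off-target sites dropped
  expect_equal(v$alt_fraction[v$position == e4], 0.5)
  expect_equal(v$alt_fraction[v$position == e4 + 1L], 1 / 3)
  expect_true(all(v$label == "exon4"))
})

test_that("VCF without allelic depths names the missing field", {
  panel <- testPanel()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"),
           paste("chr19", start(panel)[5] + 1L, ".", "A", "G", ".",
                 "PASS", ".", "GT", "0/1", sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(extractVafs(path, panel), "AD")
})

test_that("VAF VCF writer round-trips through the extractor", {
  panel <- testPanel()
  sim <- simCarrier("exon2", "exon6", cn = 3L, seed = 21)
  v1 <- sim$vafs[sim$vafs$sample == "S001", ]
  path <- tempfile(fileext = ".vcf")
  writeVafVcf(v1, panel, path)
  back <- extractVafs(path, panel)
  expect_identical(nrow(back), nrow(v1))
  ord <- order(v1$position)
  expect_identical(back$position, as.integer(v1$position[ord]))
  expect_identical(back$depth, as.integer(v1$depth[ord]))
  # fractions recovered up to integer rounding of the alt depth
  expect_true(all(abs(back$alt_fraction - v1$alt_fraction[ord]) <=
                    0.5 / pmax(v1$depth[ord], 1)))
})

test_that("call tables round-trip through write/read as identity", {
  ev <- data.frame(sample = c("A", "B"), gene = "LDLR",
                   type = c("het_del", "dup"),
                   first_label = c("exon2", "exon7"),
                   last_label = c("exon6", "exon7"),
                   n_targets = c(5L, 1L),
                   mean_ratio = c(0.5377919, 1.4712345),
                   mean_z = c(-7.2885367, 7.3000001),
                   vaf_support = c("neutral", "supports"),
                   passes_filter = c(TRUE, TRUE),
                   filter_reason = c(NA_character_, NA_character_))
  path <- tempfile(fileext = ".tsv")
  writeCalls(ev, path)
  back <- readCalls(path)
  expect_equal(back$mean_ratio, ev$mean_ratio, tolerance = 0)
  expect_equal(back$mean_z, ev$mean_z, tolerance = 0)
  expect_identical(back$sample, ev$sample)
  expect_identical(back$passes_filter, ev$passes_filter)

  writeCalls(ev[0, ], path)
  expect_identical(nrow(readCalls(path)), 0L)

  expect_error(writeCalls(ev, path, format = "parquet"), "tsv, vcf")
})

test_that("symbolic-allele VCF output carries span and metrics", {
  panel <- testPanel()
  ev <- data.frame(sample = "A", gene = "LDLR", type = "het_del",
                   first_label = "exon2", last_label = "exon6",
                   n_targets = 5L, mean_ratio = 0.54, mean_z = -9.7,
                   vaf_support = "neutral", passes_filter = TRUE,
                   filter_reason = NA_character_)
  path <- tempfile(fileext = ".vcf")
  writeCalls(ev, path, format = "vcf", panel = panel)
  lines <- readLines(path)
  rec <- lines[!startsWith(lines, "#")]
  expect_length(rec, 1L)
  expect_match(rec, "<DEL>")
  expect_match(rec, "SVTYPE=DEL")
  expect_match(rec, "SPAN=exon2-exon6")
  e6 <- end(panel)[mcols(panel)$label == "exon6"]
  expect_match(rec, paste0("END=", e6))
})

test_that("the packaged fixture holds the 38 published records verbatim", {
  fx <- loadTable2Fixture()
  expect_identical(nrow(fx), 38L)
  gl133 <- fx[fx$sample == "GL133", ]
  expect_identical(gl133$type, "het_del")
  expect_identical(gl133$region, "promoter-exon1")
  expect_equal(gl133$mean_ratio, 0.62)
  expect_equal(gl133$mean_z, -6.1)
  gl12812 <- fx[fx$sample == "GL12812", ]
  expect_identical(gl12812$type, "dup")
  expect_identical(gl12812$region, "exon7")
  expect_equal(gl12812$mean_ratio, 1.47)
  expect_equal(gl12812$mean_z, 7.3)
  # write -> read round trip preserves all 38 records
  path <- tempfile(fileext = ".tsv")
  writeCalls(fx, path)
  back <- readCalls(path)
  expect_identical(nrow(back), 38L)
  expect_equal(back$mean_ratio, fx$mean_ratio)
  expect_identical(back$sample, fx$sample)
})
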