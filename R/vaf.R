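## Variant allele fraction (VAF) evidence: heterozygous-SNP allele balance
## inside panel targets. ~0.5 argues against a deletion (both haplotypes
## present); ~1/3 or ~2/3 is the balance expected under a duplication.

#' Extract VAF observations from a VCF
#'
#' Reads per-sample allelic depths (the `AD` FORMAT field) for biallelic
#' SNVs falling inside panel targets and converts them to variant allele
#' fractions `alt / (ref + alt)`. Sites with total allelic depth below
#' `minDepth` are dropped (fraction estimates are unstable at low depth).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param panel panel `GRanges`.
#' @param minDepth minimum total allelic depth to keep a site (default 20).
#' @return data.frame with columns `sample`, `gene`, `target_index`,
#'   `label`, `position` (1-based), `depth`, `alt_fraction`.
#' @export
extractVafs <- function(path, panel, minDepth = 20) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unspecified")
  ad <- tryCatch(VariantAnnotation::geno(vcf)$AD, error = function(e) NULL)
  if (is.null(ad))
    stop("VCF lacks the per-sample AD (allelic depths) FORMAT field, ",
         "which is required to compute variant allele fractions")
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  hits <- findOverlaps(rr, panel, ignore.strand = TRUE)
  keep <- intersect(which(snv), queryHits(hits))
  if (!length(keep))
    return(data.frame(sample = character(), gene = character(),
                      target_index = integer(), label = character(),
                      position = integer(), depth = integer(),
                      alt_fraction = numeric()))
  tgt <- subjectHits(hits)[match(keep, queryHits(hits))]
  out <- list()
  for (s in seq_len(ncol(vcf))) {
    adv <- ad[keep, s]
    if (is.matrix(adv)) adv <- split(adv, row(adv))  # single-site edge
    ref <- vapply(adv, function(x)
      if (length(x) >= 1 && !is.na(x[1])) as.numeric(x[1]) else NA_real_,
      numeric(1))
    alt <- vapply(adv, function(x)
      if (length(x) >= 2 && !is.na(x[2])) as.numeric(x[2]) else NA_real_,
      numeric(1))
    dp <- ref + alt
    ok <- !is.na(dp) & dp >= minDepth
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      sample = colnames(vcf)[s],
      gene = mcols(panel)$gene[tgt[ok]],
      target_index = mcols(panel)$index[tgt[ok]],
      label = mcols(panel)$label[tgt[ok]],
      position = start(rr)[keep[ok]],
      depth = as.integer(dp[ok]),
      alt_fraction = alt[ok] / dp[ok])
  }
  if (!length(out))
    return(data.frame(sample = character(), gene = character(),
                      target_index = integer(), label = character(),
                      position = integer(), depth = integer(),
                      alt_fraction = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample, res$position), , drop = FALSE]
}

#' Write VAF observations for one sample as a VCF
#'
#' Emits a minimal single-sample VCF 4.2 with synthetic `A>G` SNVs and a
#' `GT:AD:DP` FORMAT whose allelic depths reproduce each observation's
#' total depth and alt fraction (alt reads rounded to the nearest integer).
#' [extractVafs()] on the written file recovers the observations.
#'
#' @param vafs data.frame in the [extractVafs()] layout, one sample only.
#' @param panel panel `GRanges` (source of chromosome names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVafVcf <- function(vafs, panel, path) {
  sid <- unique(vafs$sample)
  if (length(sid) > 1L)
    stop("writeVafVcf writes one sample per file; got ",
         length(sid), " samples")
  if (length(sid) == 0L) sid <- "sample"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelcnv",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                  "Description=\"Read depth\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sid), collapse = "\t"))
  lines <- hdr
  if (nrow(vafs)) {
    key <- paste(vafs$gene, vafs$label, sep = ":")
    chrom <- as.character(seqnames(panel))[match(key, names(panel))]
    if (anyNA(chrom))
      stop("VAF observation refers to target(s) absent from the panel: ",
           paste(unique(key[is.na(chrom)]), collapse = ", "))
    ord <- order(chrom, vafs$position)
    vafs <- vafs[ord, , drop = FALSE]; chrom <- chrom[ord]
    alt <- as.integer(round(vafs$alt_fraction * vafs$depth))
    ref <- as.integer(vafs$depth) - alt
    gt <- ifelse(vafs$alt_fraction > 0.9, "1/1",
                 ifelse(vafs$alt_fraction < 0.1, "0/0", "0/1"))
    lines <- c(lines, paste(chrom, vafs$position, ".", "A", "G", ".",
                            "PASS", ".", "GT:AD:DP",
                            paste0(gt, ":", ref, ",", alt, ":", vafs$depth),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
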