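## Panel design: target regions with gene/label/GC annotation.
## Internally 0-based half-open (BED native); GRanges storage is 1-based,
## so BED starts are shifted by +1 on ingestion and -1 on output.

.panelGRanges <- function(chrom, start0, end, gene, label, gc) {
  ord <- order(chrom, start0)
  chrom <- chrom[ord]; start0 <- start0[ord]; end <- end[ord]
  gene <- gene[ord]; label <- label[ord]; gc <- gc[ord]
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end))
  mcols(gr)$gene <- gene
  mcols(gr)$label <- label
  mcols(gr)$gc <- gc
  idx <- integer(length(gr))
  for (g in unique(gene)) {
    sel <- which(gene == g)
    if (anyDuplicated(label[sel]))
      stop("duplicate target label within gene ", g, ": ",
           paste(label[sel][duplicated(label[sel])], collapse = ", "))
    idx[sel] <- seq_along(sel) - 1L
  }
  mcols(gr)$index <- idx
  names(gr) <- paste(gene, label, sep = ":")
  gr
}

#' Synthetic LDLR panel design (promoter + exons 1-18)
#'
#' A 19-target panel for the *LDLR* gene laid out like a lipid-gene capture
#' design: one probe region over ~1 kb of promoter/5'UTR and one per exon
#' (with ~150 bp flanks folded into the target widths). Coordinates are
#' synthetic hg19-like positions on chr19 spanning ~40 kb; they are
#' internally consistent (ordered, non-overlapping) but are not the vendor's
#' probe coordinates, which are not public. GC fractions span 0.35-0.66 so
#' GC-dependent bias is expressible.
#'
#' @return a `GRanges` with metadata columns `gene`, `label`, `gc`, `index`
#'   (0-based rank of the target along the gene in genomic order).
#' @examples
#' p <- ldlrPanel()
#' length(p)   # 19
#' @export
ldlrPanel <- function() {
  label <- c("promoter", paste0("exon", 1:18))
  start0 <- c(11199980L, 11201100L, 11203000L, 11205000L, 11208000L,
              11210500L, 11213000L, 11215500L, 11217500L, 11219500L,
              11221500L, 11223500L, 11226000L, 11228000L, 11230300L,
              11233000L, 11235500L, 11238000L, 11240500L)
  width <- c(1000L, 190L, 123L, 142L, 381L, 123L, 143L, 120L, 126L,
             172L, 227L, 120L, 140L, 142L, 231L, 173L, 131L, 165L, 400L)
  gc <- c(0.63, 0.64, 0.48, 0.52, 0.54, 0.50, 0.47, 0.44, 0.42, 0.46,
          0.41, 0.38, 0.36, 0.43, 0.40, 0.35, 0.41, 0.39, 0.45)
  .panelGRanges(rep("chr19", 19L), start0, start0 + width,
                rep("LDLR", 19L), label, gc)
}

.gcOfSequence <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gcn <- n - nchar(gsub("[GCgc]", "", seq))
  gcn / n
}

#' Read a panel design from BED
#'
#' Parses a BED file (0-based half-open) whose name column carries
#' `gene:label` (for example `LDLR:exon1`). GC fraction is taken from an
#' optional numeric 5th column; alternatively, if `refSeqs` supplies the
#' chromosome sequences, GC is computed from the target sequence. Targets
#' are returned sorted by coordinate with per-gene 0-based indices.
#'
#' @param path BED file path.
#' @param refSeqs optional named character vector (or coercible, e.g. a
#'   `Biostrings::DNAStringSet` via `as.character`) of chromosome sequences
#'   used to compute GC when no 5th column is present.
#' @return a `GRanges` like [ldlrPanel()]; empty input gives an empty
#'   `GRanges`.
#' @export
readPanel <- function(path, refSeqs = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(.panelGRanges(character(), integer(), integer(),
                         character(), character(), numeric()))
  fields <- strsplit(lines, "[\t ]+")
  n <- length(fields)
  chrom <- character(n); start0 <- integer(n); end <- integer(n)
  gene <- character(n); label <- character(n); gc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop("malformed BED line ", lineno[i], ": expected >= 4 columns")
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s < 0L || s >= e)
      stop("malformed BED line ", lineno[i],
           ": need 0 <= start < end, got '", f[2L], "', '", f[3L], "'")
    nm <- strsplit(f[4L], ":", fixed = TRUE)[[1L]]
    if (length(nm) != 2L || !nzchar(nm[1L]) || !nzchar(nm[2L]))
      stop("malformed BED line ", lineno[i],
           ": name column must be gene:label, got '", f[4L], "'")
    chrom[i] <- f[1L]; start0[i] <- s; end[i] <- e
    gene[i] <- nm[1L]; label[i] <- nm[2L]
    if (length(f) >= 5L) {
      g5 <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(g5) || g5 < 0 || g5 > 1)
        stop("malformed BED line ", lineno[i],
             ": GC column must be a fraction in [0,1], got '", f[5L], "'")
      gc[i] <- g5
    }
  }
  if (any(is.na(gc)) && !is.null(refSeqs)) {
    seqNames <- names(refSeqs)
    refSeqs <- as.character(refSeqs)   # accepts DNAStringSet etc.
    names(refSeqs) <- seqNames
    for (i in which(is.na(gc))) {
      if (!chrom[i] %in% names(refSeqs)) next
      gc[i] <- .gcOfSequence(substr(refSeqs[[chrom[i]]],
                                    start0[i] + 1L, end[i]))
    }
  }
  .panelGRanges(chrom, start0, end, gene, label, gc)
}

#' Write a panel design as BED
#'
#' Inverse of [readPanel()]: 0-based half-open coordinates, `gene:label` in
#' the name column, GC fraction in the 5th column.
#'
#' @param panel panel `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanelBed <- function(panel, path) {
  df <- data.frame(chrom = as.character(seqnames(panel)),
                   start = start(panel) - 1L, end = end(panel),
                   name = paste(mcols(panel)$gene, mcols(panel)$label,
                                sep = ":"),
                   gc = mcols(panel)$gc)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Index of one labelled target within a gene (0-based panel index).
.labelIndex <- function(panel, gene, label) {
  sel <- which(mcols(panel)$gene == gene & mcols(panel)$label == label)
  if (length(sel) != 1L)
    stop("unknown target label '", label, "' in gene ", gene)
  mcols(panel)$index[sel]
}

## All labels of a gene between first and last label (inclusive, gene order).
.spanLabels <- function(panel, gene, first, last) {
  sel <- which(mcols(panel)$gene == gene)
  sel <- sel[order(mcols(panel)$index[sel])]
  lab <- mcols(panel)$label[sel]
  i <- match(first, lab); j <- match(last, lab)
  if (is.na(i) || is.na(j))
    stop("unknown target label '", if (is.na(i)) first else last,
         "' in gene ", gene)
  if (i > j) stop("span ", first, "-", last, " is reversed in gene order")
  lab[i:j]
}
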