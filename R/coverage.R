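#' Construct a CoverageExperiment
#'
#' @param depth numeric matrix of mean depth of coverage, targets x samples;
#'   row order must follow `panel`, columns must be named by sample.
#' @param panel panel `GRanges` (see [ldlrPanel()], [readPanel()]).
#' @return a [CoverageExperiment].
#' @examples
#' p <- ldlrPanel()
#' d <- matrix(300, nrow = length(p), ncol = 3,
#'             dimnames = list(names(p), paste0("S", 1:3)))
#' CoverageExperiment(d, p)
#' @export
CoverageExperiment <- function(depth, panel) {
  depth <- as.matrix(depth)
  if (nrow(depth) != length(panel))
    stop("depth has ", nrow(depth), " rows but the panel has ",
         length(panel), " targets")
  if (is.null(colnames(depth)))
    stop("depth columns must be named by sample")
  rownames(depth) <- names(panel)
  se <- SummarizedExperiment(assays = list(depth = depth),
                             rowRanges = panel)
  new("CoverageExperiment", se)
}

#' Read a coverage matrix from TSV
#'
#' The file holds one row per sample: first column the sample identifier,
#' remaining columns the per-target mean depth of coverage under a header of
#' `gene:label` target names. Columns are aligned to the panel's target
#' order; every panel target must be present and every cell filled.
#'
#' @param path TSV path.
#' @param panel panel `GRanges` the matrix belongs to.
#' @return a [CoverageExperiment].
#' @seealso [writeCoverage()]
#' @export
readCoverage <- function(path, panel) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("coverage TSV needs a sample column plus targets")
  samples <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  want <- names(panel)
  extra <- setdiff(colnames(mat), want)
  if (length(extra))
    stop("coverage matrix has target(s) absent from the panel: ",
         paste(extra, collapse = ", "))
  missing <- setdiff(want, colnames(mat))
  if (length(missing))
    stop("coverage matrix lacks panel target(s): ",
         paste(missing, collapse = ", "))
  mat <- mat[, want, drop = FALSE]
  if (anyNA(mat)) stop("coverage matrix has missing cells")
  if (!is.numeric(mat)) stop("coverage values must be numeric")
  if (any(mat < 0)) stop("coverage values must be non-negative")
  depth <- t(mat)
  colnames(depth) <- samples
  CoverageExperiment(depth, panel)
}

#' Write a coverage matrix as TSV
#'
#' Inverse of [readCoverage()]: one row per sample, `sample` first column,
#' `gene:label` target headers. Values are written in full precision so a
#' write/read round trip is exact.
#'
#' @param cov a [CoverageExperiment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoverage <- function(cov, path) {
  d <- t(docMatrix(cov))
  df <- data.frame(sample = rownames(d), check.names = FALSE)
  df <- cbind(df, as.data.frame(d, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    vals <- vapply(as.numeric(df[i, -1L]),
                   function(x) format(x, digits = 17, scientific = FALSE),
                   character(1))
    writeLines(paste(c(df$sample[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}
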