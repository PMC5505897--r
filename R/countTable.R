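#' Construct a CountTable
#'
#' @param counts integer matrix of raw counts, genes in rows, libraries in
#'   columns. Row names are gene identifiers; column names are library
#'   labels (typically diet groups such as `"AL"`, `"DR"`, `"DR-AL"`).
#' @param totalMappedReads numeric vector of per-library total mapped
#'   reads, one per column of `counts` (named or in column order). Totals
#'   need not equal the assay column sums: mapped reads are not all
#'   assigned to genes.
#'
#' @return A [CountTable-class] object.
#' @examples
#' cnt <- matrix(rpois(20, 50), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), c("AL", "DR")))
#' ct <- CountTable(cnt, totalMappedReads = c(AL = 1e6, DR = 1.2e6))
#' totalMappedReads(ct)
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @export
CountTable <- function(counts, totalMappedReads) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (!is.null(names(totalMappedReads)) && !is.null(colnames(counts))) {
    totalMappedReads <- totalMappedReads[colnames(counts)]
  }
  stop_if_not_positive(totalMappedReads, "totalMappedReads")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(totalMappedReads = as.numeric(totalMappedReads),
                        row.names = colnames(counts))
  )
  new("CountTable", se)
}

#' Per-library total mapped reads
#'
#' @param x a [CountTable-class].
#' @return Named numeric vector of mapped-read totals.
#' @export
setGeneric("totalMappedReads", function(x) standardGeneric("totalMappedReads"))

#' @rdname totalMappedReads
#' @importFrom SummarizedExperiment colData
#' @export
setMethod("totalMappedReads", "CountTable", function(x) {
  tot <- colData(x)$totalMappedReads
  names(tot) <- colnames(x)
  tot
})

#' @importFrom methods callNextMethod
setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d genes x %d libraries\n",
              nrow(object), ncol(object)))
  tot <- totalMappedReads(object)
  cat("  total mapped reads:",
      paste(sprintf("%s=%.3g", names(tot), tot), collapse = ", "), "\n")
  invisible(callNextMethod())
})

#' Read a count table from TSV plus a JSON totals sidecar
#'
#' The TSV has a `gene` column followed by one integer column per library;
#' the JSON sidecar maps each library label to its total mapped reads.
#'
#' @param countsFile path to the TSV count table.
#' @param totalsFile path to the JSON totals file. Defaults to
#'   `<countsFile>.totals.json`.
#' @return A [CountTable-class].
#' @importFrom utils read.delim
#' @export
readCountTable <- function(countsFile,
                           totalsFile = paste0(countsFile, ".totals.json")) {
  tab <- read.delim(countsFile, check.names = FALSE)
  if (!"gene" %in% colnames(tab)) stop("count TSV needs a 'gene' column")
  cnt <- as.matrix(tab[, setdiff(colnames(tab), "gene"), drop = FALSE])
  rownames(cnt) <- tab$gene
  totals <- unlist(jsonlite::read_json(totalsFile, simplifyVector = TRUE))
  CountTable(cnt, totalMappedReads = totals)
}

#' Write a count table as TSV plus a JSON totals sidecar
#'
#' @param x a [CountTable-class].
#' @param countsFile output TSV path; the totals sidecar is written next to
#'   it as `<countsFile>.totals.json`.
#' @return Invisibly, the two paths written.
#' @importFrom utils write.table
#' @importFrom SummarizedExperiment assay
#' @export
writeCountTable <- function(x, countsFile) {
  cnt <- assay(x, "counts")
  out <- data.frame(gene = rownames(cnt), cnt, check.names = FALSE)
  write.table(out, countsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  totalsFile <- paste0(countsFile, ".totals.json")
  jsonlite::write_json(as.list(totalMappedReads(x)), totalsFile,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(countsFile, totalsFile))
}
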