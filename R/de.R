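# Differential expression between two unreplicated pooled libraries.
# Counts are normalised by total mapped reads, square-root transformed
# (variance-stabilising for Poisson counts) and compared with a Z-test;
# p-values are Benjamini-Hochberg corrected across the tested genes and
# calls are filtered on a signed fold-change threshold.

#' Normalise counts to per-library rates
#'
#' Divides each count by its library's total mapped reads. Reported per
#' million mapped reads by default for readability; the Z-test consumes
#' raw rates internally.
#'
#' @param x a [CountTable-class].
#' @param perMillion logical; scale rates by 1e6 (default `TRUE`).
#' @return Numeric matrix of rates, same dimensions as the count assay.
#' @examples
#' ct <- CountTable(matrix(c(100, 200), 1, dimnames = list("g1", c("A", "B"))),
#'                  totalMappedReads = c(A = 1e6, B = 1e6))
#' normalizeRates(ct)
#' @importFrom SummarizedExperiment assay
#' @export
normalizeRates <- function(x, perMillion = TRUE) {
  stopifnot(is(x, "CountTable"))
  tot <- totalMappedReads(x)
  stop_if_not_positive(tot, "totalMappedReads")
  rates <- sweep(assay(x, "counts"), 2L, tot, "/")
  if (perMillion) rates * 1e6 else rates
}

#' Square-root-transform Poisson Z-test for two pooled libraries
#'
#' For counts `x1`, `x2` with mapped-read totals `N1`, `N2`, the rates
#' `x/N` are square-root transformed to approximate normality with
#' constant variance: for `X ~ Poisson(lambda)`, the delta method gives
#' `Var(sqrt(X/N)) ~= 1/(4N)`, independent of `lambda`. The statistic is
#' \deqn{z = \frac{\sqrt{x_1/N_1} - \sqrt{x_2/N_2}}
#'                {\tfrac{1}{2}\sqrt{1/N_1 + 1/N_2}}}
#' with a two-sided standard-normal p-value. All arguments are vectorised.
#'
#' @param x1,x2 non-negative counts in library 1 and 2.
#' @param N1,N2 strictly positive total mapped reads.
#' @return A data.frame with columns `z` and `p`; `z` is finite for all
#'   valid inputs including zero counts.
#' @examples
#' sqrtZTest(150, 1e6, 100, 1e6)
#' @importFrom stats pnorm
#' @export
sqrtZTest <- function(x1, N1, x2, N2) {
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be non-negative")
  stop_if_not_positive(N1, "N1")
  stop_if_not_positive(N2, "N2")
  z <- (sqrt(x1 / N1) - sqrt(x2 / N2)) / (0.5 * sqrt(1 / N1 + 1 / N2))
  data.frame(z = z, p = 2 * pnorm(-abs(z)))
}

#' Signed fold change between two library rates
#'
#' Computes the rate ratio `r = ((x2 + c) / N2) / ((x1 + c) / N1)` and
#' reports it with the signed convention `r` if `r >= 1`, else `-1/r`, so
#' that `|fc| >= 1` always. The pseudocount `c` is applied (to both
#' libraries) only when a zero count would otherwise make the ratio zero
#' or undefined.
#'
#' @param x1,x2 non-negative counts; `x1` is the reference library.
#' @param N1,N2 strictly positive totals.
#' @param pseudocount non-negative pseudocount (default 0.5).
#' @return Numeric vector of signed fold changes; `NA` where both counts
#'   and the pseudocount are zero (ratio undefined).
#' @examples
#' foldChange(100, 1e6, 200, 1e6)   # +2
#' foldChange(100, 1e6, 50, 1e6)    # -2
#' @export
foldChange <- function(x1, N1, x2, N2, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be non-negative")
  n <- max(length(x1), length(x2))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  useP <- x1 == 0 | x2 == 0
  a1 <- x1 + ifelse(useP, pseudocount, 0)
  a2 <- x2 + ifelse(useP, pseudocount, 0)
  r <- (a2 / N2) / (a1 / N1)
  fc <- ifelse(r >= 1, r, -1 / r)
  fc[a1 == 0 & a2 == 0] <- NA_real_
  fc
}

#' Call differentially expressed genes between two pooled libraries
#'
#' Runs [sqrtZTest()] per gene, applies Benjamini-Hochberg correction
#' across all tested genes, and flags a gene significant when `q < alpha`
#' and `|foldChange| >= fcThreshold` (defaults 0.05 and 1.25). Genes with
#' zero counts in both libraries are excluded from testing and from the BH
#' family but kept in the table with `NA` statistics so that the gene
#' universe is preserved for downstream persistence analysis.
#'
#' @param x a [CountTable-class].
#' @param comparison length-2 character: reference library label then
#'   treatment library label (e.g. `c("AL", "DR")`); fold changes are
#'   treatment over reference.
#' @param alpha FDR threshold in (0, 1).
#' @param fcThreshold signed fold-change magnitude threshold (>= 1).
#' @param pseudocount passed to [foldChange()].
#' @return A [DEGTable-class]; thresholds and comparison are recorded in
#'   `S4Vectors::metadata()`.
#' @examples
#' cnt <- matrix(c(100, 100, 100, 1000), 2,
#'               dimnames = list(c("flat", "up"), c("AL", "DR")))
#' callDEGs(CountTable(cnt, c(AL = 1e6, DR = 1e6)))
#' @importFrom S4Vectors DataFrame metadata<-
#' @importFrom SummarizedExperiment assay
#' @export
callDEGs <- function(x, comparison = c("AL", "DR"), alpha = 0.05,
                     fcThreshold = 1.25, pseudocount = 0.5) {
  stopifnot(is(x, "CountTable"), length(comparison) == 2L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (fcThreshold < 1) stop("fcThreshold must be >= 1")
  miss <- setdiff(comparison, colnames(x))
  if (length(miss)) {
    stop("library label(s) absent from count table: ",
         paste(miss, collapse = ", "))
  }
  cnt <- assay(x, "counts")
  tot <- totalMappedReads(x)
  x1 <- cnt[, comparison[1L]]; N1 <- tot[[comparison[1L]]]
  x2 <- cnt[, comparison[2L]]; N2 <- tot[[comparison[2L]]]

  tested <- !(x1 == 0 & x2 == 0)
  z <- p <- q <- fc <- rep(NA_real_, nrow(cnt))
  zt <- sqrtZTest(x1[tested], N1, x2[tested], N2)
  z[tested] <- zt$z
  p[tested] <- zt$p
  q[tested] <- bhAdjust(zt$p)
  fc[tested] <- foldChange(x1[tested], N1, x2[tested], N2, pseudocount)

  direction <- rep("none", nrow(cnt))
  direction[tested & fc > 1] <- "up"
  direction[tested & fc < -1] <- "down"
  significant <- tested & !is.na(q) & q < alpha &
    !is.na(fc) & abs(fc) >= fcThreshold
  significant[direction == "none"] <- FALSE

  res <- DataFrame(
    gene = rownames(cnt),
    rate1 = 1e6 * x1 / N1,
    rate2 = 1e6 * x2 / N2,
    foldChange = fc, z = z, p = p, q = q,
    direction = direction, significant = significant,
    row.names = rownames(cnt))
  res <- new("DEGTable", res)
  metadata(res) <- list(comparison = comparison, alpha = alpha,
                        fcThreshold = fcThreshold, pseudocount = pseudocount,
                        nTested = sum(tested))
  res
}

#' Write a DEGTable as TSV
#'
#' @param x a [DEGTable-class].
#' @param file output TSV path.
#' @return Invisibly, `file`.
#' @importFrom utils write.table
#' @export
writeDEGTable <- function(x, file) {
  write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
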