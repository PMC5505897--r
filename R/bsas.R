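# BSAS quantitation: place bisulfite amplicon reads on the reference in
# bisulfite space, call per-cytosine methylation in CG and CH contexts,
# and test group differences at the total and individual-site level.

#' Place bisulfite reads on an amplicon reference
#'
#' Ungapped comparison in bisulfite space: at reference positions that
#' were cytosines, a read C (methylated) or T (converted) both match; at
#' every other position the read base must match the reference literally.
#' Each read is assigned the offset with the fewest mismatches (ties
#' broken by the smallest offset) and accepted when its mismatch fraction
#' is at most `maxMm`.
#'
#' @param reads a [Biostrings::DNAStringSet] or character vector; read
#'   lengths must not exceed the amplicon length.
#' @param spec an [AmpliconSpec-class].
#' @param maxMm maximum tolerated mismatch fraction (default 0.1).
#' @return A data.frame with one row per read: `offset` (0-based, `NA` for
#'   rejected reads), `mismatches`, `width`, `accepted`.
#' @examples
#' amp <- makeAmplicon(40, cgPositions = 10, seed = 5)
#' conv <- convertReference(amp)$converted
#' placeReads(conv, amp)      # offset 0, zero mismatches
#' @export
placeReads <- function(reads, spec, maxMm = 0.1) {
  stopifnot(is(spec, "AmpliconSpec"))
  stop_if_not_fraction(maxMm, "maxMm")
  reads <- as.character(reads)
  refChars <- strsplit(as.character(spec@seq), "", fixed = TRUE)[[1L]]
  isC <- refChars == "C"
  L <- length(refChars)
  widths <- nchar(reads)
  if (any(widths > L)) stop("read length exceeds amplicon length")
  offset <- rep(NA_integer_, length(reads))
  mism <- rep(NA_integer_, length(reads))

  for (w in unique(widths)) {
    sel <- which(widths == w)
    rm_ <- matrix(unlist(strsplit(reads[sel], "", fixed = TRUE),
                         use.names = FALSE), nrow = length(sel), byrow = TRUE)
    isCT <- rm_ == "C" | rm_ == "T"
    best <- rep(w + 1L, length(sel))
    bestOff <- rep(NA_integer_, length(sel))
    for (o in 0:(L - w)) {
      refSlice <- refChars[(o + 1L):(o + w)]
      cSlice <- isC[(o + 1L):(o + w)]
      ok <- rm_ == matrix(refSlice, nrow = length(sel), ncol = w,
                          byrow = TRUE)
      if (any(cSlice)) {
        ok[, cSlice] <- ok[, cSlice, drop = FALSE] |
          isCT[, cSlice, drop = FALSE]
      }
      mm <- w - rowSums(ok)
      better <- mm < best
      best[better] <- mm[better]
      bestOff[better] <- o
    }
    offset[sel] <- bestOff
    mism[sel] <- best
  }
  accepted <- !is.na(offset) & mism / widths <= maxMm
  offset[!accepted] <- NA_integer_
  data.frame(read = if (!is.null(names(reads))) names(reads) else
               seq_along(reads),
             offset = offset, mismatches = mism, width = widths,
             accepted = accepted)
}

#' Call per-site methylation from placed bisulfite reads
#'
#' At each annotated cytosine, a read C is counted as methylated, a T as
#' unmethylated (converted), and any other base as `other` (ignored in the
#' percentage). Percent methylation is `100 * nMeth / (nMeth + nUnmeth)`.
#' Sites whose informative coverage falls below `minCoverage` in any
#' sample are flagged (`covered = FALSE` in `rowData`) and excluded from
#' totals and site tests; the default floor of 1000 reflects the BSAS
#' design depth of more than 1000x.
#'
#' @param reads a named list of [Biostrings::DNAStringSet] (one element
#'   per sample) or a single `DNAStringSet` treated as one sample.
#' @param spec an [AmpliconSpec-class].
#' @param groups optional character vector of group labels, one per
#'   sample; defaults to the part of each sample name before the last
#'   underscore, or the sample name itself.
#' @param minCoverage minimum informative calls per site per sample.
#' @param maxMm passed to [placeReads()].
#' @return A [MethCallMatrix-class] (sites x samples).
#' @examples
#' amp <- makeAmplicon(50, cgPositions = c(10, 30), seed = 2)
#' sc <- MethylationScenario(amp,
#'   matrix(c(1, 0), 1, nrow(ampliconSites(amp)),
#'          dimnames = list("AL", NULL))[, rep(1, nrow(ampliconSites(amp))),
#'                                       drop = FALSE],
#'   depth = 20, nSamplesPerGroup = 1, seed = 4)
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData
#'   assay
#' @importFrom S4Vectors DataFrame metadata<-
#' @export
callSites <- function(reads, spec, groups = NULL, minCoverage = 1000L,
                      maxMm = 0.1) {
  stopifnot(is(spec, "AmpliconSpec"))
  if (!is.list(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("sample%d", seq_along(reads))
  }
  if (is.null(groups)) {
    groups <- sub("_[^_]*$", "", names(reads))
  }
  stopifnot(length(groups) == length(reads))
  sites <- spec@sites
  ns <- nrow(sites)
  nsamp <- length(reads)
  nMeth <- nUnmeth <- nOther <- matrix(0L, ns, nsamp,
    dimnames = list(sprintf("site_%d", sites$offset), names(reads)))
  nReads <- nRejected <- integer(nsamp)

  if (all(lengths(reads) == 0L)) {
    warning("empty read set: returning an empty methylation matrix")
  }
  for (i in seq_len(nsamp)) {
    rs <- as.character(reads[[i]])
    if (!length(rs)) next
    pl <- placeReads(rs, spec, maxMm = maxMm)
    nReads[i] <- sum(pl$accepted)
    nRejected[i] <- sum(!pl$accepted)
    keep <- pl$accepted
    if (!any(keep)) next
    rs <- rs[keep]
    off <- pl$offset[keep]
    w <- pl$width[keep]
    for (j in seq_len(ns)) {
      s <- sites$offset[j]
      covering <- off <= s & s <= off + w - 1L
      if (!any(covering)) next
      base <- substring(rs[covering], s - off[covering] + 1L,
                        s - off[covering] + 1L)
      nMeth[j, i] <- sum(base == "C")
      nUnmeth[j, i] <- sum(base == "T")
      nOther[j, i] <- sum(base != "C" & base != "T")
    }
  }
  inf <- nMeth + nUnmeth
  pct <- ifelse(inf > 0, 100 * nMeth / inf, NA_real_)
  covered <- apply(inf >= minCoverage, 1L, all)
  se <- SummarizedExperiment(
    assays = list(nMeth = nMeth, nUnmeth = nUnmeth, nOther = nOther,
                  pct = pct),
    rowData = DataFrame(offset = sites$offset, context = sites$context,
                        covered = covered),
    colData = DataFrame(group = groups, nReads = nReads,
                        nRejected = nRejected, row.names = names(reads)))
  out <- new("MethCallMatrix", se)
  metadata(out) <- list(amplicon = spec@name, minCoverage = minCoverage,
                        maxMm = maxMm)
  out
}

#' Per-sample total methylation in one context
#'
#' Aggregates per-site percentages over all covered sites of the requested
#' context. The default is the unweighted mean of site percentages, which
#' is invariant to coverage imbalance between sites; `"read-weighted"`
#' pools methylated and informative calls across sites instead. The two
#' agree exactly when coverage is identical at all sites.
#'
#' @param m a [MethCallMatrix-class].
#' @param context `"CG"` or `"CH"`.
#' @param weighting `"site-mean"` (default) or `"read-weighted"`.
#' @return Named numeric vector of per-sample total percent methylation.
#' @examples
#' # with m a MethCallMatrix: totalMethylation(m, "CG")
#' @importFrom SummarizedExperiment rowData assay
#' @export
totalMethylation <- function(m, context = c("CG", "CH"),
                             weighting = c("site-mean", "read-weighted")) {
  stopifnot(is(m, "MethCallMatrix"))
  context <- match.arg(context)
  weighting <- match.arg(weighting)
  rd <- rowData(m)
  sel <- rd$context == context & rd$covered
  if (!any(sel)) {
    stop("no covered ", context, " site: total methylation undefined",
         call. = FALSE)
  }
  if (weighting == "site-mean") {
    colMeans(assay(m, "pct")[sel, , drop = FALSE])
  } else {
    nm <- colSums(assay(m, "nMeth")[sel, , drop = FALSE])
    ni <- nm + colSums(assay(m, "nUnmeth")[sel, , drop = FALSE])
    100 * nm / ni
  }
}

#' Test group differences in total methylation
#'
#' One-way ANOVA on per-sample totals with Tukey HSD adjusted pairwise
#' comparisons, plus the percent decrease of each non-reference group
#' relative to the reference-group mean,
#' `100 * (mean_ref - mean_g) / mean_ref` (the effect scale on which BSAS
#' promoter results are reported).
#'
#' @param totals numeric vector of per-sample totals (e.g. from
#'   [totalMethylation()]).
#' @param groups group label per sample; at least 2 groups with at least
#'   2 samples each.
#' @param refGroup reference group for percent decrease (default `"AL"`,
#'   falling back to the first group present).
#' @return A list of class `TotalMethResult`: `groupMeans`, `anova`
#'   (`F`, `p`, `df`), `tukey` (data.frame `pair`, `diff`, `padj`),
#'   `pctDecrease` (named, vs the reference mean).
#' @examples
#' totals <- c(70, 72, 71, 60, 61, 59)
#' testTotal(totals, rep(c("AL", "DR"), each = 3))
#' @export
testTotal <- function(totals, groups, refGroup = "AL") {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  if (!refGroup %in% groups) refGroup <- groups[1L]
  av <- anovaOneway(totals, groups)
  tk <- tukeyHsd(totals, groups)
  gm <- tapply(totals, groups, mean)
  others <- setdiff(names(gm), refGroup)
  pctDecrease <- 100 * (gm[[refGroup]] - gm[others]) / gm[[refGroup]]
  names(pctDecrease) <- others
  out <- list(groupMeans = gm, anova = av, tukey = tk,
              pctDecrease = pctDecrease, refGroup = refGroup)
  class(out) <- "TotalMethResult"
  out
}

#' @export
print.TotalMethResult <- function(x, ...) {
  cat("TotalMethResult\n  group means:",
      paste(sprintf("%s=%.2f", names(x$groupMeans), x$groupMeans),
            collapse = ", "), "\n")
  cat(sprintf("  ANOVA F = %.3f, p = %.4g\n", x$anova$F, x$anova$p))
  print(x$tukey)
  invisible(x)
}

#' Per-site group tests with BH correction within context families
#'
#' One-way ANOVA per covered site on per-sample percent methylation, with
#' Benjamini-Hochberg correction applied separately within the CG and CH
#' site families of the amplicon (the two contexts are reported and tested
#' separately). Sites below the coverage floor are excluded from testing
#' and from the BH families.
#'
#' @param m a [MethCallMatrix-class] with `group` in its `colData`.
#' @param alpha FDR threshold used for the `flagged` column.
#' @return A data.frame, one row per tested site: `offset`, `context`,
#'   one `mean.<group>` column per group, `F`, `p`, `q`, `flagged`.
#' @importFrom SummarizedExperiment rowData colData assay
#' @export
testSites <- function(m, alpha = 0.05) {
  stopifnot(is(m, "MethCallMatrix"))
  groups <- as.character(colData(m)$group)
  if (length(unique(groups)) < 2L) {
    stop("need >= 2 groups for per-site tests", call. = FALSE)
  }
  rd <- rowData(m)
  pct <- assay(m, "pct")
  keep <- which(rd$covered)
  res <- lapply(keep, function(j) {
    av <- anovaOneway(pct[j, ], groups)
    gm <- tapply(pct[j, ], groups, mean)
    c(list(offset = rd$offset[j], context = rd$context[j]),
      as.list(stats::setNames(gm, paste0("mean.", names(gm)))),
      list(F = av$F, p = av$p))
  })
  out <- do.call(rbind, lapply(res, function(r) as.data.frame(r)))
  out$q <- NA_real_
  for (ctx in unique(out$context)) {
    fam <- out$context == ctx
    out$q[fam] <- bhAdjust(out$p[fam])
  }
  out$flagged <- out$q < alpha
  rownames(out) <- sprintf("site_%d", out$offset)
  out
}

#' Write per-site methylation calls as TSV
#'
#' One row per site: offset, context, coverage flag, then per-sample
#' percent methylation.
#'
#' @param m a [MethCallMatrix-class].
#' @param file output TSV path.
#' @return Invisibly, `file`.
#' @importFrom utils write.table
#' @importFrom SummarizedExperiment rowData assay
#' @export
writeMethCalls <- function(m, file) {
  rd <- rowData(m)
  out <- data.frame(offset = rd$offset, context = rd$context,
                    covered = rd$covered,
                    round(assay(m, "pct"), 4), check.names = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write site test results as a BED-like track
#'
#' Amplicon-local, 0-based half-open single-base intervals with the BH q
#' as score annotation.
#'
#' @param siteResults result of [testSites()].
#' @param file output path.
#' @param ampliconName chromosome-column label (the amplicon name).
#' @return Invisibly, `file`.
#' @importFrom utils write.table
#' @export
writeSiteTrack <- function(siteResults, file, ampliconName = "amplicon") {
  bed <- data.frame(chrom = ampliconName,
                    start = siteResults$offset,
                    end = siteResults$offset + 1L,
                    name = paste0(siteResults$context, "_",
                                  siteResults$offset),
                    score = signif(siteResults$q, 6),
                    strand = "+")
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
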