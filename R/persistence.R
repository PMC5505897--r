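# Persistence of DR-induced expression changes after the switch back to
# ad-libitum feeding: a gene is persistent when it is significantly
# altered in DR vs AL and remains significantly altered in the same
# direction in DR-AL vs AL.

#' Classify DR-induced expression changes as persistent or transient
#'
#' Both inputs must be differential calls against the same AL reference on
#' the same gene universe. A gene is persistent-up when it is
#' significant-up in the DR comparison and significant-up in the DR-AL
#' comparison; persistent-down analogously. Direction mismatches are not
#' persistent. Genes significant only in DR-AL ("new" changes) are
#' reported separately.
#'
#' @param degDR [DEGTable-class] for DR vs AL.
#' @param degDRAL [DEGTable-class] for DR-AL vs AL.
#' @param lenient logical; when `TRUE`, persistence only requires
#'   significance in DR plus a same-sign fold change in DR-AL (regardless
#'   of its significance). Default `FALSE`: significance in both.
#' @return A list of class `PersistenceSummary` with counts (`nUpDR`,
#'   `nDownDR`, `nUpDRAL`, `nDownDRAL`, `nPersistUp`, `nPersistDown`),
#'   percentages of DR-altered genes that persisted (`pctPersistUp`,
#'   `pctPersistDown`, `NA` when no DR gene was altered in that
#'   direction), and gene lists for every category (including `newUp`,
#'   `newDown`).
#' @examples
#' sim <- simulateCounts(ExpressionScenario(nGenes = 500, seed = 11))
#' dDR <- callDEGs(sim$counts, c("AL", "DR"))
#' dSw <- callDEGs(sim$counts, c("AL", "DR-AL"))
#' classifyPersistence(dDR, dSw)$nPersistUp
#' @export
classifyPersistence <- function(degDR, degDRAL, lenient = FALSE) {
  stopifnot(is(degDR, "DEGTable"), is(degDRAL, "DEGTable"))
  if (!identical(degDR$gene, degDRAL$gene)) {
    stop("the two DEG tables must share the same gene universe",
         call. = FALSE)
  }
  sig_dir <- function(d, dir) d$gene[d$significant & d$direction == dir]
  upDR <- sig_dir(degDR, "up");     downDR <- sig_dir(degDR, "down")
  upSW <- sig_dir(degDRAL, "up");   downSW <- sig_dir(degDRAL, "down")
  if (lenient) {
    upSW <- degDRAL$gene[!is.na(degDRAL$foldChange) & degDRAL$foldChange > 1]
    downSW <- degDRAL$gene[!is.na(degDRAL$foldChange) & degDRAL$foldChange < -1]
  }
  persistUp <- intersect(upDR, upSW)
  persistDown <- intersect(downDR, downSW)
  newUp <- setdiff(sig_dir(degDRAL, "up"), upDR)
  newDown <- setdiff(sig_dir(degDRAL, "down"), downDR)
  out <- list(
    nUpDR = length(upDR), nDownDR = length(downDR),
    nUpDRAL = length(sig_dir(degDRAL, "up")),
    nDownDRAL = length(sig_dir(degDRAL, "down")),
    nPersistUp = length(persistUp), nPersistDown = length(persistDown),
    pctPersistUp = if (length(upDR)) 100 * length(persistUp) / length(upDR)
                   else NA_real_,
    pctPersistDown = if (length(downDR))
                       100 * length(persistDown) / length(downDR)
                     else NA_real_,
    genes = list(upDR = upDR, downDR = downDR,
                 upDRAL = upSW, downDRAL = downSW,
                 persistUp = persistUp, persistDown = persistDown,
                 newUp = newUp, newDown = newDown),
    lenient = lenient)
  class(out) <- "PersistenceSummary"
  out
}

#' @export
print.PersistenceSummary <- function(x, ...) {
  cat("PersistenceSummary\n")
  cat(sprintf("  DR vs AL:    %d up, %d down\n", x$nUpDR, x$nDownDR))
  cat(sprintf("  DR-AL vs AL: %d up, %d down\n", x$nUpDRAL, x$nDownDRAL))
  cat(sprintf("  persistent:  %d up (%.1f%%), %d down (%.1f%%)\n",
              x$nPersistUp, x$pctPersistUp,
              x$nPersistDown, x$pctPersistDown))
  invisible(x)
}

#' Intersect persistent gene sets across tissues
#'
#' @param sets named list of at least two character vectors of gene
#'   identifiers (duplicates are dropped; set semantics).
#' @return A list with `common` (genes present in every set), `nCommon`,
#'   `setSizes`, and `pairwise` (data.frame of all pairwise intersection
#'   sizes with the member genes as a comma-separated string).
#' @examples
#' intersectTissues(list(liver = c("A", "B", "C"),
#'                       fat = c("B", "C", "D"),
#'                       colon = c("B", "C", "E")))$common
#' @importFrom utils combn
#' @export
intersectTissues <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("need a named list of >= 2 gene sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  common <- Reduce(intersect, sets)
  pairs <- combn(names(sets), 2L)
  pairwise <- data.frame(
    set1 = pairs[1L, ], set2 = pairs[2L, ],
    nCommon = apply(pairs, 2L, function(p) {
      length(intersect(sets[[p[1L]]], sets[[p[2L]]]))
    }),
    genes = apply(pairs, 2L, function(p) {
      paste(sort(intersect(sets[[p[1L]]], sets[[p[2L]]])), collapse = ",")
    }))
  list(common = sort(common), nCommon = length(common),
       setSizes = vapply(sets, length, 0L), pairwise = pairwise)
}
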