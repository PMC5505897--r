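#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom IRanges IRanges
NULL

#' CountTable: gene-by-library raw counts with per-library mapped-read totals
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay of non-negative integers and a mandatory
#' `totalMappedReads` column in `colData`. Totals are per-library *mapped*
#' read counts used for rate normalisation; they may exceed (and are not
#' required to equal) the column sums of the assay, because not every mapped
#' read is assigned to a gene.
#'
#' @seealso [CountTable()], [totalMappedReads()], [callDEGs()]
#' @export
setClass("CountTable", contains = "SummarizedExperiment")

setValidity("CountTable", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0)) {
      msg <- c(msg, "counts must be non-negative and non-missing")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"totalMappedReads" %in% colnames(cd)) {
    msg <- c(msg, "colData column 'totalMappedReads' is required")
  } else if (anyNA(cd$totalMappedReads) || any(cd$totalMappedReads <= 0)) {
    msg <- c(msg, "totalMappedReads must be strictly positive")
  }
  if (is.null(msg)) TRUE else msg
})

#' DEGTable: per-gene differential-expression results
#'
#' A [S4Vectors::DataFrame] subclass with one row per gene and columns
#' `gene`, `rate1`, `rate2` (reads per million mapped reads in each
#' library), `foldChange` (signed, so that |fc| >= 1 always), `z`, `p`,
#' `q` (Benjamini-Hochberg), `direction` (`"up"`, `"down"`, `"none"`) and
#' `significant`. Genes with zero counts in both libraries are retained in
#' the table (to preserve the gene universe) but carry `NA` statistics and
#' are excluded from the BH family. The comparison labels and thresholds
#' used are stored in `metadata()`.
#'
#' @seealso [callDEGs()], [classifyPersistence()]
#' @export
setClass("DEGTable", contains = "DFrame")

setValidity("DEGTable", function(object) {
  need <- c("gene", "rate1", "rate2", "foldChange", "z", "p", "q",
            "direction", "significant")
  miss <- setdiff(need, colnames(object))
  if (length(miss)) {
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  ok <- stats::complete.cases(object$p)
  if (any(object$p[ok] < 0 | object$p[ok] > 1)) return("p outside [0, 1]")
  TRUE
})

#' AmpliconSpec: a bisulfite amplicon reference with annotated cytosines
#'
#' Holds the amplicon reference sequence (top strand, uppercase A/C/G/T),
#' the ordered list of cytosine sites as 0-based offsets with their
#' sequence context (`"CG"` if the next reference base is G, otherwise
#' `"CH"` where H is A, C or T), and optional annotation intervals such as
#' a transcription-factor consensus motif span. The site list covers every
#' cytosine in the reference: BSAS quantifies methylation at single-base
#' resolution in both contexts.
#'
#' @slot name single character, amplicon label.
#' @slot seq [Biostrings::DNAString] reference sequence.
#' @slot sites [S4Vectors::DataFrame] with columns `offset` (0-based
#'   integer) and `context` (`"CG"`/`"CH"`), one row per reference cytosine,
#'   in increasing offset order.
#' @slot annotations [IRanges::IRanges] of named amplicon-local intervals
#'   (may be empty).
#' @seealso [AmpliconSpec()], [makeAmplicon()], [convertReference()]
#' @export
setClass("AmpliconSpec",
  slots = c(
    name = "character",
    seq = "DNAString",
    sites = "DFrame",
    annotations = "IRanges"
  )
)

setValidity("AmpliconSpec", function(object) {
  msg <- NULL
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  chars <- strsplit(as.character(object@seq), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    msg <- c(msg, "reference must contain only A/C/G/T")
  }
  st <- object@sites
  if (!all(c("offset", "context") %in% colnames(st))) {
    return(c(msg, "sites needs columns 'offset' and 'context'"))
  }
  cpos <- which(chars == "C") - 1L  # 0-based
  if (!identical(sort(as.integer(st$offset)), cpos)) {
    msg <- c(msg, "site list must cover exactly the reference's cytosines")
  }
  nxt <- chars[as.integer(st$offset) + 2L]  # base after each C (may be NA at end)
  expect_ctx <- as.character(ifelse(!is.na(nxt) & nxt == "G", "CG", "CH"))
  if (!identical(as.character(st$context), expect_ctx)) {
    msg <- c(msg, "context must be CG iff the next base is G")
  }
  if (is.null(msg)) TRUE else msg
})

#' MethCallMatrix: per-sample, per-site methylation calls
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with one row per
#' annotated cytosine site and one column per sample. Assays: `nMeth`
#' (C calls), `nUnmeth` (T calls), `nOther` (ignored calls) and `pct`
#' (percent methylation, `100 * nMeth / (nMeth + nUnmeth)`, `NA` where no
#' informative calls exist). `rowData` carries `offset`, `context` and
#' `covered` (whether the site met the coverage floor in every sample);
#' `colData` carries `group`, `nReads` (placed) and `nRejected`.
#'
#' @seealso [callSites()], [totalMethylation()], [testSites()]
#' @export
setClass("MethCallMatrix", contains = "SummarizedExperiment")

setValidity("MethCallMatrix", function(object) {
  need <- c("nMeth", "nUnmeth", "nOther", "pct")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss)) {
    return(paste("missing assays:", paste(miss, collapse = ", ")))
  }
  pct <- SummarizedExperiment::assay(object, "pct")
  ok <- !is.na(pct)
  if (any(pct[ok] < 0 | pct[ok] > 100)) return("pct outside [0, 100]")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("offset", "context") %in% colnames(rd))) {
    return("rowData needs 'offset' and 'context'")
  }
  TRUE
})

#' QpcrPlate: technical-replicate Ct values for a target and a control gene
#'
#' Long-format real-time PCR plate: one row per (sample, gene, technical
#' replicate) with the measured cycle-threshold value. The endogenous
#' control (e.g. beta-actin) must be present for every sample.
#'
#' @slot data data.frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @slot targetGene,controlGene single character gene labels; both must
#'   occur in `data$gene`.
#' @seealso [QpcrPlate()], [ddct()], [simulateQpcr()]
#' @export
setClass("QpcrPlate",
  slots = c(data = "data.frame", targetGene = "character",
            controlGene = "character")
)

setValidity("QpcrPlate", function(object) {
  d <- object@data
  need <- c("sample", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(is.finite(d$ct))) return("Ct values must be finite")
  for (g in c(object@targetGene, object@controlGene)) {
    if (!g %in% d$gene) return(paste("gene", g, "absent from plate"))
  }
  tab <- table(d$sample, d$gene)[, c(object@targetGene, object@controlGene),
                                 drop = FALSE]
  if (any(tab < 1L)) return("every sample needs >= 1 replicate per gene")
  TRUE
})

# ---- simulation scenarios ------------------------------------------------

#' ExpressionScenario: design of a synthetic pooled RNA-seq experiment
#'
#' Describes a three-group (AL, DR, DR-AL) pooled-library experiment with a
#' known fraction of up-/down-regulated genes, a common true fold change,
#' and a known fraction of affected genes whose DR effect persists after
#' the switch back to AL.
#'
#' @slot nGenes number of genes.
#' @slot groups ordered group labels; the first is the reference (AL).
#' @slot librarySizes total mapped reads per group, named by group.
#' @slot baselineMean expected reads per gene in the reference library.
#' @slot fracUp,fracDown fractions of genes truly up-/down-regulated under
#'   DR (`fracUp + fracDown <= 1`).
#' @slot effectFold true fold change of affected genes (>= 1).
#' @slot fracPersistent fraction of affected genes whose DR effect is
#'   retained in DR-AL.
#' @slot seed integer RNG seed.
#' @seealso [ExpressionScenario()], [simulateCounts()]
#' @export
setClass("ExpressionScenario",
  slots = c(nGenes = "integer", groups = "character",
            librarySizes = "numeric", baselineMean = "numeric",
            fracUp = "numeric", fracDown = "numeric",
            effectFold = "numeric", fracPersistent = "numeric",
            seed = "integer")
)

setValidity("ExpressionScenario", function(object) {
  msg <- NULL
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@groups) < 2L) msg <- c(msg, "need >= 2 groups")
  if (length(object@librarySizes) != length(object@groups) ||
      any(object@librarySizes <= 0)) {
    msg <- c(msg, "librarySizes must be positive, one per group")
  }
  if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be positive")
  fr <- c(object@fracUp, object@fracDown, object@fracPersistent)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@fracUp + object@fracDown > 1) {
    msg <- c(msg, "fracUp + fracDown must not exceed 1")
  }
  if (object@effectFold < 1) msg <- c(msg, "effectFold must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' MethylationScenario: design of a synthetic BSAS experiment
#'
#' Per-group, per-site true methylation fractions over an amplicon, with
#' sequencing depth, bisulfite conversion efficiency and a uniform
#' base-call error rate. Conversion inefficiency is modelled as
#' unconverted unmethylated cytosines, which read as C and therefore
#' inflate apparent methylation.
#'
#' @slot amplicon an [AmpliconSpec].
#' @slot groupSiteMethylation numeric matrix, groups x sites, values in
#'   \[0, 1\]; column order follows the amplicon's site list.
#' @slot depth reads per sample (the study design calls for > 1000x).
#' @slot conversionEfficiency fraction of unmethylated C successfully
#'   converted to T.
#' @slot baseErrorRate per-base uniform miscall probability.
#' @slot nSamplesPerGroup samples per group.
#' @slot seed integer RNG seed.
#' @seealso [MethylationScenario()], [simulateBisulfiteReads()]
#' @export
setClass("MethylationScenario",
  slots = c(amplicon = "AmpliconSpec", groupSiteMethylation = "matrix",
            depth = "integer", conversionEfficiency = "numeric",
            baseErrorRate = "numeric", nSamplesPerGroup = "integer",
            seed = "integer")
)

setValidity("MethylationScenario", function(object) {
  msg <- NULL
  m <- object@groupSiteMethylation
  if (ncol(m) != nrow(object@amplicon@sites)) {
    msg <- c(msg, "one methylation value per annotated site per group")
  }
  if (anyNA(m) || any(m < 0 | m > 1)) {
    msg <- c(msg, "methylation fractions must lie in [0, 1]")
  }
  if (is.null(rownames(m))) msg <- c(msg, "group rows must be named")
  if (object@depth < 1L) msg <- c(msg, "depth must be positive")
  pr <- c(object@conversionEfficiency, object@baseErrorRate)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@nSamplesPerGroup < 1L) msg <- c(msg, "need >= 1 sample per group")
  if (is.null(msg)) TRUE else msg
})

#' QpcrScenario: design of a synthetic comparative-Ct qPCR experiment
#'
#' Each group carries a true log2 expression offset relative to the
#' calibrator group (the first group, offset forced to be interpreted
#' relative to it). Target Ct decreases by one cycle per log2 unit of
#' expression; the endogenous-control Ct is flat across groups. Technical
#' replicates are drawn independently with Gaussian Ct noise.
#'
#' @slot groups ordered group labels; first is the calibrator.
#' @slot nSamplesPerGroup samples per group.
#' @slot log2Offsets per-group true log2 expression offset vs calibrator,
#'   named by group.
#' @slot controlCtMean,targetCtMean mean Ct of control gene and of the
#'   target gene in the calibrator group.
#' @slot nReplicates technical replicates per sample per gene (default 3).
#' @slot ctNoiseSd Gaussian sd of replicate Ct noise (cycles).
#' @slot seed integer RNG seed.
#' @seealso [QpcrScenario()], [simulateQpcr()], [ddct()]
#' @export
setClass("QpcrScenario",
  slots = c(groups = "character", nSamplesPerGroup = "integer",
            log2Offsets = "numeric", controlCtMean = "numeric",
            targetCtMean = "numeric", nReplicates = "integer",
            ctNoiseSd = "numeric", seed = "integer")
)

setValidity("QpcrScenario", function(object) {
  msg <- NULL
  if (length(object@groups) < 2L) msg <- c(msg, "need >= 2 groups")
  if (length(object@log2Offsets) != length(object@groups)) {
    msg <- c(msg, "one log2 offset per group")
  }
  if (object@nReplicates < 1L) msg <- c(msg, "replicate count must be >= 1")
  if (object@ctNoiseSd < 0) msg <- c(msg, "noise sd must be >= 0")
  if (object@nSamplesPerGroup < 1L) msg <- c(msg, "need >= 1 sample per group")
  if (is.null(msg)) TRUE else msg
})
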