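# Synthetic-data generators emulating the three-group dietary-restriction
# design: AL (ad libitum), DR (restricted to 60% of AL intake), and DR-AL
# (switched from DR back to AL). Ground truth is returned alongside every
# simulated data set so downstream estimates can be scored.

#' Construct an ExpressionScenario
#'
#' Defaults mirror the pooled RNA-seq design: one pooled library per diet
#' group, on the order of 8e7 mapped reads each, Poisson-distributed gene
#' counts, and a subset of genes whose DR-induced fold change either
#' persists in DR-AL or reverts.
#'
#' @param nGenes number of genes.
#' @param groups ordered group labels; the first is the AL reference, the
#'   second the DR group, the third (if present) the DR-AL switch group.
#' @param librarySizes per-group total mapped reads (recycled if scalar).
#' @param baselineMean expected reads per gene in the reference library.
#' @param fracUp,fracDown fractions of genes up-/down-regulated under DR.
#' @param effectFold true fold change of affected genes (>= 1).
#' @param fracPersistent fraction of affected genes whose DR effect is
#'   retained in DR-AL.
#' @param seed integer RNG seed.
#' @return An [ExpressionScenario-class].
#' @export
ExpressionScenario <- function(nGenes = 10000,
                               groups = c("AL", "DR", "DR-AL"),
                               librarySizes = 8e7,
                               baselineMean = 100,
                               fracUp = 0.05, fracDown = 0.05,
                               effectFold = 2,
                               fracPersistent = 0.3,
                               seed = 1L) {
  if (length(librarySizes) == 1L) {
    librarySizes <- rep(librarySizes, length(groups))
  }
  librarySizes <- as.numeric(librarySizes)
  names(librarySizes) <- groups
  new("ExpressionScenario", nGenes = as.integer(nGenes), groups = groups,
      librarySizes = librarySizes, baselineMean = as.numeric(baselineMean),
      fracUp = as.numeric(fracUp), fracDown = as.numeric(fracDown),
      effectFold = as.numeric(effectFold),
      fracPersistent = as.numeric(fracPersistent), seed = as.integer(seed))
}

#' Simulate pooled RNA-seq count libraries with known ground truth
#'
#' Assigns each gene a true status among `null`, `up_persistent`,
#' `up_transient`, `down_persistent` and `down_transient`: the status fully
#' determines the per-group rate multiplier (1 in AL; `effectFold` or
#' `1/effectFold` in DR; the DR multiplier again in DR-AL for persistent
#' genes, 1 for transient ones). Counts are drawn independently per gene
#' and library from a Poisson law with mean
#' `baselineMean * multiplier * librarySize / referenceLibrarySize`.
#'
#' @param scenario an [ExpressionScenario-class].
#' @return A list with `counts` (a [CountTable-class]) and `truth`
#'   (a [S4Vectors::DataFrame] with per-gene `status` and one
#'   `multiplier.<group>` column per group).
#' @examples
#' sim <- simulateCounts(ExpressionScenario(nGenes = 200, seed = 42))
#' table(sim$truth$status)
#' @importFrom stats rpois
#' @importFrom S4Vectors DataFrame metadata<-
#' @export
simulateCounts <- function(scenario) {
  stopifnot(is(scenario, "ExpressionScenario"))
  validObject(scenario)
  n <- scenario@nGenes
  groups <- scenario@groups
  libs <- scenario@librarySizes
  nUp <- round(scenario@fracUp * n)
  nDown <- round(scenario@fracDown * n)

  with_seed(scenario@seed, {
    idx <- sample.int(n)                       # which genes carry effects
    up <- idx[seq_len(nUp)]
    down <- idx[nUp + seq_len(nDown)]
    upPersist <- up[seq_len(round(scenario@fracPersistent * nUp))]
    downPersist <- down[seq_len(round(scenario@fracPersistent * nDown))]

    status <- rep("null", n)
    status[up] <- "up_transient"
    status[upPersist] <- "up_persistent"
    status[down] <- "down_transient"
    status[downPersist] <- "down_persistent"

    mult <- matrix(1, nrow = n, ncol = length(groups),
                   dimnames = list(NULL, groups))
    if (length(groups) >= 2L) {
      mult[up, 2L] <- scenario@effectFold
      mult[down, 2L] <- 1 / scenario@effectFold
    }
    if (length(groups) >= 3L) {
      mult[upPersist, 3L] <- scenario@effectFold
      mult[downPersist, 3L] <- 1 / scenario@effectFold
    }

    lambda <- scenario@baselineMean * mult %*% diag(libs / libs[1L],
                                                    length(groups))
    counts <- matrix(rpois(n * length(groups), lambda),
                     nrow = n, ncol = length(groups),
                     dimnames = list(sprintf("gene%05d", seq_len(n)), groups))

    truth <- DataFrame(gene = rownames(counts), status = status)
    for (g in groups) truth[[paste0("multiplier.", g)]] <- mult[, g]
    list(counts = CountTable(counts, totalMappedReads = libs), truth = truth)
  })
}

#' Construct a MethylationScenario
#'
#' @param amplicon an [AmpliconSpec-class].
#' @param groupSiteMethylation numeric matrix of true methylation fractions,
#'   one row per group (rownames are group labels), one column per
#'   annotated site in amplicon order. A per-group vector of length
#'   `nrow(ampliconSites(amplicon))` may also be supplied as a plain matrix
#'   built by `rbind()`.
#' @param depth reads per sample; the BSAS design calls for depth above
#'   1000x, the default here is 2000.
#' @param conversionEfficiency fraction of unmethylated cytosines
#'   successfully converted (default 1; incomplete conversion inflates
#'   apparent methylation).
#' @param baseErrorRate uniform per-base miscall probability (default 0).
#' @param nSamplesPerGroup samples per group (the study used 5 mice/group).
#' @param seed integer RNG seed.
#' @return A [MethylationScenario-class].
#' @export
MethylationScenario <- function(amplicon, groupSiteMethylation,
                                depth = 2000L, conversionEfficiency = 1,
                                baseErrorRate = 0, nSamplesPerGroup = 5L,
                                seed = 1L) {
  pm <- as.matrix(groupSiteMethylation)
  storage.mode(pm) <- "double"
  new("MethylationScenario", amplicon = amplicon,
      groupSiteMethylation = pm,
      depth = as.integer(depth),
      conversionEfficiency = as.numeric(conversionEfficiency),
      baseErrorRate = as.numeric(baseErrorRate),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      seed = as.integer(seed))
}

# One sample's reads as a character vector of full-length top-strand
# amplicon sequences in bisulfite space.
simulate_sample_reads <- function(refChars, siteOffsets, siteProbs,
                                  depth, conv, err) {
  L <- length(refChars)
  m <- matrix(refChars, nrow = depth, ncol = L, byrow = TRUE)
  for (j in seq_along(siteOffsets)) {
    meth <- stats::runif(depth) < siteProbs[j]
    converted <- !meth & (stats::runif(depth) < conv)
    m[, siteOffsets[j] + 1L] <- ifelse(converted, "T", "C")
  }
  if (err > 0) {
    hit <- which(matrix(stats::runif(depth * L), depth, L) < err)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      shift <- sample.int(3L, length(hit), replace = TRUE)
      m[hit] <- bases[(match(m[hit], bases) + shift - 1L) %% 4L + 1L]
    }
  }
  apply(m, 1L, paste, collapse = "")
}

#' Simulate bisulfite-converted amplicon reads with known ground truth
#'
#' For every read, each annotated cytosine is methylated with its site's
#' group-specific probability. Methylated cytosines stay C; unmethylated
#' cytosines convert to T with probability `conversionEfficiency` (an
#' unconverted unmethylated C reads as C, i.e. appears methylated).
#' Uniform base-call errors are then applied at `baseErrorRate`. Reads span
#' the full amplicon on the top strand.
#'
#' @param scenario a [MethylationScenario-class].
#' @return A list with `reads` (named list of [Biostrings::DNAStringSet],
#'   one per sample), `sampleSheet` (data.frame `sample`, `group`) and
#'   `truth` (list with the programmed `groupSiteMethylation` matrix, site
#'   offsets, and the conversion and error rates).
#' @examples
#' amp <- makeAmplicon(60, cgPositions = c(10, 30), seed = 3)
#' sc <- MethylationScenario(amp,
#'   groupSiteMethylation = matrix(0.5, 2, nrow(ampliconSites(amp)),
#'                                 dimnames = list(c("AL", "DR"), NULL)),
#'   depth = 50, nSamplesPerGroup = 2, seed = 9)
#' sim <- simulateBisulfiteReads(sc)
#' lengths(sim$reads)
#' @importFrom Biostrings DNAStringSet
#' @export
simulateBisulfiteReads <- function(scenario) {
  stopifnot(is(scenario, "MethylationScenario"))
  validObject(scenario)
  amp <- scenario@amplicon
  refChars <- strsplit(as.character(amp@seq), "", fixed = TRUE)[[1L]]
  offs <- as.integer(amp@sites$offset)
  groups <- rownames(scenario@groupSiteMethylation)

  with_seed(scenario@seed, {
    reads <- list()
    sheet <- data.frame(sample = character(), group = character())
    for (g in groups) {
      for (k in seq_len(scenario@nSamplesPerGroup)) {
        sm <- sprintf("%s_%d", g, k)
        strs <- simulate_sample_reads(
          refChars, offs, scenario@groupSiteMethylation[g, ],
          scenario@depth, scenario@conversionEfficiency,
          scenario@baseErrorRate)
        ss <- DNAStringSet(strs)
        names(ss) <- sprintf("%s_read%06d", sm, seq_along(ss))
        reads[[sm]] <- ss
        sheet <- rbind(sheet, data.frame(sample = sm, group = g))
      }
    }
    list(reads = reads, sampleSheet = sheet,
         truth = list(groupSiteMethylation = scenario@groupSiteMethylation,
                      siteOffsets = offs,
                      context = as.character(amp@sites$context),
                      conversionEfficiency = scenario@conversionEfficiency,
                      baseErrorRate = scenario@baseErrorRate))
  })
}

#' Write a bisulfite simulation to FASTQ files plus sidecars
#'
#' Emits one 4-line FASTQ (Phred+33, constant quality) per sample, a
#' sample-sheet TSV (`sample`, `group`, `fastq`) and a JSON truth sidecar
#' recording the programmed per-site fractions.
#'
#' @param sim result of [simulateBisulfiteReads()].
#' @param dir output directory (created if missing).
#' @param quality single Phred+33 quality character applied to every base.
#' @return Invisibly, the sample-sheet path.
#' @importFrom Biostrings writeXStringSet BStringSet width
#' @importFrom utils write.table
#' @export
writeBisulfiteReads <- function(sim, dir, quality = "I") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$sampleSheet
  # paths in the sheet are relative to its directory, so a run directory
  # can be moved or compared wholesale
  sheet$fastq <- paste0(sheet$sample, ".fastq")
  for (i in seq_len(nrow(sheet))) {
    ss <- sim$reads[[sheet$sample[i]]]
    quals <- BStringSet(strrep(quality, width(ss)))
    writeXStringSet(ss, file.path(dir, sheet$fastq[i]), format = "fastq",
                    qualities = quals)
  }
  sheetFile <- file.path(dir, "samples.tsv")
  write.table(sheet, sheetFile, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$groupSiteMethylation <-
    as.list(as.data.frame(t(truth$groupSiteMethylation)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sheetFile)
}

#' Read simulated (or real) per-sample amplicon FASTQ files
#'
#' @param sheetFile sample-sheet TSV with columns `sample`, `group`,
#'   `fastq` (paths relative to the sheet's directory or absolute).
#' @return A list with `reads` (named list of [Biostrings::DNAStringSet])
#'   and `sampleSheet`.
#' @importFrom Biostrings readDNAStringSet
#' @importFrom utils read.delim
#' @export
readBisulfiteReads <- function(sheetFile) {
  sheet <- read.delim(sheetFile)
  stopifnot(all(c("sample", "group", "fastq") %in% colnames(sheet)))
  reads <- list()
  for (i in seq_len(nrow(sheet))) {
    path <- sheet$fastq[i]
    if (!file.exists(path)) path <- file.path(dirname(sheetFile), path)
    if (!file.exists(path)) stop("FASTQ not found: ", sheet$fastq[i])
    reads[[sheet$sample[i]]] <- readDNAStringSet(path, format = "fastq")
  }
  list(reads = reads, sampleSheet = sheet[, c("sample", "group")])
}

#' Construct a QpcrScenario
#'
#' @param groups ordered labels; the first group is the calibrator (AL).
#' @param nSamplesPerGroup biological samples per group (study: 5).
#' @param log2Offsets true log2 expression offsets vs the calibrator, one
#'   per group (calibrator entry typically 0).
#' @param controlCtMean,targetCtMean mean Ct of the endogenous control and
#'   of the target gene in the calibrator group.
#' @param nReplicates technical replicates per sample per gene (study: 3).
#' @param ctNoiseSd Gaussian replicate noise sd in cycles.
#' @param seed integer RNG seed.
#' @return A [QpcrScenario-class].
#' @export
QpcrScenario <- function(groups = c("AL", "DR", "DR-AL"),
                         nSamplesPerGroup = 5L,
                         log2Offsets = c(0, 0, 0),
                         controlCtMean = 18, targetCtMean = 25,
                         nReplicates = 3L, ctNoiseSd = 0.1, seed = 1L) {
  names(log2Offsets) <- groups
  new("QpcrScenario", groups = groups,
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      log2Offsets = log2Offsets, controlCtMean = controlCtMean,
      targetCtMean = targetCtMean, nReplicates = as.integer(nReplicates),
      ctNoiseSd = ctNoiseSd, seed = as.integer(seed))
}

#' Simulate a comparative-Ct qPCR plate
#'
#' Target Ct per replicate is `targetCtMean - log2Offset[group] + noise`
#' (one PCR cycle per twofold change in template); control Ct is
#' `controlCtMean + noise`. Replicates are drawn independently.
#'
#' @param scenario a [QpcrScenario-class].
#' @return A [QpcrPlate-class] with target gene `"target"` and endogenous
#'   control `"control"`.
#' @examples
#' plate <- simulateQpcr(QpcrScenario(log2Offsets = c(0, 1, 2),
#'                                    ctNoiseSd = 0, seed = 2))
#' head(ddct(plate))
#' @importFrom stats rnorm
#' @export
simulateQpcr <- function(scenario) {
  stopifnot(is(scenario, "QpcrScenario"))
  validObject(scenario)
  with_seed(scenario@seed, {
    rows <- list()
    for (g in scenario@groups) {
      for (k in seq_len(scenario@nSamplesPerGroup)) {
        sm <- sprintf("%s_%d", g, k)
        nr <- scenario@nReplicates
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sm, group = g, gene = "target", replicate = seq_len(nr),
          ct = scenario@targetCtMean - scenario@log2Offsets[[g]] +
            rnorm(nr, sd = scenario@ctNoiseSd))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sm, group = g, gene = "control", replicate = seq_len(nr),
          ct = scenario@controlCtMean + rnorm(nr, sd = scenario@ctNoiseSd))
      }
    }
    QpcrPlate(do.call(rbind, rows), targetGene = "target",
              controlGene = "control")
  })
}
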