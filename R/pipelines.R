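# End-to-end orchestration: simulate -> differential expression ->
# persistence, and simulate -> methylation calling -> group statistics.
# Every run is deterministic given its scenario seed, and the JSON report
# records all parameters needed to reproduce it.

#' Run the expression pipeline: simulate, call DEGs, classify persistence
#'
#' Simulates the three-group pooled design, calls differential expression
#' for DR vs AL and DR-AL vs AL, classifies persistence, and scores the
#' calls against the simulation ground truth. When `outDir` is given, the
#' count table, both DEG tables, the persistent gene lists and a JSON
#' report (sufficient to reproduce the run via [rerunFromReport()]) are
#' written there.
#'
#' @param scenario an [ExpressionScenario-class] with at least 3 groups
#'   (reference, DR, DR-AL).
#' @param alpha,fcThreshold,pseudocount passed to [callDEGs()].
#' @param lenient passed to [classifyPersistence()].
#' @param outDir optional output directory.
#' @return A list with `counts`, `truth`, `degDR`, `degDRAL`,
#'   `persistence`, `truthRecovery` (estimated vs programmed persistence
#'   fractions) and `report`.
#' @examples
#' run <- runExpressionPipeline(ExpressionScenario(nGenes = 300, seed = 5))
#' run$persistence
#' @export
runExpressionPipeline <- function(scenario, alpha = 0.05,
                                  fcThreshold = 1.25, pseudocount = 0.5,
                                  lenient = FALSE, outDir = NULL) {
  stopifnot(is(scenario, "ExpressionScenario"))
  if (length(scenario@groups) < 3L) {
    stop("expression pipeline needs reference, DR and DR-AL groups",
         call. = FALSE)
  }
  sim <- simulateCounts(scenario)
  ref <- scenario@groups[1L]
  degDR <- callDEGs(sim$counts, c(ref, scenario@groups[2L]),
                    alpha = alpha, fcThreshold = fcThreshold,
                    pseudocount = pseudocount)
  degDRAL <- callDEGs(sim$counts, c(ref, scenario@groups[3L]),
                      alpha = alpha, fcThreshold = fcThreshold,
                      pseudocount = pseudocount)
  pers <- classifyPersistence(degDR, degDRAL, lenient = lenient)

  # score against ground truth: among truly affected genes detected in DR,
  # which fraction was classified persistent
  st <- sim$truth$status
  affectedUp <- sim$truth$gene[st %in% c("up_persistent", "up_transient")]
  affectedDown <- sim$truth$gene[st %in% c("down_persistent",
                                           "down_transient")]
  detUp <- intersect(pers$genes$upDR, affectedUp)
  detDown <- intersect(pers$genes$downDR, affectedDown)
  estFracUp <- if (length(detUp)) {
    mean(detUp %in% pers$genes$persistUp)
  } else NA_real_
  estFracDown <- if (length(detDown)) {
    mean(detDown %in% pers$genes$persistDown)
  } else NA_real_

  report <- list(
    pipeline = "expression",
    version = pkg_version_string(),
    scenario = list(nGenes = scenario@nGenes, groups = scenario@groups,
                    librarySizes = as.list(scenario@librarySizes),
                    baselineMean = scenario@baselineMean,
                    fracUp = scenario@fracUp, fracDown = scenario@fracDown,
                    effectFold = scenario@effectFold,
                    fracPersistent = scenario@fracPersistent,
                    seed = scenario@seed),
    thresholds = list(alpha = alpha, fcThreshold = fcThreshold,
                      pseudocount = pseudocount, lenient = lenient),
    results = list(nUpDR = pers$nUpDR, nDownDR = pers$nDownDR,
                   nPersistUp = pers$nPersistUp,
                   nPersistDown = pers$nPersistDown,
                   estFracPersistentUp = estFracUp,
                   estFracPersistentDown = estFracDown))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCountTable(sim$counts, file.path(outDir, "counts.tsv"))
    writeDEGTable(degDR, file.path(outDir, "deg_DR_vs_AL.tsv"))
    writeDEGTable(degDRAL, file.path(outDir, "deg_DRAL_vs_AL.tsv"))
    for (nm in names(pers$genes)) {
      writeLines(pers$genes[[nm]],
                 file.path(outDir, paste0("genes_", nm, ".txt")))
    }
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(counts = sim$counts, truth = sim$truth, degDR = degDR,
       degDRAL = degDRAL, persistence = pers,
       truthRecovery = list(estFracPersistentUp = estFracUp,
                            estFracPersistentDown = estFracDown,
                            programmed = scenario@fracPersistent),
       report = report)
}

#' Run the methylation pipeline: simulate reads, call sites, test groups
#'
#' Simulates bisulfite amplicon reads, places them, calls per-site
#' methylation, aggregates total CG and CH methylation per sample, and
#' runs the group statistics: ANOVA with Tukey HSD on totals, per-site
#' ANOVA with BH correction within each context family.
#'
#' @param scenario a [MethylationScenario-class].
#' @param alpha FDR / significance threshold.
#' @param minCoverage,maxMm passed to [callSites()].
#' @param weighting passed to [totalMethylation()].
#' @param outDir optional output directory.
#' @return A list with `calls` (a [MethCallMatrix-class]), `totals`
#'   (per-context per-sample totals), `totalTests` (per context, or `NULL`
#'   when fewer than 2 samples per group), `siteResults`, and `report`.
#' @examples
#' amp <- makeAmplicon(80, cgPositions = c(20, 50), seed = 1)
#' pm <- matrix(0.5, 2, nrow(ampliconSites(amp)),
#'              dimnames = list(c("AL", "DR"), NULL))
#' run <- runMethylationPipeline(
#'   MethylationScenario(amp, pm, depth = 200, nSamplesPerGroup = 2,
#'                       seed = 3),
#'   minCoverage = 100)
#' @importFrom SummarizedExperiment colData
#' @export
runMethylationPipeline <- function(scenario, alpha = 0.05,
                                   minCoverage = 1000L, maxMm = 0.1,
                                   weighting = "site-mean",
                                   outDir = NULL) {
  stopifnot(is(scenario, "MethylationScenario"))
  sim <- simulateBisulfiteReads(scenario)
  calls <- callSites(sim$reads, scenario@amplicon,
                     groups = sim$sampleSheet$group,
                     minCoverage = minCoverage, maxMm = maxMm)
  groups <- as.character(colData(calls)$group)
  contexts <- intersect(c("CG", "CH"),
                        unique(scenario@amplicon@sites$context))
  totals <- lapply(stats::setNames(contexts, contexts), function(ctx) {
    totalMethylation(calls, ctx, weighting = weighting)
  })
  canTest <- length(unique(groups)) >= 2L && all(table(groups) >= 2L)
  totalTests <- if (canTest) {
    lapply(totals, function(tt) testTotal(tt, groups))
  }
  siteResults <- if (length(unique(groups)) >= 2L) testSites(calls, alpha)

  report <- list(
    pipeline = "methylation",
    version = pkg_version_string(),
    scenario = list(
      ampliconName = scenario@amplicon@name,
      ampliconSeq = as.character(scenario@amplicon@seq),
      groupSiteMethylation =
        as.list(as.data.frame(t(scenario@groupSiteMethylation))),
      depth = scenario@depth,
      conversionEfficiency = scenario@conversionEfficiency,
      baseErrorRate = scenario@baseErrorRate,
      nSamplesPerGroup = scenario@nSamplesPerGroup,
      seed = scenario@seed),
    thresholds = list(alpha = alpha, minCoverage = as.integer(minCoverage),
                      maxMm = maxMm, weighting = weighting),
    results = list(
      totalMeans = lapply(totals, function(tt) {
        as.list(tapply(tt, groups, mean))
      }),
      nFlaggedSites = if (!is.null(siteResults)) {
        sum(siteResults$flagged, na.rm = TRUE)
      } else NA))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeBisulfiteReads(sim, file.path(outDir, "reads"))
    writeMethCalls(calls, file.path(outDir, "site_calls.tsv"))
    if (!is.null(siteResults)) {
      utils::write.table(siteResults,
                         file.path(outDir, "site_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeSiteTrack(siteResults, file.path(outDir, "site_tests.bed"),
                     ampliconName = scenario@amplicon@name)
    }
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(calls = calls, totals = totals, totalTests = totalTests,
       siteResults = siteResults, report = report)
}

#' Reproduce a pipeline run from its JSON report
#'
#' The report written by [runExpressionPipeline()] or
#' [runMethylationPipeline()] records the full scenario and all
#' thresholds; feeding it back re-executes the identical run.
#'
#' @param reportFile path to a pipeline `report.json`.
#' @param outDir optional output directory for the re-run.
#' @return The pipeline result list (see the respective pipeline).
#' @export
rerunFromReport <- function(reportFile, outDir = NULL) {
  rp <- jsonlite::read_json(reportFile, simplifyVector = TRUE)
  th <- rp$thresholds
  if (identical(rp$pipeline, "expression")) {
    sc <- rp$scenario
    scenario <- ExpressionScenario(
      nGenes = sc$nGenes, groups = sc$groups,
      librarySizes = unlist(sc$librarySizes),
      baselineMean = sc$baselineMean, fracUp = sc$fracUp,
      fracDown = sc$fracDown, effectFold = sc$effectFold,
      fracPersistent = sc$fracPersistent, seed = sc$seed)
    runExpressionPipeline(scenario, alpha = th$alpha,
                          fcThreshold = th$fcThreshold,
                          pseudocount = th$pseudocount,
                          lenient = th$lenient, outDir = outDir)
  } else if (identical(rp$pipeline, "methylation")) {
    sc <- rp$scenario
    amp <- AmpliconSpec(sc$ampliconSeq, name = sc$ampliconName)
    pm <- do.call(rbind, sc$groupSiteMethylation)
    scenario <- MethylationScenario(
      amp, pm, depth = sc$depth,
      conversionEfficiency = sc$conversionEfficiency,
      baseErrorRate = sc$baseErrorRate,
      nSamplesPerGroup = sc$nSamplesPerGroup, seed = sc$seed)
    runMethylationPipeline(scenario, alpha = th$alpha,
                           minCoverage = th$minCoverage,
                           maxMm = th$maxMm, weighting = th$weighting,
                           outDir = outDir)
  } else {
    stop("unrecognised pipeline in report: ", rp$pipeline, call. = FALSE)
  }
}
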