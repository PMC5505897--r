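# Synthetic-data generators: truth bookkeeping, distributional checks,
# determinism.

test_that("simulateCounts bookkeeping follows the scenario definition", {
  # no effects: everything null, all multipliers 1
  sc0 <- ExpressionScenario(nGenes = 50, fracUp = 0, fracDown = 0,
                            seed = 1)
  sim0 <- simulateCounts(sc0)
  expect_true(all(sim0$truth$status == "null"))
  expect_true(all(sim0$truth$multiplier.DR == 1))
  expect_true(all(sim0$truth$`multiplier.DR-AL` == 1))

  # fully persistent: exactly round(fracUp * n) genes at effectFold in
  # both DR and DR-AL
  sc1 <- ExpressionScenario(nGenes = 250, fracUp = 0.1, fracDown = 0,
                            effectFold = 2, fracPersistent = 1, seed = 2)
  sim1 <- simulateCounts(sc1)
  expect_equal(sum(sim1$truth$multiplier.DR == 2), round(0.1 * 250))
  expect_equal(sum(sim1$truth$`multiplier.DR-AL` == 2), round(0.1 * 250))
  expect_identical(sim1$truth$multiplier.DR,
                   sim1$truth$`multiplier.DR-AL`)

  # transient fraction: persistent genes are a subset of DR-affected ones
  sc2 <- ExpressionScenario(nGenes = 1000, fracUp = 0.2, fracDown = 0.1,
                            fracPersistent = 0.4, seed = 3)
  st <- simulateCounts(sc2)$truth$status
  expect_equal(sum(st == "up_persistent"), round(0.4 * round(0.2 * 1000)))
  expect_equal(sum(st == "down_persistent"),
               round(0.4 * round(0.1 * 1000)))
  expect_equal(sum(st != "null"), round(0.2 * 1000) + round(0.1 * 1000))
})

test_that("simulateCounts draws Poisson counts at the programmed means", {
  # unequal library sizes exercise the depth scaling
  sc <- ExpressionScenario(nGenes = 10000, librarySizes = c(1e6, 2e6, 1e6),
                           baselineMean = 100, fracUp = 0.1, fracDown = 0,
                           effectFold = 2, fracPersistent = 1, seed = 4)
  sim <- simulateCounts(sc)
  up <- sim$truth$status == "up_persistent"
  cnt <- SummarizedExperiment::assay(sim$counts, "counts")
  # expected mean in DR: 100 * 2 * (2e6 / 1e6) = 400
  m <- mean(cnt[up, "DR"])
  se <- sd(cnt[up, "DR"]) / sqrt(sum(up))
  expect_lt(abs(m - 400), 3 * se)
  # null genes in the reference library stay at baseline
  m0 <- mean(cnt[!up, "AL"])
  se0 <- sd(cnt[!up, "AL"]) / sqrt(sum(!up))
  expect_lt(abs(m0 - 100), 3 * se0)
})

test_that("simulateCounts and simulateBisulfiteReads are deterministic", {
  sc <- ExpressionScenario(nGenes = 100, seed = 7)
  expect_identical(simulateCounts(sc), simulateCounts(sc))
  sc2 <- ExpressionScenario(nGenes = 100, seed = 8)
  expect_false(identical(
    SummarizedExperiment::assay(simulateCounts(sc)$counts),
    SummarizedExperiment::assay(simulateCounts(sc2)$counts)))

  amp <- makeAmplicon(60, cgPositions = c(10, 30), seed = 1)
  pm <- matrix(0.5, 1, nrow(ampliconSites(amp)),
               dimnames = list("AL", NULL))
  ms <- MethylationScenario(amp, pm, depth = 30, nSamplesPerGroup = 2,
                            seed = 5)
  s1 <- simulateBisulfiteReads(ms)
  s2 <- simulateBisulfiteReads(ms)
  expect_identical(lapply(s1$reads, as.character),
                   lapply(s2$reads, as.character))

  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateCounts(sc)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("scenario validation rejects invalid rates and sizes", {
  expect_error(ExpressionScenario(nGenes = 0), "positive")
  expect_error(ExpressionScenario(librarySizes = -1), "positive")
  expect_error(ExpressionScenario(fracUp = 0.7, fracDown = 0.5), "exceed")
  expect_error(ExpressionScenario(effectFold = 0.5), ">= 1")
  amp <- makeAmplicon(20, cgPositions = 5, seed = 1)
  expect_error(
    MethylationScenario(amp, matrix(1.5, 1, nrow(ampliconSites(amp)),
                                    dimnames = list("AL", NULL))),
    "\\[0, 1\\]")
  expect_error(QpcrScenario(ctNoiseSd = -1), "sd")
  expect_error(QpcrScenario(nReplicates = 0), "replicate")
})

test_that("makeAmplicon plants exactly the requested CG layout", {
  layouts <- list(
    nts1 = list(len = 397, cg = c(60, 180, 300)),
    hsph1 = list(len = 342, cg = c(40, 120, 200, 260, 320)),
    pomc = list(len = 560, cg = seq(15, 540, length.out = 22)),
    empty = list(len = 100, cg = integer())
  )
  for (nm in names(layouts)) {
    ly <- layouts[[nm]]
    cg <- as.integer(round(ly$cg))
    amp <- makeAmplicon(ly$len, cgPositions = cg, seed = 11, name = nm)
    seq <- as.character(ampliconSeq(amp))
    # brute-force CG scan of the emitted sequence
    hits <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
    scan <- if (hits[1L] == -1L) integer() else as.integer(hits) - 1L
    expect_identical(scan, cg, label = nm)
    st <- ampliconSites(amp)
    expect_identical(as.integer(st$offset[st$context == "CG"]), cg)
    # every annotated site is a C and contexts match the next base
    chars <- strsplit(seq, "")[[1L]]
    expect_true(all(chars[st$offset + 1L] == "C"))
    nxt <- chars[st$offset + 2L]
    expect_identical(as.character(st$context),
                     ifelse(!is.na(nxt) & nxt == "G", "CG", "CH"))
  }
  expect_error(makeAmplicon(100, cgPositions = c(10, 11), seed = 1),
               "overlap")
  expect_error(makeAmplicon(100, cgPositions = 99, seed = 1),
               "length - 2")
})

test_that("bisulfite reads follow the programmed methylation model", {
  amp <- makeAmplicon(80, cgPositions = c(20, 50), seed = 2)
  ns <- nrow(ampliconSites(amp))
  mk <- function(p, conv = 1, err = 0, depth = 200, seed = 31) {
    pm <- matrix(p, 1, ns, dimnames = list("AL", NULL))
    simulateBisulfiteReads(MethylationScenario(
      amp, pm, depth = depth, conversionEfficiency = conv,
      baseErrorRate = err, nSamplesPerGroup = 1, seed = seed))
  }
  offs <- ampliconSites(amp)$offset

  # saturated: methylation 1, no error -> C at every site in every read
  r1 <- mk(1)$reads[[1L]]
  for (o in offs) expect_equal(site_pct_brute(r1, o), 100)

  # fully converted: methylation 0, efficiency 1 -> T everywhere
  r0 <- mk(0)$reads[[1L]]
  for (o in offs) expect_equal(site_pct_brute(r0, o), 0)

  # binomial oracle at 0.5 and depth 10000
  rh <- mk(0.5, depth = 10000, seed = 13)$reads[[1L]]
  for (o in offs) {
    expect_lt(abs(site_pct_brute(rh, o) / 100 - 0.5),
              3 * sqrt(0.25 / 10000))
  }

  # non-site positions match the reference when error-free
  ref <- as.character(ampliconSeq(amp))
  nonC <- setdiff(seq_len(nchar(ref)), offs + 1L)
  rchars <- strsplit(as.character(r1[1L]), "")[[1L]]
  expect_identical(rchars[nonC], strsplit(ref, "")[[1L]][nonC])

  # incomplete conversion inflates apparent methylation at a 0% site
  rc <- mk(0, conv = 0.9, depth = 5000, seed = 17)$reads[[1L]]
  app <- site_pct_brute(rc, offs[1L]) / 100
  expect_lt(abs(app - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("qPCR simulation honours its closed forms", {
  # offset 0, no noise -> rq exactly 1 everywhere
  p0 <- simulateQpcr(QpcrScenario(log2Offsets = c(0, 0, 0), ctNoiseSd = 0,
                                  seed = 1))
  expect_equal(ddct(p0)$rq, rep(1, 15))

  # +1 log2 offset, no noise -> rq exactly 2 in that group
  p1 <- simulateQpcr(QpcrScenario(log2Offsets = c(0, 1, 0), ctNoiseSd = 0,
                                  seed = 1))
  r1 <- ddct(p1)
  expect_equal(r1$rq[r1$group == "DR"], rep(2, 5))

  # Gaussian propagation: recovered group mean log2 expression within 3 SE
  pn <- simulateQpcr(QpcrScenario(log2Offsets = c(0, 1.5, 0),
                                  ctNoiseSd = 0.1, nSamplesPerGroup = 5,
                                  seed = 21))
  rn <- ddct(pn)
  est <- -rn$ddct[rn$group == "DR"]       # log2 expression per sample
  # each ddct combines 4 replicate means of sd 0.1 (2 genes x 2 groups in
  # the calibrator mean); bound the SE generously by propagation
  se <- sqrt(4 * 0.1^2 / 3) / sqrt(5)
  expect_lt(abs(mean(est) - 1.5), 3 * se)
})
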