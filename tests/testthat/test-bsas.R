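# BSAS quantitation: reference conversion, read placement in bisulfite
# space, per-site calling and the group statistics.

test_that("convertReference replaces every C and keeps the site map", {
  expect_equal(convertReference(AmpliconSpec("ACGT")),
               list(converted = "ATGT", cytosineOffsets = 1L))
  expect_equal(convertReference(AmpliconSpec("ATGGTA"))$converted,
               "ATGGTA")

  amp <- makeAmplicon(397, cgPositions = c(50, 200, 350), seed = 19)
  conv <- convertReference(amp)
  # per-character oracle
  chars <- strsplit(as.character(ampliconSeq(amp)), "")[[1L]]
  oracle <- paste(ifelse(chars == "C", "T", chars), collapse = "")
  expect_identical(conv$converted, oracle)
  expect_identical(conv$cytosineOffsets, which(chars == "C") - 1L)
})

test_that("placeReads accepts bisulfite-space matches and rejects noise", {
  amp <- makeAmplicon(100, cgPositions = c(20, 60), seed = 23)
  conv <- convertReference(amp)$converted
  st <- ampliconSites(amp)

  # fully converted read: offset 0, zero mismatches
  p0 <- placeReads(conv, amp)
  expect_equal(p0$offset, 0L)
  expect_equal(p0$mismatches, 0L)
  expect_true(p0$accepted)

  # C at cytosine positions is equally a perfect match (C/T ambiguity)
  chars <- strsplit(conv, "")[[1L]]
  chars[st$offset + 1L] <- "C"
  pC <- placeReads(paste(chars, collapse = ""), amp)
  expect_equal(pC$mismatches, 0L)

  # internal fragment is placed at its true offset
  frag <- substr(conv, 31, 70)
  pf_ <- placeReads(frag, amp)
  expect_equal(pf_$offset, 30L)
  expect_equal(pf_$mismatches, 0L)

  # 15% mismatches at non-cytosine positions exceed maxMm = 0.1
  set.seed(5)
  chars <- strsplit(conv, "")[[1L]]
  nonC <- setdiff(seq_along(chars), st$offset + 1L)
  flip <- sample(nonC, 15)
  chars[flip] <- vapply(chars[flip], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1L]
  }, "")
  noisy <- paste(chars, collapse = "")
  expect_false(placeReads(noisy, amp)$accepted)
  expect_true(is.na(placeReads(noisy, amp)$offset))
  expect_true(placeReads(noisy, amp, maxMm = 0.2)$accepted)

  # ties resolve to the smallest offset
  rep_amp <- AmpliconSpec(strrep("AT", 10))
  expect_equal(placeReads("ATAT", rep_amp)$offset, 0L)

  expect_error(placeReads(strrep("A", 101), amp), "exceeds")
})

test_that("callSites counts C as methylated and T as unmethylated", {
  amp <- makeAmplicon(30, cgPositions = 10, seed = 29)
  conv <- convertReference(amp)$converted
  st <- ampliconSites(amp)
  site <- 10L

  # 7 methylated / 3 unmethylated reads at the CG site
  mk_read <- function(base) {
    chars <- strsplit(conv, "")[[1L]]
    chars[site + 1L] <- base
    paste(chars, collapse = "")
  }
  reads <- Biostrings::DNAStringSet(c(rep(mk_read("C"), 7),
                                      rep(mk_read("T"), 3)))
  m <- callSites(list(s1 = reads), amp, groups = "AL", minCoverage = 5)
  i <- which(SummarizedExperiment::rowData(m)$offset == site)
  expect_equal(SummarizedExperiment::assay(m, "pct")[i, "s1"], 70)
  expect_equal(SummarizedExperiment::assay(m, "nMeth")[i, "s1"], 7L)

  # all-T reads: 0 percent
  readsT <- Biostrings::DNAStringSet(rep(mk_read("T"), 10))
  mT <- callSites(list(s1 = readsT), amp, groups = "AL", minCoverage = 5)
  expect_equal(SummarizedExperiment::assay(mT, "pct")[i, "s1"], 0)

  # a G call at the site is 'other' and excluded from the percentage
  readsG <- Biostrings::DNAStringSet(c(rep(mk_read("C"), 5), mk_read("G")))
  mG <- callSites(list(s1 = readsG), amp, groups = "AL", minCoverage = 2)
  expect_equal(SummarizedExperiment::assay(mG, "nOther")[i, "s1"], 1L)
  expect_equal(SummarizedExperiment::assay(mG, "pct")[i, "s1"], 100)

  # below the coverage floor the site is flagged uncovered
  mLow <- callSites(list(s1 = reads), amp, groups = "AL",
                    minCoverage = 50)
  expect_false(any(SummarizedExperiment::rowData(mLow)$covered))

  expect_warning(callSites(list(s1 = Biostrings::DNAStringSet()), amp,
                           groups = "AL"),
                 "empty")
})

test_that("callSites recovers programmed fractions at depth (binomial)", {
  amp <- makeAmplicon(50, cgPositions = c(10, 30), seed = 2)
  ns <- nrow(ampliconSites(amp))
  pm <- matrix(0.42, 1, ns, dimnames = list("AL", NULL))
  sim <- simulateBisulfiteReads(MethylationScenario(
    amp, pm, depth = 5000, nSamplesPerGroup = 1, seed = 37))
  m <- callSites(sim$reads, amp, groups = "AL", minCoverage = 1000)
  pct <- SummarizedExperiment::assay(m, "pct")[, 1L]
  expect_true(all(abs(pct / 100 - 0.42) < 3 * sqrt(0.42 * 0.58 / 5000)))
})

test_that("totalMethylation aggregates site percentages per context", {
  amp <- makeAmplicon(60, cgPositions = c(10, 25, 40), seed = 3)
  st <- ampliconSites(amp)
  ns <- nrow(st)
  # programme CG sites at 40/50/60% and CH sites at 0
  p <- rep(0, ns)
  p[st$context == "CG"] <- c(0.4, 0.5, 0.6)
  pm <- matrix(p, 1, ns, dimnames = list("AL", NULL), byrow = TRUE)
  sim <- simulateBisulfiteReads(MethylationScenario(
    amp, pm, depth = 4000, nSamplesPerGroup = 1, seed = 41))
  m <- callSites(sim$reads, amp, groups = "AL", minCoverage = 1000)

  cg <- totalMethylation(m, "CG")
  pct <- SummarizedExperiment::assay(m, "pct")
  sel <- SummarizedExperiment::rowData(m)$context == "CG"
  expect_equal(unname(cg), mean(pct[sel, 1L]))
  expect_lt(abs(cg - 50), 2)

  # equal coverage at all sites: read-weighted equals the site mean
  rw <- totalMethylation(m, "CG", weighting = "read-weighted")
  expect_equal(unname(rw), unname(cg), tolerance = 1e-10)

  # context separation: CH total reflects only CH sites (programmed 0)
  ch <- totalMethylation(m, "CH")
  expect_lt(ch, 1)
  expect_gt(cg, 40)

  # no covered site of a context -> undefined
  cgOnly <- callSites(sim$reads, amp, groups = "AL", minCoverage = 1e6)
  expect_error(totalMethylation(cgOnly, "CG"), "undefined")
})

test_that("testTotal reports ANOVA, Tukey and percent decrease vs AL", {
  set.seed(47)
  totals <- c(rnorm(5, 70, 1), rnorm(5, 60, 1), rnorm(5, 58, 1))
  groups <- rep(c("AL", "DR", "DR-AL"), each = 5)
  res <- testTotal(totals, groups)
  expect_lt(res$anova$p, 0.001)
  want <- 100 * (mean(totals[1:5]) - mean(totals[6:10])) /
    mean(totals[1:5])
  expect_equal(unname(res$pctDecrease["DR"]), want)

  # trivial definition: 50 vs a reference mean of 100 is a 50% decrease
  res2 <- testTotal(c(100, 100, 50, 50), rep(c("AL", "DR"), each = 2))
  expect_equal(unname(res2$pctDecrease["DR"]), 50)

  # identical values: F = 0 convention, no pair significant
  flat <- testTotal(rep(60, 9), rep(c("AL", "DR", "DR-AL"), each = 3))
  expect_equal(flat$anova$F, 0)
  expect_true(all(flat$tukey$padj == 1))

  expect_error(testTotal(1:4, rep("AL", 4)), ">= 2 groups")
  expect_error(testTotal(1:3, c("AL", "DR", "DR")), ">= 2 samples")
})

test_that("testSites flags programmed sites within separate BH families", {
  amp <- makeAmplicon(397, cgPositions = c(60, 180, 300), seed = 7,
                      name = "nts1_like")
  st <- ampliconSites(amp)
  ns <- nrow(st)
  base <- rep(0.30, ns)
  base[st$context == "CG"] <- c(0.70, 0.45, 0.80)
  dr <- base
  dr[st$context == "CG"][1L] <- 0.40   # one CG site decreased 30 points
  pm <- rbind(AL = base, DR = dr)
  sim <- simulateBisulfiteReads(MethylationScenario(
    amp, pm, depth = 2000, nSamplesPerGroup = 5, seed = 53))
  m <- callSites(sim$reads, amp, minCoverage = 1000)
  res <- testSites(m, alpha = 0.05)

  cgRes <- res[res$context == "CG", ]
  target <- cgRes$offset == 60
  expect_true(cgRes$flagged[target])
  expect_false(any(cgRes$flagged[!target]))

  # BH applied within each context family, never across
  expect_equal(res$q[res$context == "CG"],
               bh_brute(res$p[res$context == "CG"]))
  expect_equal(res$q[res$context == "CH"],
               bh_brute(res$p[res$context == "CH"]))

  # single group rejected
  one <- callSites(sim$reads[1:5], amp, groups = rep("AL", 5),
                   minCoverage = 1000)
  expect_error(testSites(one), ">= 2 groups")
})

test_that("null per-site tests stay near the BH false-flag expectation", {
  amp <- makeAmplicon(120, cgPositions = c(20, 60, 100), seed = 9)
  ns <- nrow(ampliconSites(amp))
  pm <- matrix(0.5, 2, ns, dimnames = list(c("AL", "DR"), NULL))
  sim <- simulateBisulfiteReads(MethylationScenario(
    amp, pm, depth = 1200, nSamplesPerGroup = 4, seed = 61))
  m <- callSites(sim$reads, amp, minCoverage = 1000)
  res <- testSites(m, alpha = 0.05)
  # with no true effects, BH keeps false flags rare
  expect_lte(sum(res$flagged), ceiling(0.05 * nrow(res)) + 1)
})
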