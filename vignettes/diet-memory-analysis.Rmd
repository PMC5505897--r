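---
title: "Analysing dietary-restriction memory: pooled differential expression, persistence, and promoter methylation"
author: "dremseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dietary-restriction memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dremseq)
```

# The question and the designs

Dietary restriction (DR, here 60% of ad-libitum intake) changes gene
expression in many tissues. The question this package addresses is
*cellular memory*: when DR is discontinued and the animals return to
ad-libitum feeding (the DR-AL group), which DR-induced changes persist,
and is persistent expression accompanied by persistent promoter
methylation changes?

Three assay designs are supported, each with a matched synthetic-data
generator that carries its ground truth:

1. **Pooled RNA-seq.** One pooled library per diet group per tissue (no
   biological replicates), tens of millions of mapped reads each.
2. **Real-time qPCR.** Individual samples (typically 5 per group), three
   technical replicates, an endogenous control gene (beta-actin),
   quantified by the comparative-Ct method.
3. **BSAS** (bisulfite amplicon sequencing). A 300–600 bp promoter
   amplicon sequenced to depth above 1000x per sample, giving absolute
   single-cytosine methylation in both CG and CH contexts (H = A, C or
   T).

# Differential expression between pooled libraries

With one library per group there is no dispersion to estimate, so the
test leans entirely on the Poisson behaviour of read counts. For gene
counts $x_1, x_2$ in libraries with total mapped reads $N_1, N_2$:

* counts are normalised to rates $x/N$ (total-mapped-read
  normalisation);
* the square root is applied as a variance-stabilising transform: for
  $X \sim \mathrm{Pois}(\lambda)$ the delta method gives
  $\mathrm{Var}\,\sqrt{X/N} \approx 1/(4N)$, independent of $\lambda$;
* the statistic is
  $z = \dfrac{\sqrt{x_1/N_1} - \sqrt{x_2/N_2}}
             {\tfrac12\sqrt{1/N_1 + 1/N_2}}$
  with a two-sided normal p-value.

The denominator is the unique constant-variance consequence of the
sqrt/Poisson argument; it is exactly why the transform is used. `z` is
finite for all valid inputs, including zero counts, and its magnitude
grows with depth — deeper libraries give more power, which is a feature
of the statistic, not a normalisation artefact (the rates and fold
changes, by contrast, are exactly invariant to rescaling a library's
count and total together).

Benjamini–Hochberg correction is applied across all tested genes of a
comparison; a gene is called when $q < \alpha$ (default 0.05) **and**
its signed fold change satisfies $|fc| \ge 1.25$ (default). The signed
convention reports the rate ratio $r$ as $r$ when $r \ge 1$ and $-1/r$
otherwise, so $|fc| \ge 1$ always.

```{r de}
sim <- simulateCounts(ExpressionScenario(nGenes = 500, librarySizes = 1e7,
                                         seed = 42))
deg <- callDEGs(sim$counts, c("AL", "DR"))
summary(deg$q[deg$significant])
```

Numerical choices worth knowing:

* **Both-zero genes** are excluded from testing and from the BH family
  (their $z$ would be 0 and would only dilute the correction), but kept
  in the table with `NA` statistics so the gene universe is stable.
* **Pseudocount** (default 0.5) enters the fold change only when one
  count is zero, in which case it is added to both libraries; it never
  touches the test statistic.
* BH is applied per comparison (each tissue's DR-vs-AL and DR-AL-vs-AL
  families are corrected separately), matching a per-tissue analysis
  normalised to that tissue's AL group.
* DESeq-style size-factor normalisation is deliberately **not** used:
  the Z-test is defined on total-mapped-read rates, and mixing the two
  normalisations would change the variance argument. The two coincide
  when totals are proportional to size factors.

# Persistence and cross-tissue intersection

A gene is **persistent** when it is significantly altered in DR vs AL
*and* significantly altered in the same direction in DR-AL vs AL (both
comparisons against the same AL reference on the same gene universe).
Direction mismatches are never persistent, and genes significant only in
DR-AL are reported separately as "new" changes rather than persistent
ones. A `lenient = TRUE` option relaxes the second requirement to a
same-sign fold change regardless of significance, for sensitivity
analyses; the strict rule is the default and is what the persistence
percentages refer to.

```{r persistence}
degSw <- callDEGs(sim$counts, c("AL", "DR-AL"))
classifyPersistence(deg, degSw)
```

`intersectTissues()` applies plain set semantics to per-tissue
persistent gene lists (overall and pairwise intersections); it does no
enrichment testing.

# Comparative-Ct qPCR

Technical replicates are averaged arithmetically per sample and gene
(standard comparative-Ct practice). Then per sample
$\Delta C_t = \bar{C_t}^{target} - \bar{C_t}^{control}$,
$\Delta\Delta C_t = \Delta C_t - \overline{\Delta C_t}^{calibrator}$,
and $rq = 2^{-\Delta\Delta C_t}$. The calibrator is the AL group mean
(all figures are normalised to AL), so the calibrator group's $rq$ has
geometric mean 1 by construction. Group comparisons use one-way ANOVA
with Tukey HSD on $rq$ by default; `response = "dct"` tests the
$\Delta C_t$ values instead — the study does not state which response
its ANOVA used, the orderings agree, and both are exposed.

# BSAS methylation quantitation

**Placement.** Amplicons are short, primer-defined and read in a fixed
orientation, so reads are compared ungapped against the reference in
*bisulfite space*: at positions that are cytosines in the reference, a
read C (methylated) or T (converted) both match; everywhere else the
read must match literally. A read takes the offset with the fewest
mismatches (ties to the smallest offset) and is rejected above a 10%
mismatch fraction (`maxMm`). Full local alignment would add nothing for
this read structure.

**Calling.** At each annotated cytosine, C calls are methylated, T calls
unmethylated, anything else is counted `other` and excluded from the
percentage. Sites with fewer than `minCoverage` informative calls in any
sample are flagged and excluded from totals and tests; the default floor
of 1000 matches the design depth of the assay.

**Totals.** Total CG (or CH) methylation per sample is the *unweighted
mean of per-site percentages* over covered sites of that context. The
aggregation is not dictated by the assay definition; the unweighted mean
is chosen because it is invariant to coverage imbalance between sites.
The read-weighted pooled fraction is available via
`weighting = "read-weighted"` and equals the site mean exactly when
coverage is uniform.

**Tests.** Totals: one-way ANOVA with Tukey HSD, plus the percent
decrease of each non-AL group versus the AL mean,
$100\,(\bar m_{AL} - \bar m_g)/\bar m_{AL}$ — the effect scale on which
promoter hypomethylation is conventionally reported. Individual sites:
one-way ANOVA per site with BH correction applied *within* the CG and CH
families separately, since the two contexts are reported and tested
separately.

```{r bsas}
amp <- makeAmplicon(397, cgPositions = c(60, 180, 300), seed = 7,
                    name = "promoter")
amp
```

# The synthetic-data generators

The generators define the study conditions the tests run under; their
defaults are fixed once and documented here.

* **Expression** (`ExpressionScenario`): 3 groups, one pooled library
  each at $8\times10^7$ mapped reads (the sequencing runs averaged
  roughly 80 million reads per library), baseline 100 expected reads
  per gene, 5% of genes up- and 5% down-regulated at fold 2 under DR,
  and 30% of affected genes persistent — a central value for the
  per-tissue persistence range seen in this kind of data (roughly 20–50%).
  Counts are Poisson, matching the distributional assumption the Z-test
  itself makes; overdispersion across biological replicates is
  deliberately out of scope because the design pools them.
* **Methylation** (`MethylationScenario`): per-group, per-site true
  fractions over an `AmpliconSpec`; depth 2000 per sample (above the
  1000x design floor), 5 samples per group, perfect conversion and no
  base errors unless asked otherwise. Conversion inefficiency is
  modelled as unconverted unmethylated C (reading as C, i.e. apparent
  methylation $\approx 100\,(1-e)\%$ at a truly unmethylated site) —
  the standard failure mode. Whether a high apparent CH level in real
  data reflects true CH methylation or incomplete conversion cannot be
  decided by the simulator; it exposes both knobs instead.
* **qPCR** (`QpcrScenario`): 5 samples per group, 3 technical
  replicates, Gaussian Ct noise (default sd 0.1 cycles), one cycle per
  twofold expression change.

Reads are simulated full-length on the amplicon top strand only (BSAS
amplifies one bisulfite strand per primer pair); there are no
paired-end reads, indels or PCR-duplicate structure, and CHH/CHG are
not distinguished. Passing tests on these simulations therefore
demonstrate the *estimators and tests*, not robustness to alignment
artefacts or strand asymmetries in real libraries.

All generators take an explicit integer seed and restore the caller's
RNG state; identical scenario + seed gives byte-identical output files,
and every pipeline report JSON contains the full scenario so
`rerunFromReport()` reproduces a run exactly.

# Degenerate inputs and conventions

* ANOVA with zero between-group variance returns $F = 0, p = 1$; zero
  within-group variance with distinct means returns $F = \infty, p = 0$
  (both checked with exact arithmetic rather than through the linear
  model's QR residuals).
* Tukey HSD with zero pooled variance assigns $p = 1$ to identical
  pairs and $p = 0$ to differing pairs.
* `totalMethylation()` errors rather than guessing when a context has
  no covered site; `callSites()` on an empty read set warns and returns
  an empty matrix.
* `makeAmplicon()` guarantees no accidental CG: any CG arising in the
  random background has its G mutated to A/T, which cannot create a new
  CG elsewhere.

# Problem sizes

The shipped tests and the acceptance script use: $10^5$ null genes for
Z-test calibration; 2000-gene scenarios at $10^7$ mapped reads for
persistence recovery; depth 10000 for single-sample site exactness;
depth 2000 with 5 samples per group for the 3-CG promoter scenarios;
1000 Gaussian replicates for the Tukey power check. These sizes make
the Monte-Carlo error small relative to every asserted tolerance while
keeping a full run in the order of a minute.

# Limitations

Unreplicated pooled DE is hypothesis discovery: the Z-test calibration
shown here is calibration against Poisson *technical* noise, and says
nothing about biological variance between animals, which pooling hides.
Persistence percentages estimated from pooled data inherit this. The
BSAS module quantifies what the reads show; it does not model
copy-number variation, SNPs at cytosines (which appear as `other`
calls), or hemimethylation.
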