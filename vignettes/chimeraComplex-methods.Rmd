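---
title: "Detecting destabilized protein complexes from SEC-SILAC co-fractionation data"
author: "chimeraComplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting destabilized protein complexes from SEC-SILAC co-fractionation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(chimeraComplex))
```

## The problem

When two diverged yeast genomes meet in one cell — as in hybrids, or in
chromosome-replacement lines where one or two *S. cerevisiae* chromosomes
are swapped for their *S. bayanus* var. *uvarum* homologs — multiprotein
complexes can become chimeric: some subunits come from each parent.
Subunit interfaces coevolve within a lineage, so chimeric complexes may
assemble poorly, dissociate, and load the cell with orphan subunits that
must be degraded or that aggregate. This package implements the
quantitative side of that question: given native size-exclusion
chromatography (SEC) co-fractionation proteomics of a replacement line
mixed 1:1 (via SILAC labeling) with its parent, which complexes are
destabilized, are their subunits less abundant, does the transcriptome
show a shared stress signature, and do organismal phenotypes track the
number of chimeric complexes a line carries?

## Elution patterns and the EPD statistic

A lysate is fractionated on an SEC column; 81 raw fractions are pooled in
threes into 27 analyzed fractions (`poolFractions()`). Per-fraction
peptide concentrations multiply the MS intensities
(`concentrationCorrect()`). For each protein and each SILAC channel the
intensities are divided by the channel total and expressed as
percentages — the *elution pattern* — so the two channels are comparable
regardless of absolute protein levels (`elutionPatterns()`; every pattern
sums to 100 within 1e-6).

The *elution pattern difference* for a protein is the L1 distance between
its heavy- and light-channel patterns over the 27 fractions:

EPD = sum over f of | heavy%(f) - light%(f) |

with d(f) = heavy%(f) - light%(f) kept as the signed per-fraction profile
(`epdDifferences()`). EPD lives in [0, 200]: 0 means identical co-elution
behavior in both samples, 200 means completely disjoint elution. It is
symmetric in the channels, satisfies the triangle inequality (it is an L1
metric on pattern space), and is invariant to rescaling either channel's
raw intensities. Percentages, not proportions, are the canonical unit —
this doubles the numeric scale relative to a proportion-based L1
distance, so the 0-200 range is stated prominently wherever EPD appears.

Missing (protein, channel, fraction) intensities are treated as zero
before normalization, which is how MaxQuant-style outputs represent
undetected fractions. A protein quantified in only one channel cannot
form a pattern pair and is dropped with a logged count; a
`minFractions` switch additionally drops proteins detected in fewer than
k fractions per channel (default 1).

## Complex-level inference

A complex is *testable* when at least `nMin` of its subunits are
quantified in both the experimental set (parent-heavy / replacement-light)
and the control set (parent-heavy / parent-light). For each testable
complex, subunit EPDs in the experimental set are compared with the same
subunits' EPDs in the control set by a paired, one-sided Wilcoxon
signed-rank test (experimental greater), and p values are
Benjamini-Hochberg adjusted across all testable complexes of one
comparison set; adjusted p < 0.05 calls the complex unstable
(`callUnstableComplexes()`).

The signed-rank implementation drops zero differences before ranking
(Wilcoxon's original treatment) and gives tied absolute differences
mid-ranks. For up to 15 nonzero pairs the p value is exact under the
sign-flip null: mid-ranks are multiples of one half, so doubling them
gives integer support and the distribution of the positive-rank sum over
all 2^n sign assignments is obtained by a short polynomial convolution
rather than explicit enumeration. Beyond 15 pairs a normal approximation
with tie correction and continuity correction takes over. The exact
branch matters here: the one-sided exact test has a hard p-value floor of
2^-n, so a five-subunit complex can at best reach p = 0.03125 and the
default `nMin = 5` is the smallest size at which a complex can be
significant at all before multiplicity adjustment. This floor interacts
with BH: with m testable complexes and r discoveries, a complex of n
subunits is callable only if 2^-n <= 0.05 r / m. Six-subunit complexes
are therefore borderline whenever the testable family grows beyond a few
dozen — a structural property of exact nonparametric complex-level
inference worth knowing before choosing `nMin` or interpreting
borderline calls.

A robustness re-analysis (`callUnstableExcludingReplaced()`) removes
subunits encoded on the replaced chromosomes from every complex before
testing, so that calls cannot be driven by the foreign proteins
themselves; destabilization that propagates to the native subunits
(trans-acting disassembly) survives this filter.

Group-level context mirrors the grouped box-plot analysis: quantified
proteins are partitioned into chr-complex proteins (member of at least
one complex with a replaced-chromosome subunit), non-chr-complex
proteins, and non-complex proteins (`assignProteinGroups()`; a protein in
both kinds of complexes is labeled chr-complex by default, since any such
membership exposes it to a chimeric complex — the rule is configurable).
Kruskal-Wallis with tie correction tests overall heterogeneity and Dunn's
pairwise z tests with Bonferroni correction localize it;
`groupLetters()` derives the shared-letter display (letters are maximal
cliques of the non-significant-pair graph). Enrichment of
replaced-chromosome subunits among unstable complexes is a one-sided
Fisher exact test on the 2x2 (unstable vs stable) x (contains replaced
subunit vs not) table.

## Abundance and protein-transcript coupling

The same machinery runs on per-protein log2 SILAC ratios
(`summarizeRatios()`: log2 of summed light over summed heavy corrected
intensity) with the one-sided alternative reversed — reduced abundance in
the replacement line means experimental ratios below control
(`complexAbundanceTest()`). A shared code path guarantees the two tests
agree p-for-p when fed the same numbers.

To ask whether abundance loss is transcription-driven,
`proteinTranscriptCorrelation()` computes the Spearman correlation
between protein ratios and transcript log2 fold-changes within each
protein group and compares groups with Fisher's r-to-z for independent
correlations: z = (atanh(rA) - atanh(rB)) / sqrt(1/(nA-3) + 1/(nB-3)).
The independent-groups form is the correct one here because the groups
are disjoint protein sets. Equal correlations short-circuit to z = 0
without the transform (which would be degenerate at |rho| = 1). The
transcript quantity used is the log2 fold-change against the parent, the
natural mirror of a SILAC ratio; absolute expression would be an equally
defensible but different choice.

## Transcriptome response rules

DE status uses a linear fold-change threshold: up means fold-change >
1.5 (log2FC > log2 1.5 ~ 0.585) with adjusted p < 0.05; down
symmetrically (`classifyDE()`). Genes on a line's replaced chromosomes
are masked for that line — their fold-changes conflate trans effects
with sequence divergence — and never contribute a call
(`deStatusMatrix()`). A gene is a *common-response* gene when it is DE in
the same direction in at least k = 4 lines with no opposite call in any
line; genes DE in at least k lines with both directions present are
excluded as bidirectional (`commonResponse()`). The bidirectional rule
adopted here is strict: mixed signs across >= k DE lines exclude the gene
even if one direction alone reaches k, and any opposite call below k
demotes the gene to not-common. Both thresholds are arguments, because
the boundary between "common response with one discordant line" and
"bidirectional" is a judgment call, not a fact.

The environmental stress response (ESR) check correlates the median log2
fold-change of ESR genes across all lines with each canonical stress
profile (Spearman; `esrCorrelation()`), requiring at least 10 shared
genes.

## Phenotypes

`maxGrowthRate()` estimates the maximum specific growth rate as the
largest slope of ln(OD) over sliding windows of consecutive readings,
with an OD floor of 0.02 excluding pre-growth noise, and reports doubling
time ln(2)/mu. The window default is 9 points (90 minutes at 10-minute
sampling). This width was chosen from the estimator's error budget: the
maximum over ~50 overlapping windows is upward-biased by roughly twice
the per-window slope standard error, and at 1 percent multiplicative read
noise a 9-point window keeps the mean doubling-time error near 3.5
percent, whereas a 5-point window inflates it to ~9 percent on a clean
exponential. Fitness defect is the doubling-time difference
treated-minus-untreated; sporulation sensitivity is 1 minus the ratio of
sporulation frequencies with and without Hsp90-inhibitor pre-treatment;
aggregate load is the percentage of cells with Hsp104 foci, flagged when
fewer than 500 cells were scored. `phenotypeComplexCorrelation()` ties
any of these to the per-line count of complexes containing
replaced-chromosome subunits (Spearman with p value, >= 5 lines).
One-sided two-sample comparisons default to Welch's unequal-variance t
(replicate variances differ between lines), with a pooled-variance
switch.

## The synthetic-data generator

Every stage is testable without external data because
`simulateStudy()` generates all inputs with planted ground truth:

* **Genome and compendium.** Genes are uniform over 16 chromosomes;
  complex sizes are sizeMin + Geometric(p) truncated at sizeMax, and
  members are drawn without replacement so complexes are disjoint —
  planted effects then have unambiguous truth labels. Defaults: 2000
  genes, 60 complexes, sizes in [2, 30] with p = 0.35.
* **Co-fractionation.** SEC elutes large assemblies first, so each
  complex gets a peak fraction from a fixed monotone size map (size 30
  at fraction 3 down to monomers at fraction 24 — the map is arbitrary
  but frozen and documented). A subunit's noiseless profile is
  alpha x Gaussian(complex peak, sigma) + (1 - alpha) x Gaussian(monomer
  peak, sigma) discretized over the 27 fractions; the reference channel
  uses alpha = 0.9, the light channel of a planted complex uses
  alpha (1 - delta) and its total is scaled by gamma. Non-complex
  proteins are monomer-only. Per-cell multiplicative log-normal noise
  with CV 0.2, optional intensity-threshold dropout (off by default —
  thresholded rather than probabilistic, matching intensity-dependent
  missingness), per-fraction concentrations the tables are pre-divided
  by, and a control set made of two independent reference draws.
  Closed-form anchor: with delta = 1, vanishing sigma, no noise and
  distinct peaks, affected subunits have EPD exactly 2 x alpha x 100.
* **Transcriptome.** Background log2FC ~ Normal(0, 0.2); planted
  common-response genes get +/-1.2 in at least 4 random lines; ESR genes
  share a latent per-line stress factor whose loadings also generate the
  stress profiles, planting a positive ESR correlation; adjusted p
  values come from the matching z-to-p with per-line BH, so significance
  is consistent with effect size by construction. Genes on a line's
  replaced chromosome are masked.
* **Phenotypes.** Eleven lines, each replacing one chromosome; fitness
  defect = 3 min/complex x chimeric-complex count + Normal(0, 10 min),
  chosen once as a realistic signal-to-noise for an 11-line panel;
  growth curves are exponentials with the same coupling and 1 percent
  read noise.

All randomness flows from one master seed through named per-stage
substreams, so stages are independently reproducible and a rerun with
the same configuration is byte-identical.

What the generator does **not** emulate: correlated noise across
fractions (retention-time drift), inter-subunit correlation within a
complex (the tests treat subunits as exchangeable, as the analysis
does), shared subunits between complexes, peptide-level missingness, or
chromosome-scale linkage in expression. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to every artifact of real CF-MS data.

## Study conditions used by the tests and the acceptance script

The package's own verification runs at desk scale, with sizes chosen to
make replicate loops cheap while keeping every statistical property
measurable: null FDR is estimated from 200 replicate null studies
(delta = 0, gamma = 1, CV = 0.2, 60 complexes, nMin = 5); recovery from
20 replicate planted studies (10 planted complexes of >= 6 subunits,
delta = 0.7 or gamma = 0.5, two replaced chromosomes, size distribution
p = 0.2 so that enough large chr-complexes exist to plant); phenotype
sign recovery from 100 replicate 11-line panels. Under these conditions
the measured values are approximately: empirical FDR 0-2 percent,
destabilization recovery ~95 percent, degradation recovery ~94 percent,
phenotype sign recovery >= 95 percent — all recomputed at run time by
`scripts/acceptance.R`, never asserted as constants.

## Numerical choices and degenerate inputs

* Exact signed-rank switches to the normal approximation above 15
  nonzero pairs; all-zero difference vectors return p = 1 with a
  degenerate flag.
* Kruskal-Wallis on identical observations errors (the tie-correction
  denominator vanishes) rather than returning NaN; the pipeline reports
  the group comparison as absent in that case.
* Degenerate Fisher margins (all complexes unstable, or none) return
  p = 1 rather than erroring.
* Spearman on a constant vector errors; correlation comparisons skip
  groups below 4 pairs with a warning.
* Flat growth curves (mu below 1e-10 per minute) report infinite
  doubling time with a flag; t tests between two zero-variance,
  equal-mean groups return p = 0.5 with a flag.
* Chromosome labels accept Arabic or Roman numerals (converted at load);
  complexes with fewer than two members are kept but flagged, and are
  excluded from chromosome counting.

## Limitations

Counts of unstable complexes depend on `nMin`, on the BH family (each
comparison set is adjusted separately), and on the exact-p floor
described above; comparisons across datasets should hold these fixed.
The compendium is consumed as curated input — no attempt is made to
rebuild it from interaction databases. Upstream quantification
(peptide-to-protein rollup, SILAC ratio extraction, read mapping,
dispersion estimation) is out of scope: the package starts from tidy
intensity and fold-change tables.
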