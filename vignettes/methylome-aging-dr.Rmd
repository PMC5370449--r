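---
title: "Binned differential methylation, DR-ameliorated aging changes and the TG lipidome"
author: "methylDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned differential methylation, DR-ameliorated aging changes and the TG lipidome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDR)
```

# The scientific problem

Dietary restriction (DR) extends lifespan and delays many aspects of aging.
One candidate mechanism is DNA methylation: CpG methylation drifts with age,
and nutrition is known to modulate the methylation machinery. methylDR
implements an analysis of whole-genome bisulfite (BS-seq) methylomes from a
2 x 2 design — diet (ad libitum, AL, vs DR) crossed with age (young vs old),
with three animals per group — aimed at three questions:

1. Which regions change methylation with age, and which with diet?
2. Are age-related changes *attenuated* ("ameliorated") under DR?
3. Do diet-induced gene-body methylation changes couple to transcription,
   and do the affected pathways (lipid metabolism) leave a measurable trace
   in the hepatic triglyceride (TG) lipidome?

Every stage is driven by a seeded synthetic-data generator with known
ground truth, so the whole pipeline is verifiable at desk scale.

# Fixed-CpG-count binning

CpG density is extremely uneven (CpG islands vs background). Windows of
fixed genomic width would carry wildly different amounts of data and hence
wildly different statistical power, biasing differential calls toward
CpG-dense regions. The package therefore bins the genome by *CpG count*:
each bin covers exactly 50 consecutive retained CpGs and consecutive bins
share 25, so every bin carries about the same information. The genomic span
of a bin is an *outcome* (narrow in islands, wide in background), not a
parameter.

Two filters precede binning, in this order:

* **High-observation filter.** Total read observations are tallied in
  non-overlapping 25 kb windows; windows above `Q3 + 10 * IQR` are removed
  (PCR / mapping pile-ups). Quartiles use linear interpolation
  (`quantile` type 7); the quartile type and stringency are arguments,
  since box-whisker conventions differ between tools.
* **Coverage filter.** After pooling replicates per group, only CpGs with
  at least 3 observations in *every* group are retained, so all four
  conditions contribute to every bin.

Each bin is quantified two ways: the *reporting* level is the unweighted
mean of per-CpG methylation percentages, and the *testing* quantities are
the pooled methylated/unmethylated counts. The two agree at equal per-CpG
depth and diverge under depth imbalance; keeping both reconciles a
per-CpG-average quantitation with a count-based test, which needs counts.

# DMR calling

For a named pairwise contrast (aging under AL, aging under DR, diet at
young age, diet at old age) every bin is tested by a Pearson chi-squared
test (1 df, no continuity correction — pooled counts are in the thousands)
on the 2 x 2 table of pooled counts, followed by Benjamini–Hochberg
correction across all tested bins. A bin is a DMR when the adjusted p is
below 0.05 **and** the reported methylation difference is at least 10
percentage points; the difference is always the second group minus the
first (old minus young, DR minus AL). Both cutoffs are arguments.

```{r dmr-example}
cfg <- simConfig(nChroms = 1, nCpgsPerChrom = 12000, nAgeDMR = 10,
                 nDietDMR = 5, nGenes = 8, nWholeGene = 4, seed = 7)
sim <- simulateMethylome(cfg)
merged <- filterMinCoverage(mergeReplicates(sim$counts))
bins <- makeBins(merged)
bins
age <- callDMRs(bins, "age_AL")
summarizeMagnitude(age)$summary
```

# Amelioration of age-related changes by DR

This is the package's central procedure. For every bin compute

* `d_age_AL = AL_old - AL_young` (aging change under AL),
* `d_age_DR = DR_old - DR_young` (aging change under DR),
* `d_diet_old = DR_old - AL_old` (diet difference after aging).

If DR and AL methylomes aged identically, `d_diet_old` would be unrelated
to either aging axis beyond noise. Two ordinary-least-squares fits of
`d_diet_old` — one on `d_age_AL`, one on `d_age_DR` — plus their Pearson
correlations summarize the relationship. When DR attenuates age effects,
bins with large AL-aging changes show a compensating old-age diet
difference, while their DR-aging change collapses toward zero: the DR-side
fit decorrelates and flattens relative to the AL side.

The classification cutoff is `2 * sigma`, where `sigma` is the sample
standard deviation of the AL-fit residuals over **all** bins — an estimate
of the naturally random scatter (a DMR-only scope is available via
`sigmaScope`). Age-related DMRs whose residual from the **DR** fit exceeds
the cutoff are called DR-ameliorated, split hyper/hypo by their age
direction. This estimate assumes genuinely ameliorated bins are rare; the
generator's defaults keep planted bins at a few percent of all bins to
mirror that regime (in the real data that motivated the design, DMRs are
~0.3% of >1M bins).

### Permutation nulls and a geometric caveat

Three per-bin label-shuffling schemes provide robustness nulls:
`all_labels` (random permutation of the four labels), young/old swaps
within each diet, and AL/DR swaps within each age. One algebraic fact
matters when reading them: `d_diet_old` shares `AL_old` (negatively) with
`d_age_AL` and `DR_old` (positively) with `d_age_DR`. Under label noise
this forces null slopes of about −1/2 on the AL side and +1/2 on the DR
side — *not* 0. The informative comparison is therefore on the DR side and
on the AL−DR contrast, where strongly ameliorated data (DR slope near 0)
sit far outside every null envelope. The tests assert exactly this; they
do not assert a zero-centred null, which the shared-term geometry forbids.

```{r amelioration}
am <- ameliorationAnalysis(bins, age, nPerm = 50, seed = 1)
am
```

# Genomic and chromatin elements

Annotation tracks are combined into rule-based element classes: promoters
(TSS − 5 kb to TSS + 100 bp, strand-aware), CpG islands classified
promoter > gene > intergenic by overlap precedence, active enhancers
(H3K4me1 ∩ H3K27ac; geneic vs distal), active promoter chromatin (H3K4me3
within 100 bp of H3K9ac, clear of H3K27me3, on a promoter), repressive
promoter chromatin (H3K27me3 narrower than 3.5 kb, clear of active marks,
on a promoter), repressive geneic chromatin (same without the width cap,
on a gene body, promoter precedence), and bivalent CGIs (CGI under a
H3K4me3–H3K27me3 coChIP peak). Proximity rules are edge-to-edge; "overlap"
is ≥ 1 bp. Enrichment of a DMR set over an element compares overlap
frequency against the full bin background by one-sided Fisher test
(direction flippable to detect depletion, e.g. of transposons), with BH
correction across the elements of a run and observed/expected ratios for
cross-element comparison.

# Gene-level analyses

**Whole-gene-body methylation.** Genes with at least 4 overlapping bins
are tested for enrichment of DMR bins (one-sided Fisher against the
genome-wide bin set, BH across tested genes); surviving genes are
re-quantified over *all* gene-body CpGs and kept only if the gene-wide
difference reaches 2.5 points. Because a shift distributed evenly over a
whole gene at a few percentage points never produces 10-point bins, this
stage is fed a DMR set called at `minDiff = 2.5` (its own gene-wide
cutoff); the headline 10-point DMR sets are unchanged.

**Methylation–expression coupling.** Genes overlapped by ≥ 2 gene-body
DMRs get the average DMR delta; genes below a 10-point average are dropped
as unclear (balanced hyper- and hypomethylation). Each retained gene falls
into a quadrant of (methylation difference, log2 fold change); the
quadrant table is tested one-sided by Fisher's exact test for the inverse
relationship (hyper–down / hypo–up) and Pearson's r is reported, then both
are repeated restricted to significant DEGs. Note that the exact Fisher p
is discrete and conservative under the null — its null distribution is
sub-uniform by construction, which is why the calibration tests check
validity (no excess of small p-values) rather than literal uniformity.

# Triglyceride lipidomics

TG species are keyed by total acyl carbons (even, 38–60; a chain-length
proxy) and total double bonds (0–12; a saturation proxy). Species are
normalized per sample to percent of the total TG lipidome, then aggregated
by carbons or double bonds. Statistics follow the design: per-category
one-way ANOVA with Tukey HSD across the four groups; interval tests
comparing condition means per category over the left (38–52) and right
(54–60) chain-length tails (or 0–3 vs 4–12 double bonds) with a Wilcoxon
signed-rank test on the paired per-category means (with k all-positive
differences its exact one-sided p is 2^−k, e.g. 1/256 for the 8-category
left tail); and two-way ANOVA for the age × diet interaction on total TG.

# The synthetic-data generator

`simulateMethylome()` emulates the statistical structure the analysis
assumes, not sequence-level reality:

* CpG sites: uniform background (~240 bp spacing at the defaults) plus
  dense island clusters (~10 bp spacing, ≥ 200 bp), some at TSSs
  (promoter CGIs, baseline 10% methylation), some in gene bodies,
  some intergenic; all other CpGs at an 85% baseline — the bimodal
  landscape of a liver methylome.
* Counts: per CpG, sample coverage is Poisson (mean 30, a realistic WGBS
  depth; the source study does not state its per-CpG depth) and methylated
  counts are beta-binomial with mean = group mean and overdispersion
  `rho = 0.05` (`alpha = m(1-rho)/rho`), giving the modest
  between-replicate excess variance seen in real libraries.
* Plants: age-effect and diet-effect regions are 75 consecutive CpGs
  aligned to the 25-CpG bin grid, so each plant fully covers exactly two
  bins — detectability is then a property of the caller, not of partial
  overlap. (A 60-CpG unaligned run, the obvious alternative, covers a full
  bin only when a grid start happens to fall in its first 11 CpGs.)
  Effects are drawn from U(10%, 35%); hyper plants sit on low baselines
  and hypo plants on high ones so both directions stay in range. A
  configurable fraction of age regions has its DR-arm age effect scaled by
  `attenuationFactor` (ameliorated plants). Whole-gene plants span 150
  CpGs (≥ 4 bins) and shift the entire gene body in the DR groups.
* Expression: planted genes get `log2FC = -5 * effect + noise` (inverse
  coupling); other genes are pure noise.
* TG tables: discretized bivariate-normal profiles over (carbons, double
  bonds) centred at 54 carbons / 3 double bonds for AL, with the DR carbon
  centre displaced left by 2 carbons per `shift` category; log-normal
  species noise (CV 15%) and total-TG noise (CV 10%); an optional old-AL
  total boost plants the age × diet interaction. Default group sizes are
  4 young and 3 old animals per diet.

What the generator does **not** emulate: read-level errors, bisulfite
conversion failure, non-CpG methylation (negligible in liver), correlated
coverage along the genome, strand asymmetries, or biological
between-animal heterogeneity beyond beta-binomial overdispersion. Passing
recovery tests therefore demonstrate correctness of the statistical
machinery under its stated assumptions, not robustness to every artifact
of real libraries.

# Numerical choices and degenerate inputs

* Chi-squared tables with a zero marginal return `chi2 = 0, p = 1`.
* `fitScatter()` refuses zero-variance predictors; inside permutations a
  degenerate shuffle (all levels equal) returns slope = r = 0 instead.
* Bins with no covered CpG in a group give `NaN` levels and are dropped
  (with a message) from the delta computation.
* Sample standard deviation (n − 1) is used for `sigma`.
* Identical-valued lipid categories short-circuit to F = 0, p = 1 (the
  ANOVA is 0/0 there).
* Coordinates are GRanges (1-based closed) internally; BED files are read
  and written through rtracklayer, which owns the 0-based half-open
  conversion; bismark coverage files are 1-based with counts as primary
  data (a disagreeing percent column is reported and overridden).
* Problem sizes in the shipped tests: ~2,000–5,000 bins, 20-seed null
  calibrations, 100–200-seed detection/calibration loops — sizes chosen so
  the whole suite exercises every claim at desk scale.

# Known limitations

* The chi-squared test on pooled counts ignores between-replicate
  variance; the 10-point difference cutoff is what keeps overdispersion
  from inflating the DMR list (a per-replicate sign-consistency diagnostic
  is the natural extension).
* `sigma` estimated over all bins is inflated when true effects are
  common; `sigmaScope = "dmr"` and sparse plants are the mitigations.
* The permutation nulls inherit the shared-term slopes of about ∓1/2
  described above; they are robustness checks, not parameter-free nulls.
* Whole-gene detection includes the tested gene's own bins in the
  background row by default (`excludeSelf` flips this); with genome-scale
  backgrounds the difference is negligible.
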