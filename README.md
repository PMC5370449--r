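# methylDR

Binned differential methylation analysis of aging and dietary restriction
(DR), with matched transcriptome coupling and triglyceride (TG) lipidomics.

Whole-genome bisulfite sequencing of liver from young and old mice fed ad
libitum (AL) or dietarily restricted, three animals per group, raises a
specific analytical problem: CpG density is so uneven that fixed-width
windows carry wildly unequal data and power. methylDR implements the
fixed-CpG-count answer and everything built on top of it, for
epigenomicists who want the complete, testable pipeline rather than
one-off scripts:

* **Binning** — sliding windows of exactly 50 retained CpGs, stepped by
  25, after a box-whisker high-observation filter (25 kb windows,
  `> Q3 + 10*IQR` removed) and a ≥ 3-observations-per-condition coverage
  filter. Bin levels are the mean of per-CpG percentages; tests use
  pooled counts.
* **DMR calling** — per-bin Pearson chi-squared on pooled counts
  (no continuity correction), Benjamini–Hochberg across bins, DMR iff
  adjusted p < 0.05 and |Δmethylation| ≥ 10 points, for the four contrasts
  of the 2 × 2 design.
* **Amelioration** — the central procedure. With per-bin deltas
  `d_age_AL = AL_old − AL_young`, `d_age_DR = DR_old − DR_young` and
  `d_diet_old = DR_old − AL_old`, regress `d_diet_old` on each aging axis
  (OLS + Pearson r). σ = sd of the AL-fit residuals estimates natural
  scatter; age-related DMRs farther than 2σ from the **DR** fit are
  DR-ameliorated. Three per-bin label-permutation schemes provide null
  envelopes.
* **Elements** — rule-based promoter/CGI/enhancer/repressive-chromatin/
  bivalent-CGI catalogs from annotation tracks, with one-sided Fisher
  enrichment (observed/expected vs the full bin background).
* **Gene links** — whole-gene-body differential methylation (≥ 4 bins,
  per-gene Fisher enrichment of DMR bins, BH, gene-wide |Δ| ≥ 2.5 points)
  and methylation–expression coupling (≥ 2 DMRs per gene, |mean Δ| ≥ 10,
  quadrant Fisher test for the hyper–down/hypo–up relationship, Pearson r).
* **Lipidomics** — TG species (total acyl carbons 38–60 × double bonds
  0–12) normalized to percent of the TG lipidome; per-category one-way
  ANOVA + Tukey HSD; signed-rank interval tests on chain-length tails
  (38–52 vs 54–60) and saturation intervals (0–3 vs 4–12); two-way ANOVA
  for the age × diet interaction on total TG.
* **Synthetic data** — a seeded generator (`simulateMethylome()`,
  `simulateAnnotations()`, `simulateExpression()`, `simulateTGTable()`)
  producing beta-binomial methylomes with planted age/diet/ameliorated/
  whole-gene effects and TG tables with planted chain-length shifts, all
  with exported ground truth.

## Worked example

```r
library(methylDR)

cfg <- simConfig(nChroms = 1, nCpgsPerChrom = 12000, nAgeDMR = 10,
                 nDietDMR = 5, nGenes = 8, nWholeGene = 4, seed = 7)
sim    <- simulateMethylome(cfg)
merged <- filterMinCoverage(mergeReplicates(sim$counts))
bins   <- makeBins(merged)
bins
#> BinSet: 479 bins x 4 groups; median span 24386 bp

age <- callDMRs(bins, "age_AL")
summarizeMagnitude(age)$summary
#>   direction  n median_reference median_delta
#> 1     hyper 12         48.86238     15.69201
#> 2      hypo 19         84.83104    -19.04195

am <- ameliorationAnalysis(bins, age, nPerm = 50, seed = 1)
am
#> AmeliorationResult: 479 bins; sigma = 6.102 (cutoff 12.204)
#>   fit AL: slope -0.485, r -0.412 | fit DR: slope -0.006, r -0.004
#>   ameliorated DMRs: 11 of 31 age-related (3 hypo, 8 hyper)
```

Reading the output: 31 of the 479 bins are age-related DMRs; planted
hypermethylation sits at low starting methylation (median 48.9%) and
hypomethylation at high (84.8%), with median shifts of +15.7 and −19.0
points. The old-age diet difference tracks the AL aging change with slope
−0.49 but is unrelated to the DR aging change (slope −0.01) — the
signature of age effects attenuated under DR — and 11 age-related DMRs
scatter beyond the 2σ = 12.2-point cutoff from the DR fit, so they are
classified as DR-ameliorated.

`runPipeline(cfg, outdir)` executes every stage end-to-end, writing
bismark-style coverage files, BED annotation tracks, DMR/amelioration/
enrichment/gene/lipid tables and JSON summaries; identical configs produce
byte-identical output.

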