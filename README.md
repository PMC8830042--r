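# methRisk

Differential DNA methylation and transcriptome integration for
enrichment-based (MethylCap-seq) capture methylomes, built for tissue-cohort
studies that compare a high-risk with an average-risk group — e.g. healthy
breast tissue donors stratified by a Tyrer-Cuzick lifetime risk score
(high risk at score ≥ 20%).

MethylCap-seq infers methylation from local fragment coverage rather than
base-level bisulfite calls, so absolute coverage is confounded by library
depth and regional capture efficiency. The package's core statistic removes
both: the genome is tiled with non-overlapping 250-bp bins, and each bin's
deduplicated insert coverage is expressed as a z-score relative to the 25-kb
region containing it,

    z(b, s) = ( c(b, s) − μ(r, s) ) / σ(r, s)

where `c(b, s)` is the mean per-base insert depth of bin `b` in sample `s`,
and `μ`, `σ` are the mean and sample standard deviation of coverage over the
region's bins. Group comparison then uses

* **ΔZ** = mean z(high) − mean z(average) — positive = hypermethylated in the
  high-risk group (a guarded **Z-ratio** of the group means is reported
  alongside),
* a per-bin Welch t-test on the per-sample z-scores, and
* Benjamini–Hochberg FDR across all testable bins,

calling a bin differentially methylated when |ΔZ| ≥ 1, q < 0.05 and
p ≤ 0.05. Called bins are annotated by positional overlap against gene
models (precedence promoter > UTR > coding > intron > intergenic).

Around this core the package provides:

* fragment handling: BEDPE → insert imputation → deduplication → per-bin
  coverage (`imputeInserts`, `deduplicateFragments`, `binCoverage`);
* a count-based differential-expression arm: median-of-ratios size factors
  and Welch t-tests on log2 normalized counts with tiered filtering
  (FDR < 0.05 → p ≤ 0.05 → fold change ≥ 2), plus comparative-CT qPCR
  quantification (`computeSizeFactors`, `deTTest`, `callDegs`,
  `ddctQuantify`);
* methylation–expression integration: Pearson correlation with
  direct/inverse classification, signature overlap with rounded-percent
  reporting, and candidate prioritization by alteration frequency and
  Oncoscore (`correlatePairs`, `signatureOverlap`, `prioritizeCandidates`);
* paired two-timepoint analysis: per-subject D2/D1 changes, paired tests,
  and a risk-group "enhancement" test (`pairedChange`, `enhancementTest`,
  `clockOverlap`);
* a synthetic study generator with known ground truth that emulates the
  full design — region-structured fragment coverage with planted hyper- and
  hypomethylated bins, negative-binomial counts with planted fold changes,
  planted methylation–expression correlations, and a paired subcohort
  (`simulationConfig`, `simulateGenome`, `simulateFragments`,
  `simulateCounts`, `linkMethExpr`, `simulatePaired`).

## Worked example

Simulate the desk-scale study (one 5-Mb chromosome = 20,000 bins, 10 + 10
samples, 100 planted bins at a z-effect of 2, 98.9% hypermethylated) and run
the full methylation arm:

```r
library(methRisk)
library(SummarizedExperiment)

cfg <- simulationConfig(seed = 1)
gen <- simulateGenome(cfg)
tl  <- buildTiling(gen$chromSizes)          # 250-bp bins in 25-kb regions
sim <- simulateFragments(cfg, tl)

fr  <- deduplicateFragments(sim$fragments)
se  <- regionZScores(binCoverage(fr, tl))
z   <- assay(se, "z")
grp <- setNames(sim$sampleSheet$group, sim$sampleSheet$sample_id)

tt   <- binTTest(z, grp)
dz   <- deltaZ(z, grp)
dmrs <- callDmrs(annotateBins(tl, gen$geneModels), dz,
                 tt$p_value, bhFdr(tt$p_value),
                 z_ratio = zRatio(z, grp), t_stat = tt$t_stat)

length(dmrs)                                   # 87 called bins
mean(sim$truth$bin_id %in% mcols(dmrs)$bin_id) # 0.86 sensitivity
hyperFraction(dmrs)$fraction                   # 0.9885 hypermethylated
```

Of the 100 planted bins, 86 are recovered at the default thresholds with a
single false call among the 19,900 null bins (0.005%), and 98.85% of calls
are hypermethylated — the planted direction split. `localizationSummary`
then tabulates the feature percentages per direction, and
`writeDmrTable` emits a BED-style TSV with a provenance header.

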