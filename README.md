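# tipomics

Time-course multi-omics analysis of cell-state transitions, built for
short differentiation series (e.g. chondrocytes sampled at days 0, 4, 8
and 12 with three replicates) profiled at the transcriptome and a targeted
metabolite panel. The package answers four questions about such a series:

1. **What changes?** Pairwise differential expression with an
   empirical-Bayes moderated t-test (gene-wise variances shrunk toward a
   method-of-moments inverse-chi-square prior), DEGs at |log2FC| ≥ 1 and
   p < 0.05; OPLS-DA/VIP screening of differentially regulated metabolites
   (fold change ≥ 2 or ≤ 0.5 and VIP > 1).
2. **How does it change over time?** Fuzzy c-means clustering of
   standardized temporal profiles into archetypes; per-sample gene-set
   enrichment scores from a rank-weighted Kolmogorov–Smirnov walk, tested
   across timepoints.
3. **Who drives it?** Per-state directional TF→target networks:
   TF-family enrichment (cumulative hypergeometric), PWM scanning of 1 kb
   promoters with exact DP-computed p-values, and an activation/inhibition
   sign from whether TF and target move together or oppositely.
4. **When does the system commit?** Dynamic-network-biomarker (DNB)
   analysis: per timepoint, candidate gene modules are scored by the
   criticality index

   CI = SDin · PCCin / max(PCCout, ε)

   (mean member standard deviation × mean |within-module correlation| /
   mean |module-to-outside correlation|); the timepoint where CI peaks is
   the tipping point and the peak module the DNB.

A joint-enrichment stage projects DEGs and DRMs onto shared pathways, and
a synthetic-data generator with planted ground truth (archetype clusters,
a correlated DNB module with a variance/correlation spike at the tip,
promoter motif insertions, metabolite fold-changes) backs the test suite
and an end-to-end pipeline driver.

## Worked example

```r
library(tipomics)

cfg  <- simConfig(seed = 42)          # 600 genes, 4 timepoints, 3 replicates
sim  <- simulateAll(cfg)              # expression + promoters + metabolites + truth
logm   <- logTransform(sim$tce)       # log2(x + 1)
design <- designTable(sim$tce)

cmp  <- allComparisons(logm, design)  # six pairwise moderated t-tests
degs <- unionDegs(cmp)
length(degs)
#> [1] 260

dnb <- criticalityCurve(logm[intersect(degs, rownames(logm)), ], design)
dnb
#> DnbResult
#>  timepoint size      SDin     PCCin    PCCout        CI
#>         D0   72 0.1953050 0.9636364 0.5340139 0.3524310
#>         D4   78 0.5935359 0.9354297 0.4897501 1.1336619
#>         D8   99 0.2091879 0.9123891 0.4888326 0.3904420
#>        D12   88 0.2479803 0.9142768 0.4980033 0.4552632
#>   tipping point: D4 (78 members)

scr <- pairwiseDrm(sim$metabolites, groupA = "D0", groupB = "D4")
sum(scr$drm_flag)
#> [1] 16
head(scr[scr$drm_flag, c("metabolite", "fold_change", "vip", "direction")], 3)
#>   metabolite fold_change      vip direction
#> 1       M001    4.214580 1.557940 increased
#> 2       M002    4.209306 1.580154 increased
#> 3       M003    3.925657 1.529124 increased
```

The CI column peaks at D4 — the planted tipping timepoint, where the
simulated module's correlation jumps from 0.25 to 0.9 and its standard
deviation triples — and all 16 planted metabolites (true log2FC = 2, so
fold change ≈ 4) are recovered. `runPipeline(config, outDir)` chains all
seven stages (differential expression → clustering → regulatory networks →
DNB → enrichment → metabolomics → integration) from one YAML/R config,
writing per-stage TSVs and a JSON manifest with input/output checksums;
reruns with the same seed are byte-identical.

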