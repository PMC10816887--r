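---
title: "Models and methods behind tipomics"
author: "tipomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tipomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipomics)
```

# Scope

`tipomics` implements the computational chain used to characterise a
differentiating cell population profiled over a short time course — here
motivated by chondrocytes sampled at days 0, 4, 8 and 12 of in vitro
differentiation with three replicates per day, plus a targeted
energy-metabolite panel on the same design. The chain is: pairwise
differential expression, fuzzy time-series clustering, TF-driven
directional regulatory networks per transcriptional state,
dynamic-network-biomarker (DNB) tipping-point detection, gene-set
over-representation and per-sample enrichment scoring, OPLS-DA/VIP
metabolite screening, and joint gene–metabolite pathway projection.
Everything upstream of the expression matrix (alignment, counting) and the
concentration table (peak integration, calibration) is out of scope: inputs
are already-normalised abundances.

# Data model

The central container is `TimecourseExperiment`, a thin
`SummarizedExperiment` whose `colData` binds each sample to a timepoint and
replicate. Timepoint order is taken from the design file's declaration
order, never from string sorting — `"D12"` must sort after `"D4"`. The
same container carries metabolite concentration tables. Promoters are a
`DNAStringSet` (alphabet ACGTN), motifs a `PwmLibrary` of per-position
probability matrices with a shared background, gene sets a flat
`GeneSetCollection` (GMT semantics), and the interaction network an
undirected, deduplicated edge list.

# Differential expression

Abundances are transformed as `log2(x + 1)`; the pseudocount bounds
fold-changes for zero-abundance genes and makes the transform exact at
zero. Each timepoint pair is tested with a two-group contrast whose
gene-wise residual variances are shrunk toward a common prior — the
empirical-Bayes moderated t approach. The prior (scale $s_0^2$, degrees of
freedom $d_0$) is fitted by method of moments on the log residual
variances: under the scaled inverse-chi-square model,
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ has variance
$\psi'(d/2) + \psi'(d_0/2)$, so $d_0$ comes from inverting the trigamma
function on the excess dispersion and $s_0^2$ from the mean of $e_g$. The
moderated statistic uses the posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ with $d + d_0$ degrees of freedom. This is
simpler than the reference maximum-likelihood fit used by the established
moderated-t implementation; the two agree closely in practice (a
cross-check against that implementation is part of the test suite), and
setting the prior degrees of freedom to zero recovers the classic pooled
two-sample t exactly, which anchors the correctness tests.

DEG calling uses raw p < 0.05 and |log2FC| ≥ 1 by default — the fold-change
boundary is inclusive, the p boundary exclusive — with BH-adjusted p always
reported and an optional adjusted-p gate. The union of the six pairwise DEG
sets feeds the downstream stages. Fold-changes are differences of group
means of log-transformed values (not the log of a ratio of means). The
qPCR helper implements
$2^{-((Ct_{t} - Ct_{ref}) - (Ct_{t,cal} - Ct_{ref,cal}))}$.

# Fuzzy time-series clustering

Per-gene profiles are timepoint means of log abundance, z-standardised with
the sample (n−1) standard deviation; constant profiles cannot be
standardised and are dropped with a warning. Clustering is standard fuzzy
c-means with Euclidean distance on the standardised profiles: memberships
$u_{ij} = 1/\sum_k (d_{ij}/d_{kj})^{2/(m-1)}$, centres as $u^m$-weighted
means, and an explicit degenerate rule giving a profile at zero distance
from a centre a crisp membership. Defaults: c = 4 clusters (the four
temporal archetypes), fuzzifier m = 1.25 — in the range that reference
implementations of the algorithm estimate for standardised expression
data — tolerance 1e-6
on the maximum membership change. Initialisation is seeded farthest-point
sampling of data rows, which is reproducible and cannot pick duplicate
centres on low-noise data. Hard labels are argmax memberships with ties to
the lowest cluster index and an assignment floor (default 0.3) below which
genes are reported unassigned. No automatic selection of c is attempted.

# Regulatory-state networks

DEGs from each contiguous comparison (D4 vs D0, D8 vs D4, D12 vs D8) form
transcriptional states 1–3. Within a state, TF-family over-representation
of the differentially expressed TFs against the full annotated TF universe
uses the upper-tail cumulative hypergeometric $P(X \ge k)$, with a
two-sided Fisher exact p on the same 2×2 table reported alongside and BH
adjustment across families.

Promoter scanning slides each motif over the supplied 1 kb upstream
sequences on both strands, scoring
$\sum_i \log_2(\mathrm{pwm}[b_i, i]/\mathrm{bg}[b_i])$ with probabilities
floored at 1e-4 before logs. P-values are exact: the null score
distribution under the background model is built by dynamic programming
over motif positions with scores discretised to 1e-3 log2 units — fine
enough that the discretisation error is at most a few thousandths of a
log-odds unit, coarse enough that the distribution stays small; the test
suite verifies agreement with exhaustive k-mer enumeration to within one
bin. An N base contributes the background probability, i.e. a log-odds
term of exactly 0. The hit threshold defaults to p ≤ 1e-4 and both strands
are scanned; offsets are 0-based window starts in forward coordinates.

An edge TF → target requires the TF differentially expressed in the state,
the target in the state's DEG set, and a motif hit for one of the TF's
motifs (the TF→motif map is a required input; motif databases are
external). The sign is **activation** when TF and target change in the
same direction in the state's comparison and **inhibition** otherwise —
only the signs are used, not magnitudes. Pair counts per state and TFs
active in multiple states are reported.

# DNB tipping-point analysis

At each timepoint the analysed genes (default: the union DEG set,
configurable to all genes) are clustered by average-linkage hierarchical
clustering on the distance $1 - |r|$ over replicate values, the tree is
cut at heights {0.2, 0.4, 0.6, 0.8}, and every cluster of 5–100 genes is a
candidate module. For a module, SDin is the mean within-timepoint sample
standard deviation of members; PCCin the mean absolute Pearson correlation
over member pairs; PCCout the mean absolute correlation between members
and all other analysed genes; and

$$\mathrm{CI} = \frac{\mathrm{SDin} \cdot \mathrm{PCCin}}{\max(\mathrm{PCCout}, \varepsilon)}$$

with ε = 0.05 flooring the denominator against division blow-up.
Correlations involving a zero-variance gene are defined as 0 and flagged.
The best module per timepoint maximises CI (ties: larger module, then
lexicographically smallest member list); the timepoint with the maximal
best CI is the tipping point and its best module the DNB member set. The
member-centred network is the induced subgraph on members plus their
first-neighbour DEGs in the supplied interaction network; members absent
from the network are retained as isolated nodes and their count reported,
since protein-interaction coverage routinely drops a few members.

Correlations across three replicates are extremely noisy — a limitation
inherent to the design; the recovery tests therefore use 10 replicates
while the default generator keeps the triplicate design.

# Enrichment

Over-representation of a query set against a collection is the same
upper-tail hypergeometric with BH adjustment across sets (set size bounds
3–500 after universe intersection). Per-sample scoring ranks each sample's
genes by decreasing expression and runs a weighted Kolmogorov–Smirnov walk
per set: inside steps weighted by rank$^\tau$ (τ = 0.25, top gene gets the
largest weight) normalised to sum one, outside steps $-1/(N-K)$; the score
is the signed maximum-magnitude deviation. This is a rank-based
single-sample statistic in the ssGSEA family rather than the kernel-CDF
variant used by the GSVA package; being rank-based it is invariant under
any strictly monotone transform of a sample's values, which the tests
assert. Score changes across timepoints reuse the moderated t machinery,
with significance at adjusted p ≤ 0.05 (boundary inclusive).

# Metabolite screening

OPLS-DA is fitted by NIPALS with orthogonal signal correction: variables
are mean-centred and unit-variance scaled (standard for targeted panels;
no log transform by default), the class vector ±1 coded. Each orthogonal
component removes the part of the X loading orthogonal to the predictive
direction; the final single predictive component is refitted on the
filtered matrix. The fit is deterministic. VIP for one predictive
component reduces to $\sqrt{p}\,|w_j|$ with unit-norm weights, so
$\sum_j \mathrm{VIP}_j^2 = p$ holds exactly and is asserted on every fit.
A k-fold Q² (scaling and all components refitted inside each fold)
supports permutation sanity checks.

Pairwise DRM calls use the raw-concentration fold-change of group means
with thresholds ≥ 2 or ≤ 0.5 (inclusive) and VIP > 1 (exclusive). The
lower threshold defaults to the reciprocal of the upper one — the
near-universal convention — but both are configurable (including
asymmetric choices such as 0.05), and the values used are echoed in
outputs. The multi-group screen
combines a one-way ANOVA across all timepoints (raw p < 0.05) with the VIP
from a first-vs-last timepoint OPLS-DA; the supplying contrast is
configurable since no single pairwise model is canonical for a
multi-group screen.
Set accounting reports UpSet-style exclusive intersections over the six
pairwise DRM sets, the consistently-regulated subset against the baseline
timepoint, and the fraction of increased calls.

# Integration

For each pathway, gene-side and metabolite-side over-representation run
separately (DEGs against gene members, DRMs against metabolite members,
universes supplied explicitly; the metabolite universe defaults to the
detected panel, not all known compounds). A pathway is **joint** when both
sides are BH-significant at α = 0.05. The joint flag and the optional
Fisher combination $\chi^2 = -2(\ln p_g + \ln p_m)$ on 4 df are this
package's formalisation of the qualitative notion of shared enrichment,
and are labelled as such in outputs. A long-format projection table emits every
member gene's log2FC and every member metabolite's fold-change per
comparison for pathway-map figures, with NA markers for members absent
from the data, plus a descriptive sign-concordance fraction.

# The synthetic-data generator

The generator is first-class, tested code that emulates the statistical
structure the analysis assumes, with planted ground truth:

* **Expression**: multivariate normal on the log2 scale, exponentiated
  (log-normal abundances — non-negative, fold-changes additive in log
  space). Four archetype clusters of 60 genes each (V-shape, increasing,
  decreasing, transient peak; log2 amplitudes ±1.5, noise sd 0.2) among
  600 genes total, so roughly 40% of the universe is differential — a
  scaled-down but non-saturated universe, qualitatively comparable to the
  share of differential genes in a strongly remodelling time course. A 20-gene DNB module carries pairwise correlation 0.25 that jumps
  to 0.9 at the planted tip (day 4) where its sd triples, and an upward
  mean profile so members are themselves DEGs, as observed in real data.
* **Correlation structure**: a one-factor construction per timepoint —
  members load $\sqrt{\rho_\mathrm{in}}$ on a shared factor, outsiders
  $\rho_\mathrm{out}/\sqrt{\rho_\mathrm{in}}$ — reproduces the
  within-module and member-to-outside correlations exactly. A literal
  compound-symmetric cross-block of 0.1 between 20 members and hundreds of
  outsiders is not positive semi-definite, so the factor model is the
  simplest valid structure; its side effect is a small
  ($\rho_\mathrm{out}^2/\rho_\mathrm{in}$) correlation among outsiders.
  Configurations with $\rho_\mathrm{out}^2 > \rho_\mathrm{in}$ are
  rejected with a PSD error.
* **Promoters**: i.i.d. background sequence, one exact-consensus motif
  instance per planted TF→target pair at a recorded offset; sharp PWMs
  (0.97 on the consensus base). Width 8 at a 1e-4 scan threshold makes
  planted instances unambiguous.
* **Metabolome**: log-normal concentrations, CV 0.1, five replicates per
  timepoint over ~50 metabolites; 16 planted metabolites shift all
  post-baseline timepoints by +2 log2 units — a panel in which most
  regulated metabolites rise after baseline and stay up.
* **Network and pathways**: Erdős–Rényi background edges plus guaranteed
  member-to-DEG edges; one signal pathway loaded with planted genes and
  metabolites among decoys.

All generators are pure functions of the config (the seed lives inside
it). What passing tests show is that the pipeline recovers planted
structure of this kind; real data add features the generator does not
emulate — count noise, batch effects, unbalanced designs, correlated
archetypes, motif degeneracy — so the tests validate the computations, not
biological claims.

# Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately compact
sizes chosen to exercise every code path with tight statistical margins:
600-gene universes (300 where the recovery condition is defined at that
size), 10 replicates for correlation-heavy DNB checks (50 seeded runs),
20-seed screens for the metabolite and null-calibration checks, 800
profiles for clustering recovery. Exact oracles (enumeration over draws or
k-mers, brute-force recomputation) are used wherever the statistic admits
one, at 1e-10 to 1e-12 tolerances; simulation-based checks assert rates
(recovery ≥ 0.9, type-I error within [0.03, 0.07]) rather than point
values. Degenerate inputs have explicit rules rather than NaN: zero
variance in both groups with zero difference gives p = 1; zero distance in
clustering gives crisp membership; zero-variance genes correlate as 0 in
DNB statistics; constant metabolite variables are dropped from OPLS-DA
with VIP 0.

# Known limitations

* The moderated-t prior is a method-of-moments fit, not the reference
  maximum-likelihood fit; differences are negligible at realistic gene
  counts but the prior df estimate is cruder for very few genes.
* DNB module search is hierarchical clustering on $1-|r|$ at a fixed
  height grid — the established approach in the DNB literature — not an
  exhaustive module search; modules outside the size bounds are invisible.
* Per-sample enrichment scores are the rank-weighted KS walk defined
  above, not the kernel-CDF GSVA statistic; scores are comparable within
  this package only.
* OPLS-DA is limited to binary contrasts with a single predictive
  component, which is the standard use for VIP screening.
* Three replicates make Pearson-correlation-based statistics extremely
  noisy; results on such designs should be read as exploratory.
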