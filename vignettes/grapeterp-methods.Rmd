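---
title: "Methods: integrated transcriptome-metabolome analysis of grape berry terpenes"
author: "grapeterp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated transcriptome-metabolome analysis of grape berry terpenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapeterp)
```

## The analysis problem

Muscat grape aroma is dominated by monoterpenes, which accumulate in berries
partly as free volatiles and mostly as odorless glycosidically bound
conjugates. When the same cultivar is grown in contrasting regions — a humid
eastern site (CL) and an arid, high-radiation western site (GT) — berries
ripen at different speeds and accumulate very different terpene levels.
`grapeterp` implements the combined RNA-seq / GC-MS workflow used to explain
that difference: quantify transcript and volatile levels across four E-L
developmental stages in both regions over two vintages, test which pathway
genes respond to region, correlate gene expression with metabolite
accumulation, and nominate candidate structural genes and their putative
regulators through an anchored co-expression network.

This vignette records how each stage is computed, which parameters matter,
and which design choices were genuinely open.

## Digital expression without replicates

The expression data are tag counts from 24 libraries: one library per
region-year cell at E-L 31 and E-L 36 (limited high-quality RNA at those
stages) and two at E-L 35 and E-L 38. Three conventions from the original
read-processing chain are kept:

* **Read QC** (`filter_reads()`): 2 nt trimmed from both ends; reads under
  60 nt after trimming or with more than two ambiguous bases are excluded.
* **Proportional rescue** (`assign_multireads()`): a multi-mapping group of
  `M` reads with candidate set `S` contributes `M * U_t / sum(U_S)` to each
  candidate `t`, where `U` are unique-read counts. When every candidate has
  zero unique reads the split is uniform — the source procedure is silent
  here, and a uniform split is the least-informative completion. Assigned
  counts are carried as fractions into RPKM and rounded (half up) only for
  the exact test, which needs integers.
* **RPKM** (`rpkm()`): `1e9 * C / (N * L)` with transcript length `L` in nt
  and `N` total mapped reads.

Differential expression between two conditions uses the exact conditional
binomial test (`deg_test()`): conditional on the pooled count `k = x + y`,
under the null `X ~ Binomial(k, N1/(N1+N2))`, with a two-sided p that
doubles the smaller tail including the observed point. No test was named in
the source workflow; the exact conditional binomial (equivalent to the
Audic-Claverie statistic) is the era-standard choice for replicate-free
digital counts and is assumption-light and exactly reproducible. Because the
test conditions on observed totals and ignores biological dispersion, its
p-values are meaningful for ranking within this design rather than as
population-level error statements; the joint threshold with the fold-change
filter (below) is what is actually used downstream.

Zero counts are floored at one before testing and fold-change computation —
the stated convention for transcripts undetected in one library. Replicated
conditions (E-L 35, E-L 38) are pooled by summation before testing
(`pool_replicates = TRUE`, configurable), matching how a two-library exact
test must consume them. `call_degs()` applies Bonferroni adjustment over the
`m` transcripts tested in a comparison (`adjusted_p = min(1, m * p)`) — the
source description conflates Bonferroni with FDR; the literal Bonferroni
rule is implemented and the output column is named `adjusted_p` — and flags
significance at `adjusted_p <= 0.05` and `|log2 ratio| >= 1`.

## Volatile quantification

GC-MS peak areas are semi-quantified in internal-standard equivalents
(`quantify_relative()`): with 10 uL of 4-methyl-2-pentanol stock at
1.0018 g/L spiked into 5 mL of juice, the in-sample IS concentration is
2.0036 mg/L, and an analyte at twice the IS peak area reports 4.0072 mg/L.
Response factors are fixed at 1 because no compound-specific calibration
curves are part of the workflow; concentrations are therefore comparable
within a compound across samples, not across compounds.

Odor activity values divide concentration by the sensory threshold;
`OAV >= 1` is flagged as contributing. The boundary is counted inclusively
so threshold-equal compounds are kept for review.

`totals_by_form()` totals concentrations per (region, year, stage, form)
cell: compound concentrations are summed within each biological replicate
and the replicate sums are averaged (SD over replicate sums). Free and
bound forms are never pooled, and empty cells are reported as missing, not
zero. Group comparisons use one-way ANOVA with Duncan's multiple range test
(`anova_duncan()`): ranges of `p` sorted means are compared against
`R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)` at Duncan's protection
level `alpha_p = 1 - (1 - alpha)^(p-1)`, with the standard step-down
protection (a non-significant range closes every range inside it) and
letter codes read off the maximal non-separated runs. Degenerate inputs
with zero residual variance but distinct means report `p = 0` and separate
every distinct mean.

## Developmental trends

Heatmap-style analyses operate on per-condition profiles: replicate
libraries are averaged into one value per region-year-stage cell
(`cell_means()`; 16 cells in the full design), then rows are z-scored
(`row_scale()`, sample SD, constant rows to zero with a warning).
Hierarchical clustering uses Euclidean distance with complete linkage —
the defaults of the R environment in which the original heatmaps were
drawn — and the dendrogram is exported as Newick with node depth equal to
merge height, so the tree round-trips through any standard parser.

`kmeans_trends()` clusters scaled profiles with Lloyd iterations from
k-means++ seeding under a fixed seed (default `k = 9`, seed 1; the original
UGT-family analysis reports only that clusters "1, 2 and 3" rose, not how
many clusters were fitted, so `k` is an explicit knob). A cluster is called
"upward" when its centroid correlates with the stage index at `r >= 0.7`,
replacing the visual cluster selection of the original figure with a
reproducible rule.

`classify_trend()` assigns the categorical classes used in pathway tables:
`ND` when the transcript is absent from the annotation source, `NC` when
detected at two or fewer of the four stages, otherwise increased
(`r >= 0.7` against stage ranks), decreased (`r <= -0.7`) or stable, with a
peaked subtype when an interior-stage maximum exceeds both ends at least
two-fold. The `|r| >= 0.7` and two-fold values are artifact choices
(the original classes were read off heatmaps by eye); both are exposed as
parameters. Stage ranks 1..4, not calendar days, are the covariate.

## Gene-metabolite integration

`gene_metabolite_corr()` correlates expression and concentration profiles
over the shared condition cells (Pearson, two-sided t-based p on `n - 2`
df). The `"cumulative"` mode first replaces expression by its running sum
over stages within each region-year series — glycosides accumulate, so a
transiently expressed glucosyltransferase is better reflected by its
integrated expression; a constant expression profile cumulates to a
strictly increasing one and correlates +1 with any linear accumulation.
No multiple-testing correction is applied to these screening correlations
(the original analysis reports raw p < 0.05); the candidate rule below is
the real filter.

`nominate_candidates()` requires **both** evidence arms: at least one
supporting correlation with `|r| >= 0.8` and `p <= 0.05`, all supporting
correlations concordant in sign, and a significant regional DEG call at one
or more stages. The rank score `max|r| * (1 + n_support / 10)` orders genes
by correlation strength with a mild bonus for breadth of metabolite
support; ties break on gene id for determinism.

## Anchored co-expression network

`correlation_edges()` connects profile pairs with `|r| >= 0.8`. The
threshold is inclusive by default: the source description uses both
"absolute value > 0.8" and ">= |0.8|" in different places (and admits some
positives "over 0.78"); a single inclusive threshold with per-layer
overrides is the cleanest resolution, and `inclusive = FALSE` restores the
strict reading. `build_anchored_network()` builds the three-layer network:
a TF is admitted only when it passes the threshold against **every** anchor
(the two nominated structural genes in the original analysis), and a
ripening-associated gene is admitted through at least one admitted TF;
anchors never connect directly to ripening genes. TFs whose anchor
correlations disagree in sign are kept but labelled `"mixed"` rather than
silently dropped. Exports (`export_network()`) are Cytoscape-ready SIF and
GraphML plus node/edge attribute tables; an over-threshold-free network is
valid and empty, never an error.

## qPCR validation

`expression_2ddct()` implements `2^-dCT` with the reference Ct taken as
the geometric mean of three reference genes (GAPDH, actin, ubiquitin),
technical replicates averaged arithmetically first.
`validate_against_rpkm()` correlates per-gene qPCR and RPKM values across
samples on the log2 scale and passes at `R^2 > 0.7` **and** `r > 0`: R^2
alone is directionless and an anti-correlated gene must not validate. The
log scale is used for the pass decision because expression spans orders of
magnitude; the raw-scale r is also reported.

## Climate summaries

`climate_regional_records()` carries the published per-phenophase
meteorological measurements for both regions and seasons;
`season_summary()` recomputes season totals by summation (days, radiation,
GDD, sunshine, rainfall) and the season day-night temperature difference as
the unweighted mean over phenophases, rounded half-up to two decimals. The
published 2011 totals and the GT 2010 temperature mean reproduce exactly
under the unweighted convention, while the CL 2010 printed temperature
total matches a days-weighted mean instead, and the CL 2010 printed GDD
total does not equal its phenophase sum — the 2010 rows of the source table
are internally inconsistent. The unweighted mean is the default, a
days-weighted option is provided, and the package asserts only the
self-consistent entries. GDD values are treated as opaque published
aggregates (no base temperature is stated).

## The synthetic-data generator

`simulate_berry_dataset()` draws complete datasets with the structure the
analysis assumes, so every stage is testable without the deposited raw
data. What it emulates:

* the 2 regions x 2 years x 4 stages design with the uneven library layout
  (24 libraries) and 2 metabolite repeats per cell (32 samples);
* archetypal developmental trajectories (increasing / decreasing / peaked /
  stable) on the log scale, with a 3-log2 amplitude for genes and ~2
  natural-log units for compounds;
* unique read counts as negative binomial around cell means (dispersion
  0.05, i.e. size 20 — moderate overdispersion typical of bulk RNA-seq;
  no dispersion was reported, so this is a declared model choice), with
  ~5% of reads in multi-read candidate groups and library totals near the
  1e6-read default (library sizes were not published; this is a knob);
* log-normal metabolite concentrations with the bound-form mean a
  configurable factor (default 5) above the free form, reflecting the
  dominance of glycosides;
* planted structure: `planted_effect()` fixes archetypes, regional fold
  changes ramped in log scale to the final stage, and correlation partners
  realized by mixing the standardized target profile with independent noise
  (`plant_correlated_profile()`), so the realized sample correlation is
  close to — not exactly — the target, which is honest about sampling error
  at 16 cells;
* a qPCR Ct table consistent with the latent expression and a climate table
  in the published layout with plausible, newly drawn values.

The same seed reproduces a bit-identical bundle, and generation restores
the caller's RNG state. What the generator does **not** emulate: raw reads
or alignment artifacts, compound identification noise, batch effects, or
any dependence between transcriptome and metabolome beyond the planted
correlations — so passing recovery tests demonstrates that the estimators
find the structure they were built for, not that they are robust to every
failure mode of real field data.

## Numerical choices and problem sizes

Tie-breaks and tolerances: hierarchical merges follow `hclust`'s
lowest-index convention; count conservation in the rescue step is asserted
to 1e-6; Pearson implementations are checked against the covariance/SD
formula to 1e-12; rounding for reporting (temperature means) is half-up.
The test suite verifies the rescue, edge-listing, Duncan and k-means
operators against independently coded brute-force oracles, calibrates the
exact test's type-I error on 2,000 simulated null pairs and the correlation
p-values on 1,000 independence replicates, and measures planted-structure
recovery (nomination sensitivity and false-nomination rate; exact recovery
of a planted TF layer) over 200 simulation seeds at 16 condition cells —
sizes chosen so the whole suite runs in well under a minute of simulation
per property while keeping Monte-Carlo error a few percent.

## Known limitations

* The exact conditional binomial test understates biological variability;
  with only two pooled libraries per condition this is intrinsic to the
  design, not fixable by the artifact.
* Duncan's test controls error less stringently than Tukey's HSD; it is
  implemented because it is the procedure of record for the metabolite
  comparisons.
* Correlation-based nomination and network admission cannot distinguish
  co-regulation from causation; the outputs are candidate lists.
* Semi-quantified concentrations are IS-equivalents; OAVs computed from
  them inherit that approximation.
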