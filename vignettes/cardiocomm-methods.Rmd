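---
title: "Methods: comparative single-cell analysis of cardiac inflammatory cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative single-cell analysis of cardiac inflammatory cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocomm)
```

# Scope and model

`cardiocomm` compares single-cell RNA-seq of zebrafish cardiac macrophages
and neutrophils between a regenerative condition (PBS vehicle) and a
macrophage-delayed condition (clodronate-liposome pre-treatment, CL) across
an injury timecourse (uninjured; 1, 3, 7 days post cryoinjury). It assumes
clustering and annotation have already happened upstream (CellRanger /
Seurat or equivalents): the package's inputs are gene × barcode count
matrices plus a barcode → (cluster, condition, timepoint) annotation. On
top of those it implements barcode QC, pseudobulk aggregation, a
nonparametric differential-expression caller, cluster-composition
contrasts, and ligand–receptor crosstalk networks. Upstream steps —
alignment, integration, dimensionality reduction, cluster discovery,
trajectory analysis — are deliberately out of scope.

# Barcode quality control

Four per-barcode metrics are computed: total UMIs (`n_umi`), detected genes
(`n_genes`), the library-complexity ratio
`log10(n_genes)/log10(n_umi)`, and the mitochondrial UMI fraction. A
barcode is retained only if **all four strict inequalities** hold:
`n_umi > 400`, `n_genes > 200`, complexity `> 0.8`, mitochondrial fraction
`< 0.23`. Boundary barcodes are rejected; a barcode with `n_umi ≤ 1` has an
undefined complexity ratio and therefore fails that rule (it is reported
with `NA`, never silently dropped). The four rules are applied jointly in
one pass; filtering is idempotent and monotone in each threshold.
Mitochondrial genes are identified by name prefix (default `mt-`,
case-insensitive) with an explicit-list override, since no fixed
mitochondrial gene set can be assumed across annotation versions.

# Pseudobulk aggregation and normalization

For each (cluster × dataset) group the package records summed raw counts
and the un-normalized mean over the group's cells. Normalization is
decomposed so that the two relevant quantities each enter exactly once:
cell number enters through the mean layer (`raw_mean = raw_sum / n_cells`),
and sequencing depth through column scaling of the summed layer
(`norm = scale · raw_sum / total_counts`, `scale = 1e6` by default), making
each group's normalized column sum to `scale`. Upper-quartile scaling
factors (`UQ_s / geometric mean of UQs`) are provided for bulk-style
matrices; quantiles use linear interpolation (R type 7) over **nonzero**
values, because in sparse data a quantile over all genes frequently
collapses to zero.

The marker-gene routine applies a detection filter (gene detected in
≥ 25 % of the cluster's cells), a two-sided Wilcoxon rank-sum test of
cluster vs rest, Bonferroni correction over the tested genes, retention at
adjusted p < 0.05, and ranking by average log2 fold change then p-value.
The rank-sum test is a deliberate, documented stand-in for heavier
hurdle-model testing: it is assumption-light, and the filters around it are
what shape the marker lists.

# The M–D differential-expression caller

Each gene's two-condition contrast is summarized by the pair
`M = log2(x1/x2)` and `D = |x1 − x2|` on normalized expression (zeros
replaced by `k = 0.5` before the ratio). Signal pairs are compared against
a noise distribution pooled from all within-condition replicate pairs and
all genes, computed with the same `k`. The differential probability of a
gene is the fraction of noise points it dominates in both coordinates,
with **non-strict** comparisons so that ties count toward the noise — a
conservative choice, made explicit because tie handling is easy to get
silently wrong. `q` is therefore jointly monotone in `|M|` and `D`,
invariant to permutation of the noise set, and symmetric under swapping
the conditions (M flips sign; D and q are preserved — the replicate
simulation uses the same derived seed for both samples precisely so the
pooled noise set is identical either way).

When a design has no real replicates, technical replicates are simulated:
each replicate is a multinomial draw of size `round(pnr · total)` with
probabilities proportional to the observed counts perturbed by ±`nv`
uniform noise, with defaults `pnr = 0.2`, `nss = 5`, `nv = 0.02`. Calls use
`q > 0.99` for bulk-style contrasts. For pseudobulk condition contrasts the
default threshold is `q > 0.8`: simulated technical replicates understate
biological variability, and the conventional guidance for
simulated-replicate noise is a lower threshold than for real replicates.
Both thresholds are parameters.

**What the caller assumes about its input.** The noise distribution pools
all genes, so genes with near-zero counts contribute large-|M|, small-D
noise points that no moderate fold change can dominate. The caller is
therefore intended for count-filtered matrices — standard practice for
this family of methods — and the package's own benchmarks model exactly
that: 2000 retained genes with means drawn log-normally around 500
(floored at 50, the practical detectability floor at these depths) and
sample-level negative-binomial dispersion 0.02, a typical gene-wise
dispersion for well-expressed genes in bulk RNA-seq. (The simulator's
per-cell dispersion of 0.1 is a different quantity: single-cell counts are
far noisier than the pseudobulk/bulk samples this caller sees.) Under that
design the measured null call rate at q > 0.99 is ≈ 0.001 and sensitivity
for 4-fold changes ≈ 0.9. Power is expression-dependent by construction:
a low-expression gene cannot dominate the D coordinate of high-expression
noise points, which is a known, accepted property of this statistic rather
than a defect of the implementation.

# Cluster composition

Proportions are simple count fractions per dataset. The condition contrast
per cluster is

```
log2((n_A + 0.5) / (N_A + 0.5)) − log2((n_B + 0.5) / (N_B + 0.5))
```

with the pseudocount applied to counts (a Haldane–Anscombe-style
continuity correction), so clusters that vanish in one condition — the
behaviour of resident macrophage clusters under CL — give finite ratios.
Computing the difference of logs rather than the log of a ratio makes the
contrast *exactly* antisymmetric under swapping conditions. The default
pooling policy pools the injured timepoints (1, 3, 7 dpci) per condition;
a per-timepoint mode is available, since pooling across injured
timepoints and contrasting each timepoint separately are both defensible
summaries. No significance test is attached: the ratio
is reported descriptively, and the labels (condition-A-associated /
condition-B-associated / neutral) follow the ratio's sign.

# Ligand–receptor crosstalk

The target-species database is built from a human ligand→receptor pair
table and a human→target ortholog map by full Cartesian expansion of
one-to-many orthologies (paralog receptors yield distinct pairs — best-hit
collapsing would hide exactly the paralog diversity the analysis wants),
dropping and counting pairs with an unmapped side. A gene is *expressed*
in a (cluster, dataset) group when its normalized pseudobulk value is at
or above the group's upper quartile, computed over nonzero values (both
the quantile and the zero-handling are parameters; ties at the cutoff
count as expressed). An interaction edge (sender, ligand, receptor,
receiver) exists when the ligand is expressed in the sender and the
receptor in the receiver; autocrine edges are permitted; macrophage→
neutrophil and neutrophil→macrophage directions are enumerated separately,
with the mixed MN cluster assignable to either side. Edge identity for
condition comparison excludes the dataset label; at a matched timepoint the
A-only / B-only / shared labels partition the edge union exactly. Exports:
edge CSV, Cytoscape SIF (`sender TAB ligand:receptor TAB receiver`), and
GraphML with per-(sender, receiver) event counts as edge weights.

# The synthetic-data generator

The generator emulates the seven-dataset design: UN, PBS1d/3d/7d,
CL1d/3d/7d, with twelve inflammatory clusters (Mac1–Mac9, Neu1, Neu2, MN).
Counts are negative binomial with shared per-gene dispersion (default
0.1) and log-normal library-size factors (sdlog 0.3); cluster sizes are
multinomial draws from per-dataset proportion vectors in which the
resident macrophage clusters (Mac2, Mac3) dominate the uninjured heart,
persist under PBS and collapse under CL, and neutrophils surge at 1 dpci.
Mitochondrial genes (`mt-` prefixed) are sized to an expected 5 % UMI
share so the QC rules are exercised. Ground truth is planted three ways:

* **condition-enriched genes** — mean multiplied by `2^lfc` (default
  4-fold) in one cluster under one condition;
* **condition-specific ligand–receptor pairs** — ligand and receptor set
  to a high mean (8× the upper quartile of baseline means) in their
  sender/receiver cluster under their condition, near-silent elsewhere;
* **decoy pairs** — half drawn from the top decile of baseline expression
  (expressed everywhere, hence shared between conditions), half from the
  bottom decile (silent everywhere). Decoys are deliberately kept away
  from the expression cutoff: a decoy whose truth status depends on
  sampling noise is not a usable negative control.

Defaults are desk-scale (1000 genes × 2000 cells per dataset, enough for
≥ 150 cells in the smallest persistent cluster); the study's 9–17k-cell
scale is available through the configuration. Real full-scale per-cluster
cell counts are not published, so the default proportions are chosen for
statistical power, not fidelity to any particular observed composition.
Generation is bit-identical for identical (config, dataset): every dataset
derives its own seed from the base seed.

**What the simulator does not model:** ambient RNA, doublets, batch
effects, cell-cycle structure, or read-level noise. Passing tests
therefore demonstrate that the statistical machinery recovers planted
effects under clean negative-binomial noise — not that it is robust to
artifacts the generator never produces.

# Pipeline, determinism, and problem sizes

`run_pipeline()` chains simulate (or load) → QC → pseudobulk → per-cluster
differential expression (PBS vs CL, injured timepoints pooled) →
composition → crosstalk (PBS7d vs CL7d by default), writes every stage's
tables, and emits a manifest of relative paths and MD5 hashes; identical
config + seed gives byte-identical outputs. All randomness is routed
through per-stage seeds derived from one base seed, kept within 32-bit
integer range.

The test-suite and acceptance benchmarks use deliberately scaled problem
sizes chosen to make each check statistically meaningful at interactive
cost: 50 random 200 × 500 matrices for the QC oracle; 10 × 2000-gene
samples for M–D calibration and power; 100 two-cluster datasets of 2000
cells per side for composition recovery (0.30 vs 0.10 is recovered as
log2 ratio ≈ log2 3 ± 0.3 in ≥ 95 % of runs); and 10 full two-dataset
simulations with 12 planted pairs among ~200 decoys for crosstalk
precision/recall. These sizes are the package's own benchmark design.

# Known limitations

* The M–D caller's power is expression-rank dependent (see above) and its
  simulated-replicate null understates biological variability; q values
  from simulated replicates should be read as a ranking with a calibrated
  null-rejection rate, not as posterior probabilities.
* The pseudobulk normalization sentence "total read counts and total cell
  numbers" admits more than one decomposition; the one implemented (mean
  over cells, then depth scaling of sums) uses each quantity exactly once
  and is exposed via the `scale` parameter.
* The shipped ligand–receptor and ortholog tables are small curated demos
  of the input format, not a complete database.
* Composition ratios are descriptive; no compositional-data model or
  differential-abundance test is attached.
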