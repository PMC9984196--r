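---
title: "Models and methods behind rnaloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnaloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaloc)
```

# The scientific problem

Cells place mRNAs at particular locations: epithelial monolayers sort
transcripts along their apicobasal axis, and neurons export transcripts
into neurites. Three experimental readouts quantify this, and rnaloc
implements the statistics for all three:

* **Fraction-level RNA-seq.** Libraries are prepared from subcellular
  fractions (a streptavidin pulldown of proximity-labeled RNA versus the
  input; an apical versus a basal labeling compartment; a neurite versus
  a soma fraction of mechanically separated cultures). Per gene, the
  quantity of interest is a log2 ratio of normalized abundance between the
  two fractions — *Cytoplasmic Bias* (pulldown/input), *Apical Bias*
  (apical/basal) or the neuronal *Localization Ratio* (neurite/soma).
* **5' UTR sequence.** Ribosomal-protein mRNAs and other basally or
  neurite-localized transcripts carry pyrimidine-rich regulatory elements
  (PRREs) in their 5' UTRs: at least 9 pyrimidines in any 10-nt window.
  An element starting at position 1 of the UTR is a 5' TOP motif;
  downstream elements are PRTEs.
* **smFISH spot coordinates.** Single transcripts appear as 3D spots;
  per-cell summaries (mean apicobasal z, or neurite/soma puncta counts)
  are compared between reporter constructs by Wilcoxon rank-sum tests.

A fourth layer, the **LRz meta-statistic**, pools neurite/soma
localization ratios from many heterogeneous public fractionation datasets
by z-normalizing within each dataset and taking each gene's median
z-score, and lets localization programs be correlated *across* cell types
(`correlate_compartments`).

# The enrichment model

## Normalization

`estimate_size_factors()` implements median-of-ratios: for each gene with
nonzero counts in every sample, the ratio of its count to its geometric
mean across samples is formed, and a sample's factor is the median of
those ratios, rescaled so the factors have geometric mean 1. The median
is taken on the ratio scale — the literal form of the estimator — which
differs from a log-scale median only when the number of reference genes
is even.

For the bias itself, `compute_bias()` normalizes counts to
**composition-scaled effective library sizes**: the column total times a
composition factor obtained by median-of-ratios on the count
*proportions*, expressed per million. This is the effective-library-size
convention familiar from TMM-style pipelines, and it was chosen for a
specific reason: proportions do not change when a whole column is
rescaled, so normalized values — and therefore every reported bias,
including its pseudocount — are *exactly* invariant to multiplying any
single library by a constant. A global rescaling of geometric-mean-1
factors cannot achieve this: rescaling one column perturbs every factor
through the shared per-gene reference, and all normalized counts drift by
the n-th root of the scaling constant. With an absolute pseudocount that
drift would leak into the bias at the 1e-3 level; with effective-library
CPM it cancels to machine precision.

One known property of median-of-ratios inherited here: when enrichment is
strongly asymmetric (e.g. 10% of genes 4-fold up in one fraction and
nothing down), the median reference gene is slightly displaced and all
null biases shift by a few hundredths of a log2 unit (about −0.08 under
the default simulation). This is a property of the estimator, not a bug,
and the same effect exists in standard differential-expression pipelines.

## The test

Counts are modeled as negative binomial with variance
$\mu + \alpha\mu^2$. Genes are filtered by the rule that at least one
sample must reach `min_count` (default 10) raw counts. The reported
effect is

$$\mathrm{bias}_g = \log_2\frac{\bar{y}_{g,\mathrm{num}} + c}
                               {\bar{y}_{g,\mathrm{den}} + c},$$

with $\bar y$ the mean normalized count per fraction and pseudocount
$c = 0.5$ (CPM units); the pseudocount prevents infinities for
zero-count fractions while leaving well-covered genes essentially
untouched. No shrinkage of the effect is applied.

The standard error comes from the delta method with the NB variance
plugged in. Dispersion is estimated by the method of moments on
normalized counts, with two modes:

* `dispersion = "pooled"` (default): a single common $\alpha$ across all
  genes (excess residual variance summed over genes divided by summed
  squared means), Wald statistic referred to a standard normal. With
  three replicates per fraction a per-gene variance estimate carries only
  ~4 degrees of freedom of information; pooling across thousands of genes
  makes the plug-in variance essentially noise-free, which keeps the
  nominal 5% level accurate (empirically ~0.05 on a 10,000-gene null)
  *and* preserves power (~1.0 at a planted 4-fold effect with 3v3
  replicates). This mirrors the classic common-dispersion mode of
  count-based DE tools.
* `dispersion = "genewise"`: per-gene moment estimates floored at 1e-8
  and capped at 10, with the statistic referred to a t distribution on
  the residual degrees of freedom. The t reference is essential here — a
  normal reference with per-gene variances at 3v3 inflates the type-I
  rate to ~0.12 — but the heavier tails cost power (~0.8 in the same
  planted scenario). Use this mode when per-gene dispersion heterogeneity
  is a real concern and replicates are plentiful.

Multiple testing uses Benjamini–Hochberg over all tested (post-filter)
genes; the conventional thresholds are FDR < 0.01 for Cytoplasmic Bias
and < 0.05 for the polarity metrics, both exposed in `run_config()`.
Because dispersion estimation here deliberately avoids empirical-Bayes
shrinkage toward a fitted trend, significant-gene *counts* from
trend-shrunken pipelines on real datasets are not expected to be
reproduced exactly.

# The PRRE scanner

`scan_prre()` slides a 10-nt window (configurable) and marks windows with
at least 9 pyrimidines (C/T; U read as T; N and other IUPAC ambiguity
codes count as non-pyrimidines — a conservative choice). Overlapping
*or book-ended* qualifying windows merge into one element; qualifying
windows separated by at least one non-qualifying window remain separate
elements. The element position is the start of its first qualifying
window, and an element at position 1 is classed TOP, else PRTE. Two
consequences of the 9-of-10 tolerance are worth knowing:

* any 10-nt pyrimidine run beginning at position $p$ also qualifies the
  window at $p-1$ (one purine + nine pyrimidines), so reported element
  starts extend one base 5' of a pure run;
* a TOP element therefore survives a single prepended purine (the
  element still starts at position 1), while two or more purines demote
  it to a PRTE starting at the purine run's end − hence TOP
  classification is robust to ±1 nt of transcription-start heterogeneity
  but not more, and no larger tolerance is modeled.

`mutate_prre()` applies the purine-swap rule (C→A, T/U→G) used to build
motif-dead reporter controls; scanned mutants can never contain an
element since they contain no pyrimidines. `annotate_utrs()` applies the
scanner per gene over its longest annotated UTR (ties broken
lexicographically by transcript id) and reports the most 5' element.

# smFISH summaries

`summarize_z()` averages spot z per (cell, target) and subtracts the
experiment-wide **median z of all control-transcript spots**.
Subtraction, not division, is used: the figures this supports read as
positions relative to the control, and a ratio would be ill-defined near
the coordinate origin. The reference is experiment-wide because control
and reporter constructs are expressed in different cells. Cells — never
spots — are the unit of downstream tests; duplicating every spot in a
cell changes nothing.

Rank-sum comparisons (`compare_position`, and the construct comparison in
`neurite_soma_ratio`) are exact when the combined sample is at most 30
cells without ties, and otherwise use the normal approximation with tie
and continuity corrections. `qc_filter_cells()` retains (cell, target)
groups with between 100 and 1000 spots by default (reporter expression
levels); endogenous targets should drop the upper bound (`Inf`).
Readers accept either z in µm or stack slice indices with a configurable
spacing (default 0.2 µm per slice).

`neurite_soma_ratio()` computes per-cell neurite/soma puncta count
ratios; a cell with zero soma spots has an undefined ratio and is
excluded with a warning, while zero neurite spots simply give ratio 0.

# LRz and the qPCR localization ratio

`compute_lrz()` z-normalizes each dataset column over its measured genes
(n−1 denominator) and takes each gene's median available z-score. A
dataset with zero variance is rejected by name; columns need at least 3
measured genes; genes present in fewer than `min_datasets` datasets
(default: half the datasets, rounded up) are reported missing. The
z-normalization makes LRz exactly invariant to per-dataset affine
distortions, which is the point: the pooled public datasets differ in
platform, depth and dynamic range.

`qpcr_localization_ratio()` is the ΔΔCt estimator with an unmodified
co-expressed reference transcript as internal control: technical
replicates are averaged, then
$LR = \log_2(e)\left[(Ct^{ref}_{neu} - Ct^{tgt}_{neu}) -
(Ct^{ref}_{soma} - Ct^{tgt}_{soma})\right]$ with amplification
efficiency $e$ (default 2, perfect doubling). The simulator
`generate_qpcr_ct()` is its exact inverse at zero noise.

# What the simulators emulate — and what they do not

All generators take explicit seed fields and are bit-reproducible; no
global RNG state is consulted.

* `generate_enrichment_counts()`: log-normal gene base means (default
  natural-log mean log(500), sd 1 — a typical fractionation library's
  dynamic range), NB counts with a **single common dispersion**
  (default α = 0.05, i.e. ~22% biological CV; replicate-level variance
  of labeling-based enrichment is not published, so this is a documented
  free choice), uniform per-sample library scale factors, and a planted
  log2 effect in a gene subset (or a per-gene effect vector). It does
  *not* model per-gene dispersion trends, batch structure, or
  composition beyond the planted effects — so passing recovery tests
  here demonstrates correctness of the estimator, not robustness to
  every pathology of real libraries.
* `generate_spot_table()`: per-cell 3D spot clouds in a slab of default
  height 13.6 µm (a typical monolayer stack: 68 slices at 0.2 µm). The
  shared base law is uniform over the *interior band* of the slab that
  leaves room for the largest planted |shift| plus 3 noise-sd on either
  side; targets are that law translated by their planted shift plus
  Gaussian localization noise (default 0.5 µm), with reject-and-resample
  for residual out-of-slab draws so no mass accumulates at the
  boundaries. The interior band exists because translating a
  full-height uniform would unavoidably truncate at the slab faces and
  attenuate every planted shift, breaking the contract that the planted
  shift equals the expected displacement. Spatial correlation between
  spots within a cell is not modeled.
* `generate_utr_set()`: background bases are pyrimidines with
  probability 0.25 by default (well below 0.5, so a spurious qualifying
  window arises in well under 5% of sequences); planted elements are
  pure pyrimidine runs. Because of the 9-of-10 boundary effect described
  above, the run is placed one base 3' of the recorded truth position
  behind two insulating purines, so the scanner's reported start equals
  the recorded truth exactly. Sequences use A/C/G/T only; N handling is
  exercised by hand-written fixtures in the tests.
* `generate_multidataset_lr()` / `generate_qpcr_ct()`: affine
  per-dataset distortions with Gaussian noise, and Ct tables built as
  the exact ΔΔCt inverse.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to make sampling error a
small fraction of each tolerance: 5,000 genes with 10% enriched for
effect recovery and power, a 10,000-gene pure null for type-I
calibration, 20 cells × 200 spots for smFISH shift recovery with 1,000
repeated 16v16-cell experiments for p-value uniformity, 8 datasets × 500
genes for LRz invariance, and 2,000 genes for the cross-compartment
correlation. Dispersion estimates are floored at 1e-8 and capped at 10;
z-scores use the n−1 standard deviation; BH is the standard step-up;
Spearman p-values use the tie-corrected approximation (`exact = FALSE`).
Degenerate inputs are either errors with actionable messages (zero
variance datasets, missing fractions, no all-nonzero reference gene) or
explicit missing values (all-zero gene rows).

# Known limitations

* Headline significant-gene counts from trend-shrunken DE pipelines on
  the original deposited datasets are out of scope by design (no
  empirical-Bayes dispersion shrinkage, no shrunken fold changes).
* The TOP/PRTE position convention tolerates exactly one 5' purine; true
  transcription-start heterogeneity spans several nucleotides and is not
  modeled.
* The gene universe for FDR is the post-filter gene set of the analyzed
  matrix; results are conditional on the filter.
* Ortholog mapping is a required input; only one-to-one pairs enter the
  cross-compartment correlation, and many-to-many pairs are dropped with
  a count.
* Whether per-cell means should be weighted by spot count when pooling
  across coverslips is unsettled; cells are weighted equally here.
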