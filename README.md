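# rnaloc

Statistics for subcellular RNA localization, for researchers quantifying
*where* transcripts sit inside cells: across the apicobasal axis of
epithelial monolayers, between the neurites and somata of neuronal
cultures, or between a proximity-labeling pulldown and its input.

The package covers four layers of evidence with one consistent toolkit:

1. **Fraction-level RNA-seq.** For a gene *g* with normalized mean
   abundance $\bar y$ in two fractions, the localization metric is

   $$\mathrm{bias}_g = \log_2 \frac{\bar y_{g,\mathrm{num}} + c}{\bar y_{g,\mathrm{den}} + c}, \qquad c = 0.5,$$

   the *Cytoplasmic Bias* (pulldown/input), *Apical Bias* (apical/basal)
   or neuronal *Localization Ratio* (neurite/soma) depending on the
   contrast. Counts are normalized by median-of-ratios composition
   factors on effective library sizes, genes need ≥ 10 counts in at
   least one sample, and each gene gets a negative-binomial Wald test
   (variance $\mu + \alpha\mu^2$, method-of-moments dispersion pooled
   across genes) with Benjamini–Hochberg FDR.
2. **5′ UTR motifs.** A pyrimidine-rich regulatory element (PRRE) is
   any merged run of 10-nt windows holding ≥ 9 pyrimidines; an element
   starting at UTR position 1 is a 5′ TOP motif, downstream elements are
   PRTEs. `mutate_prre()` builds the purine-swapped (C→A, T→G) motif-dead
   controls used in reporter experiments.
3. **smFISH spot tables.** Per-cell mean z positions normalized by
   subtracting the experiment-wide median of a non-localized control
   transcript, neurite/soma puncta ratios, spot-count QC, and Wilcoxon
   rank-sum comparisons with exact small-sample p-values.
4. **Cross-dataset meta-analysis.** The LRz statistic — a gene's median
   within-dataset z-score of its localization ratio across many
   fractionation experiments — and Spearman correlation of localization
   between cell types through an ortholog map.

A simulator module generates all four kinds of input with planted ground
truth (negative-binomial fraction counts, UTRs with planted pyrimidine
runs, 3D spot clouds with planted shifts, multi-dataset LR matrices with
affine distortions, ΔΔCt qPCR tables), so the whole pipeline is testable
without any external data. `build_dual_transcriptome()` additionally
emits the spliced + unspliced ("two versions of every transcript") FASTA
used to quantify pre-mRNA alongside mature mRNA.

## Worked example

```r
library(rnaloc)

# simulate a pulldown/input experiment: 1000 genes, 10% enriched 4-fold
sim  <- generate_enrichment_counts(enrichment_sim_config(n_genes = 1000, seed = 42))
bias <- compute_bias(sim$counts, "pulldown", "input")
head(bias, 4)
#>      gene_id base_mean    bias    se wald_stat  p_value      fdr
#> 1 gene_00001      2014 -0.1671 0.245   -0.6828 4.95e-01 8.20e-01
#> 2 gene_00002       293  0.0236 0.252    0.0937 9.25e-01 9.90e-01
#> 3 gene_00003       779 -0.2040 0.247   -0.8272 4.08e-01 7.53e-01
#> 4 gene_00004      2983  1.9160 0.245    7.8295 4.90e-15 1.20e-13

nrow(subset(bias, fdr < 0.01 & bias > 0))
#> 100        # all 100 planted enriched genes, none missed

# a 5' TOP motif and its purine-swapped mutant
scan_prre("CCTCTTTTTCCGGCTGGAACC")
#>   start end n_qualifying_windows motif_class
#> 1     1  12                    3         TOP
mutate_prre("CCTCTTTTTCCGGCTGGAACC")
#> [1] "AAGAGGGGGAAGGAGGGAAAA"

# smFISH: recover a planted 2 um basal shift
sm <- generate_spot_table(spot_sim_config(seed = 7),
                          targets = data.frame(target = "reporter", shift_um = -2))
sz <- summarize_z(sm$spots, control_target = "control")
median(sz$normalized_z[sz$target == "reporter"])
#> -1.99      # um below the control median
compare_position(sz, "reporter", "control")$p_value
#> 6.8e-08
```

Gene 4 above is a planted enriched gene: its estimated bias (1.92) sits
at the planted log2 fold change of 2, and the per-cell smFISH summary
recovers the planted −2 µm shift to within a few hundredths of a
micrometre.

File-based workflows (`run_enrichment_workflow()`,
`run_localization_workflow()`) read count/sample-sheet TSVs, UTR FASTA,
LR matrices and ortholog tables, and write bias tables, motif
annotations, LRz tables, a JSON report and a verbatim YAML copy of the
configuration for provenance.

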