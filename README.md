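# crcpanel

Integrative multi-omics analysis of cancer cell-line panels, as a tested,
reusable R package.

Cell-line panels profiled at the DNA, RNA and protein level are the workhorse
pre-clinical models of colorectal cancer. Characterizing such a panel means
running a family of interlocking analyses: mutation loads and trinucleotide
spectra that separate hypermutator (MSI/*POLE*) from chromosomally unstable
(MSS/CIN) lines; copy-number segmentation and aberration burdens; discovery
of the two intrinsic expression subgroups (*colon-like* vs
*undifferentiated*); the influence of copy number on each gene's own
expression (*in-cis* dosage); nomination of amplified, outlier-expressed
driver candidates; and mRNA–protein concordance. These steps are usually
performed as one-off scripts. `crcpanel` implements the whole chain as
documented, tested functions, together with a synthetic panel generator that
plants known ground truth in every data layer so each stage's recovery can be
verified end to end.

## Methods at the core

* **Penalized piecewise-constant segmentation (PCF).** Per chromosome, the
  segmentation minimizes `RSS + gamma * (number of breakpoints)` *exactly*
  via an O(n²) dynamic program (`pcf_segment()`, default `gamma = 100` on
  noise-standardized data). Gains/losses are called at PCF values ≥ 0.15 /
  ≤ −0.15 (± 0.3 for integration analyses), aberration burden is the percent
  of covered bases aberrant, and multi-sample comparison uses smallest
  regions of overlap (`compute_sro()`) and gene-level mapping with median /
  consistent-category rules (`map_genes()`).
* **96-context mutation spectra** in the pyrimidine-reference convention
  with strand collapsing (`mutation_spectrum()`), after filtering calls to
  ≥ 10 alternative reads and discarding known polymorphisms unless
  clinically associated (`filter_variants()`); loads compared by exact
  Wilcoxon rank-sum (`compare_loads()`).
* **Expression subtyping**: top-1000 variable genes, PCA, and the
  between-peaks-minima split of the bimodal PC1 density
  (`bimodal_split()`), corroborated by single-sample gene set enrichment
  (`ssgsea_score()`, rank-weighted running sum, `alpha = 0.25`) and
  moderated-*t* differential expression with empirical-Bayes variance
  shrinkage (`differential_expression()`).
* **In-cis integration**: for genes aberrant (±0.3) in more than 2 eligible
  MSS lines, Wilcoxon tests of expression in gain vs neutral∪loss (and loss
  vs neutral∪gain) with per-direction BH correction, plus gene-wise Spearman
  flagging at rho > 0.7 (`test_cis()`, `correlate_cis()`).
* **Outlier nomination**: genes whose extreme PCF value (beyond 4 × 0.15)
  and extreme expression (|z| > 3 within-sample) fall in the *same* cell
  line (`nominate_concurrent()`), optionally corroborated at the protein
  level.
* **Gene–protein concordance**: Pearson correlations per antibody–gene pair
  with a lowest-variation-quartile filter, and fold-change concordance
  across differential-expression results (`pair_and_correlate()`,
  `fc_concordance()`).

## Worked example

```r
library(crcpanel)

## simulate a 30-line panel with planted ground truth
panel <- generate_panel(panel_config(seed = 42))
panel
#> Synthetic cell-line panel
#>   samples:  30 (MSI:10, MSS:19, POLE:1)
#>   variants: 2661
#>   genes:    5000; miRNAs: 400; antibodies: 150
#>   probes:   4800 on 8 chromosomes

## variant filtering and the hypermutator load contrast
kept  <- filter_variants(panel$variants, min_alt_reads = 10)
loads <- variant_load(kept, samples = panel$annotations$sample_id)
hyper <- panel$annotations$phenotype %in% c("MSI", "POLE")
tapply(loads$n_nonsynonymous, hyper, median)
#> FALSE  TRUE
#>    17   120
compare_loads(loads$n_nonsynonymous[hyper], loads$n_nonsynonymous[!hyper])$p.value
#> [1] 7.264651e-06

## segment a (quiet, MSI) sample's probe track at penalty 100
track <- data.frame(panel$probes, value = panel$probe_values[, "CL01"])
seg <- pcf_segment(track, gamma = 100, sample_id = "CL01")
genome_fraction_aberrant(seg)
#>      CL01
#> 0.6364774

## expression subgroups: top-1000 genes -> PCA -> between-peaks split
top <- select_variable_genes(panel$expression, 1000)
pca <- pca_scores(top, marker_set = panel$gene_sets$GI_MARKERS)
pc1 <- setNames(pca$scores[, 1], rownames(pca$scores))
split <- bimodal_split(pc1)
table(split$label, panel$truth$subgroup[split$sample_id])
#>                    colon_like undifferentiated
#>   colon_like               16                0
#>   undifferentiated          0               14
```

The load medians sit at the planted hypermutator/baseline means (126 vs 18
non-synonymous variants), the rank-sum p-value mirrors the clear separation
between the groups, the MSI line carries under 1% aberrant genome, and the
PC1 split recovers the planted subgroups without error.

The whole chain (variants → segmentation → subtyping → in-cis → outliers →
protein → per-sample report) also runs as one call,
`run_pipeline(list(seed = 1, outdir = "out"))`, or from the shell via the
thin wrapper in `inst/cli/crcpanel.R` (subcommands `simulate`, `segment`,
`subtype`, `cis`, `outliers`, `protein`, `report`, `all`).

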