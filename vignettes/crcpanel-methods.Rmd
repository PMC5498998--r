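---
title: "Methods and design of the crcpanel integration pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the crcpanel integration pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crcpanel` re-implements, as a tested pipeline, the multi-level integration
analyses used to characterize colorectal cancer (CRC) cell-line panels:
variant-load and mutation-spectrum profiling, penalized piecewise-constant
copy-number segmentation and its summaries, bimodal expression subtyping
with single-sample gene set enrichment, in-cis copy-number/expression
association, amplification/expression-outlier nomination, and gene–protein
concordance. A synthetic panel generator with recorded ground truth is a
first-class component: every downstream stage is validated by recovering
what the generator planted.

This vignette documents the statistical models, the tunable parameters and
their defaults, the numerical choices made where the procedure description
left them open, what the generator does and does not emulate, and known
limitations.

# Models and procedures

## Variant filtering, classes and spectra

Variant calls are retained when they carry at least 10 alternative reads,
and calls flagged as known polymorphisms are discarded *unless* also flagged
as clinically associated (which rescues them). "Non-synonymous" is the
exhaustive list {non-synonymous SNV, stopgain SNV, stoploss SNV, frameshift
indel}; non-frameshift indels and splice variants do not count. Per-sample
loads can be expressed per megabase given the target-region size, which is a
required user parameter (`variant_load(target_bp = )`) because the panel's
sequenced coding size is assay-specific.

Spectra count SNVs into the 96 trinucleotide bins (six pyrimidine-reference
substitutions × 16 flanking contexts, COSMIC ordering). Contexts arrive on
the reference strand; purine-reference substitutions are reverse-complemented
into the pyrimidine convention. Collapsing is idempotent and conserves
counts; non-SNV calls are skipped and counted in an attribute.

Group load comparisons use the two-sided Wilcoxon rank-sum test, exact by
enumeration when the pooled sample size is ≤ 25 and tie-free, otherwise the
normal approximation with tie and continuity correction (`exact_max_n` is
configurable; panel-scale groups stay exact-capable). A fully tied input has
no evidence in either direction and returns p = 1. The load/CNA relationship
uses Spearman's rho with the exact null for n ≤ 9 and the t-approximation
otherwise; constant vectors are an error rather than a silent NA.

## Copy-number segmentation and summaries

For probes $y_1,\dots,y_n$ on one chromosome the segmentation minimizes

$$\sum_{\text{segments}} \sum_{i \in \text{seg}} (y_i - \bar y_{\text{seg}})^2
  \;+\; \gamma \cdot \#\{\text{breakpoints}\}$$

*exactly*, by the O(n²) dynamic program, rather than by a heuristic. The
penalty default is $\gamma = 100$, applied to data standardized by a robust
noise scale (median absolute deviation of first differences divided by
$\sqrt 2$); standardization can be disabled (`standardize = FALSE`), which
the test suite uses so an exhaustive-search oracle can check the optimum on
the raw objective. Segment boundaries tile the probed span contiguously
(internal boundaries at inter-probe midpoints; 0-based half-open
coordinates; SEG files are read/written 1-based inclusive).

Calls are inclusive: gain iff value ≥ 0.15, loss iff ≤ −0.15, with stricter
±0.3 thresholds for integration analyses and 4 × 0.15 = 0.6 defining
high-amplitude events. The aberrant-genome percentage uses segment-spanned
bases as the denominator — bases not covered by any segment are excluded;
probe-level denominators would differ only by edge effects and the
segment-spanned convention keeps the quantity a pure function of the
segmentation.

Smallest regions of overlap partition each chromosome at the union of all
samples' breakpoints; each region inherits the parent segment's value per
sample. Gene-level mapping follows three rules: a gene inside one segment
takes its value/category; a gene spanning several segments of one category
keeps the category with the median of the overlapping values (the value for
this case is not pinned down by the procedure description; the median keeps
it consistent with the mixed case, and a coverage-weighted mean is available
by flag); a gene spanning mixed categories takes the median PCF value with
the category re-derived from that median. Medians over an even number of
values are midpoints of the central pair; threshold ties resolve by the
inclusive comparisons above. A separate post-filter keeps only genes with a
value in every sample.

## Expression subtyping

The subgroup discovery chain is: keep the 1000 genes with the largest
cross-sample variance (variance was chosen as the "variation" measure; SD
and MAD are available by flag, and ties break by row order), compute PCA
scores from the SVD of the gene-centered (unscaled, by default) matrix, and
split samples at the PC1 density's between-peaks minimum. Orientation of PC1
is arbitrary in an SVD, so it is pinned: with a marker set supplied, the
samples with higher mean marker expression get *lower* PC1 ("colon-like =
low PC1"); otherwise the largest-magnitude loading is made positive.

The split fits a Gaussian kernel density with Silverman's rule-of-thumb
bandwidth (configurable). If at least two local maxima exist, the threshold
is the lowest local minimum between the two highest maxima (ties among
equally high peaks break leftmost). A finite sample from a *unimodal*
distribution frequently produces small spurious density wiggles — in
simulation, 30 unimodal PC1 scores were flagged "bimodal" in roughly 40% of
draws under a literal two-maxima rule. The split therefore accepts
bimodality only when the between-peaks minimum is genuinely depressed:
below `dip_ratio = 0.75` times the smaller peak height. With this rule,
planted two-cluster panels are detected essentially always (the dip between
well-separated modes is far deeper than 0.75) while null panels are flagged
unimodal; the ratio is a tunable argument.

ssGSEA scores rank features per sample (descending) and sum, over the ranked
list, the difference between the weighted in-set cumulative fraction and the
uniform out-set cumulative fraction, with in-set weights equal to the
rank-normalized value raised to `alpha = 0.25` (the conventional exponent of
the single-sample method; the citing description names no parameters, so it
is configurable, and `alpha = 0` gives the unweighted, rank-invariant
variant). Optional normalization divides by the score range across samples.

Differential expression uses the moderated *t*: gene-wise pooled two-group
variances are shrunk toward a scaled-inverse-chi-square prior fitted by the
standard method of moments on log variances (digamma/trigamma matching, with
a Newton inverse-trigamma), and the *t* statistic uses the augmented degrees
of freedom. The implementation is cross-checked against limma in the test
suite, and a plain Welch test is available by flag. The competitive gene set
test is a two-sided rank-sum of in-set versus out-set moderated *t*
statistics with BH across sets; it deliberately omits the
inter-gene-correlation variance-inflation adjustment of more elaborate
competitive tests and is therefore anti-conservative for strongly
co-expressed sets — it is used here for ranking, not for calibrated
inference on real data. miRNA counts are normalized to log2 counts-per-
million with a 0.5 pseudocount, with an optional cyclic-loess pass
(limma's implementation) that removes the composition bias a handful of
dominant species can induce.

## In-cis association

Over the eligible samples (by default the unique MSS lines — the test
population; the expression filters are computed over those same samples),
genes in the lower quartile of mean expression are excluded and only genes
with cross-sample IQR strictly above 0.7 are kept. A gene is testable for
gain (loss) when more than 2 eligible samples carry the gain (loss) category
at ±0.3; the two directions are computed independently, and a gene can be
tested for both. Each test compares expression in the aberrant samples
against all remaining (neutral plus opposite) samples with the two-sided
rank-sum test; BH correction is applied *within each direction's tested
family*, matching the separately reported gain and loss families. The
significance cutoff (q < 0.05) is not pinned by the procedure description
and is configurable; it is reported alongside results. Spearman flagging
(rho strictly above 0.7) is computed for all supplied genes, not only the
Wilcoxon-significant ones, so both outputs are available.

## Outlier nomination and protein corroboration

For each gene, the sample attaining the maximum (minimum) gene PCF value is
nominated as an amplification (deletion) event when (i) that value is beyond
±0.6, (ii) the *same* sample attains the expression maximum (minimum), and
(iii) the expression z-score — computed against the mean and SD across *all*
genes of that sample — is strictly outside ±3. Exact ties in either
arg-extreme are treated as non-concurrent (conservative) and logged. All
candidates passing the amplitude gate are emitted with the concurrence and
outlier gates reported individually, so either reading of the joint rule can
be audited. Protein corroboration computes the analogous within-sample
z-score across antibodies and reports the mapped antibody with the largest
|z|; unmapped genes and absent protein data stay missing rather than
failing.

## Gene–protein concordance

Each antibody forms its own pair with its cognate gene's mRNA (phospho and
total antibodies are separate pairs against the same transcript). Pairs in
the lowest quartile of cross-sample variation in either layer are flagged
and excluded from the summary; "variation" defaults to variance with an IQR
alternative. Fold-change concordance retains pairs with adjusted p below 0.1
in *either* layer and reports the squared Pearson correlation of the paired
log2 fold-changes.

# The synthetic panel generator

`generate_panel()` produces jointly consistent layers from one seed:

* **Phenotypes and loads.** Deterministic sample composition from the
  configured fractions (default 11:22:1 MSI:MSS:POLE over 34-line-like
  panels). Hypermutators draw non-synonymous counts around 126, baseline
  lines around 18 — the observed group medians used as generator knobs.
  Decoy calls (known polymorphisms, sub-threshold alternative reads) are
  added at configurable fractions so the filter rules are exercised; half
  of all SNVs are emitted on the purine strand to exercise strand
  collapsing.
* **Signatures.** Contexts are drawn directly as 96-bin labels from
  per-phenotype weights (MSI concentrated on C>T at NpCpG; a POLE-like
  column elevates C>A at TpCpT, C>T at TpCpG, T>G at TpTpT); the spectrum
  operations consume contexts, not sequence, so no reference genome is
  needed.
* **Genome and copy tracks.** A synthetic genome of 8 chromosomes × 600
  evenly spaced probes (10 kb spacing) with evenly spaced genes. Each
  sample's track is a true piecewise-constant signal plus Gaussian probe
  noise (SD 0.15). Base segmental aberrations occur with phenotype-specific
  probability (MSS ≈ 45% of segments, MSI/POLE ≈ 8%), which reproduces the
  aberrant-genome contrast (MSS tens of percent, hypermutators a few
  percent) and hence the load/CNA anti-correlation. Base magnitudes are
  drawn from U(0.15, 0.4): this calibration makes roughly a fifth of genes
  eligible per in-cis direction in 18 MSS samples, matching the reported
  eligible-gene fractions, and keeps all base events below the 0.6
  high-amplitude cutoff so that high-level events are exactly the planted
  ones.
* **Planted structure.** (i) Two expression subgroups: marker genes
  (default 300 of 5000) shifted by `cluster_effect` (default 0.6 log2 =
  2 expression-noise SDs) in colon-like samples. (ii) Dosage coupling: for
  each of 100 cis genes, 5–8 eligible samples carry a focal 25-probe
  aberration of amplitude U(1.0, 1.4) (one to two extra copies), and the
  gene's expression is `baseline + slope × true PCF + noise` with slope 1
  and noise SD 0.3. The carrier count and amplitude are the two knobs the
  procedure leaves open, and they are pinned by a feasibility calculation
  rather than taste: with 18 eligible samples the exact rank-sum p-value
  floor for k carriers is $2/\binom{18}{k}$, so BH at q < 0.05 over the
  ~1500-gene eligible family with ~100 true positives requires
  $\binom{18}{k} > 40\,m/n_{\text{true}}$, i.e. k ≥ 4, and 90% per-gene
  power at noise SD 0.3 requires an effect of ≳3 SDs, i.e. amplitude ≥ 1.
  (iii) Outlier events: high-amplitude (1.2) focal events whose gene is
  additionally forced to a 6-within-sample-SD expression outlier in the
  carrier line. (iv) Protein: each antibody's profile is the target-rho
  mixture $\rho z_{\text{mRNA}} + \sqrt{1-\rho^2}\,\varepsilon$, scaled and
  median-centered, which hits the configured correlation exactly in
  expectation.
* **miRNA.** Negative-binomial counts (configurable dispersion) with
  log-normal baseline abundances, balanced up/down subgroup effects and
  sample-specific library sizes.

Everything planted is recorded in `panel$truth` and immutable afterwards.

## What the generator does not emulate

No linkage to a real reference genome (interval algebra is all the analyses
consume); no sequencing reads, array intensities or RPPA images; no
gene–gene co-expression structure beyond the planted subgroup shift (so the
competitive gene set test's anti-conservatism under correlation is *not*
probed by these panels); no GC waves or segmentation artifacts; Gaussian,
homoscedastic expression noise rather than the heavier-tailed
mean-dependent noise of real arrays. Consequently, passing the planted-truth
checks demonstrates correctness of the statistical machinery and the
integration rules under the stated models — it does not certify performance
on real data, where the expression filters (lower-quartile mean, IQR > 0.7)
in particular act on a much more heterogeneous variance landscape.

# Numerical choices and degenerate inputs

* DP penalty standardization: MAD of first differences over $\sqrt2$; a
  zero noise estimate (constant or noise-free tracks) falls back to the raw
  penalty.
* `min_probes` in the DP restricts candidate segment lengths; when a prefix
  is shorter than the minimum, a single short segment is allowed rather than
  failing.
* Non-finite probe values are dropped with a message; unordered probes are
  an error.
* Rank-test edge cases: all-tied inputs return p = 1; ties disable the exact
  enumeration and switch to the corrected normal approximation.
* Constant features in differential expression get log2FC 0 and p = 1 (the
  shrunk variance is positive); `prior_df = Inf` forces every moderated
  variance to the prior, which the tests use as the shrinkage-limit check.
* Zero within-sample SD makes expression z-scores an error (a degenerate
  matrix), while constant *copy-number* vectors in the Spearman step are
  logged and flagged FALSE — the first is a data pathology, the second a
  legitimate outcome of thresholded segmentation.
* The bimodality dip rule (`dip_ratio = 0.75`) is the one deliberate
  addition to the split procedure; see above for its motivation and effect.

# Problem sizes used by the checks

The planted-truth checks run at the study's scale: 50-seed batches of
30-sample × 5000-gene panels for subgroup recovery; one 28-sample panel
(18 eligible MSS lines) with 100 planted dosage genes among 2000 nulls plus
10 expression-permutation nulls for the in-cis checks; 50 noise-only and 50
planted-event panels (20 samples × 2000 genes) for outlier nomination;
10,000 context draws for spectrum recovery; 50 seeds of 30-sample panels
with correlation families {0.2, 0.6, 0.9} for the protein checks. The
segmentation and SRO oracles run exhaustive enumeration on tracks of up to
12 probes, where brute force over all $2^{11}$ breakpoint sets is exact and
fast. The in-cis recovery is measured on eligibility alone (without the
mean/IQR expression prefilter): under the stated homogeneous noise SD of
0.3, the IQR filter — calibrated for real arrays — would remove planted and
null genes alike, and the filter has its own dedicated tests.

The spectrum check compares every bin with its weight in binomial-SD units.
Across 96 bins a correctly functioning multinomial sampler still exceeds
3 SDs somewhere in roughly a quarter of runs, so the joint criterion allows
up to two 3-SD exceedances while bounding all bins at 4 SDs; the raw maximum
|z| is reported alongside.

# Limitations

* The competitive gene set test is anti-conservative under inter-gene
  correlation (no variance-inflation adjustment); interpret its p-values as
  rankings on real data.
* The in-cis Wilcoxon verdicts depend on the BH family (per direction, over
  the eligible genes); changing the eligibility rule changes q-values.
* GISTIC-style significance of focal peaks, allele-specific copy number,
  ploidy estimation, signature deconvolution against catalogue signatures,
  and consensus-molecular-subtype classification are out of scope.
* The pipeline's per-sample report standardizes ssGSEA scores across the
  panel at hand; scores are therefore relative to the panel, not absolute.
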