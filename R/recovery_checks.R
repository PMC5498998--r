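#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(as.numeric(sij == mx))
  (sij - expected) / (mx - expected)
}

#' Subgroup-recovery benchmark on planted two-cluster panels
#'
#' For each seed, generates a panel under the default study conditions
#' (30 samples, 5000 genes, 300 marker genes shifted 2 noise-SD), runs the
#' subtype pipeline (top-1000 variable genes, PCA, between-peaks-minima
#' split) and scores the recovered labels against the planted subgroups; the
#' marker-set ssGSEA score is correlated with PC1.
#'
#' @param seeds Integer vector of panel seeds.
#' @param config_fn Function mapping a seed to a [panel_config()] (defaults
#'   to the study conditions).
#' @return List with `ari` and `r_squared` per seed, `ari_perfect_rate` and
#'   `r2_median`.
#' @export
recovery_subtype <- function(seeds,
                             config_fn = function(s) panel_config(seed = s)) {
  ari <- r2 <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    p <- generate_panel(config_fn(seeds[i]))
    top <- select_variable_genes(p$expression, min(1000, nrow(p$expression)))
    pc <- pca_scores(top, marker_set = p$truth$marker_genes)
    pc1 <- stats::setNames(pc$scores[, 1L], rownames(pc$scores))
    sp <- bimodal_split(pc1)
    ari[i] <- if (isTRUE(attr(sp, "bimodality_ok")))
      adjusted_rand_index(sp$label, p$truth$subgroup[sp$sample_id]) else 0
    ss <- ssgsea_score(p$expression, p$truth$marker_genes)
    r2[i] <- stats::cor(ss, pc1)^2
  }
  list(ari = ari, r_squared = r2,
       ari_perfect_rate = mean(ari >= 1 - 1e-12),
       r2_median = stats::median(r2))
}

#' In-cis recovery benchmark with planted dosage genes
#'
#' Generates a panel with 100 planted dosage-coupled genes (slope 1 log2 per
#' PCF unit, expression noise SD 0.3) among 2000 null genes and 18 eligible
#' MSS samples, segments the eligible samples' probe tracks with the default
#' penalty, maps segments to genes at the strict cis thresholds and runs the
#' Wilcoxon in-cis tests. Sensitivity counts planted genes recovered in
#' their planted direction; the empirical FDR counts flagged gene/direction
#' pairs whose gene carries no planted dosage coupling. Label permutations of
#' the expression columns provide a null calibration.
#'
#' @param seed Panel seed.
#' @param n_permutations Number of expression-column permutations for the
#'   null associated fraction.
#' @return List with `sensitivity`, `fdr`, `null_fractions`,
#'   `n_tested` and the `cis_result` table.
#' @export
recovery_cis <- function(seed, n_permutations = 10) {
  cfg <- panel_config(n_samples = 28, n_genes = 2100, n_cis_genes = 100,
                      marker_set_size = 300, seed = seed)
  p <- generate_panel(cfg)
  mss <- p$annotations$sample_id[p$annotations$phenotype == "MSS"]
  segs <- do.call(rbind, lapply(mss, function(s)
    pcf_segment(data.frame(p$probes, value = p$probe_values[, s]),
                gamma = 100, sample_id = s)))
  class(segs) <- c("copy_segments", class(segs))
  gct <- filter_genes_all_samples(
    map_genes(segs, p$gene_model, use_cis = TRUE))
  ccfg <- cis_config(eligible_samples = mss)
  res <- suppressMessages(test_cis(p$expression, gct, ccfg))
  planted_dir <- vapply(split(p$truth$cis_events$amplitude,
                              p$truth$cis_events$gene),
                        function(a) if (a[1L] > 0) "gain" else "loss", "")
  assoc <- res[res$wilcoxon_associated, , drop = FALSE]
  hit <- vapply(names(planted_dir), function(g)
    any(assoc$gene == g & assoc$direction == planted_dir[g]), logical(1))
  fdr <- if (nrow(assoc)) mean(!assoc$gene %in% p$truth$cis_genes) else 0
  null_fr <- vapply(seq_len(n_permutations), function(k) {
    xp <- p$expression[, sample(colnames(p$expression))]
    colnames(xp) <- colnames(p$expression)
    rp <- suppressMessages(test_cis(xp, gct, ccfg))
    if (nrow(rp)) mean(rp$wilcoxon_associated) else 0
  }, numeric(1))
  list(sensitivity = mean(hit), fdr = fdr, null_fractions = null_fr,
       n_tested = nrow(res), result = res)
}

#' Outlier-nomination benchmark on planted and noise-only panels
#'
#' For each seed, builds one noise-only panel (no planted events) and one
#' panel with three planted high-amplitude amplification events (PCF 1.2,
#' expression shift 6 within-sample SDs), maps the true segments to genes and
#' runs the concurrence nomination at default thresholds.
#'
#' @param seeds Integer vector of panel seeds.
#' @return List with `sensitivity` (fraction of planted events nominated,
#'   pooled over seeds), `clean_rate` (fraction of noise-only panels with
#'   zero nominations) and per-seed counts.
#' @export
recovery_outliers <- function(seeds) {
  base <- function(s, events) panel_config(
    n_samples = 20, n_genes = 2000, n_cis_genes = 0, cluster_effect = 0,
    n_outlier_events = events, n_chrom = 6, probes_per_chrom = 300,
    seed = s)
  n_false <- integer(length(seeds))
  n_planted <- n_found <- integer(length(seeds))
  for (i in seq_along(seeds)) {
    pn <- generate_panel(base(seeds[i], 0))
    gct <- filter_genes_all_samples(map_genes(pn$truth$true_segments,
                                              pn$gene_model))
    ev <- suppressMessages(nominate_concurrent(gct, pn$expression))
    n_false[i] <- sum(ev$nominated)

    pp <- generate_panel(base(seeds[i] + 10000L, 3))
    gct2 <- filter_genes_all_samples(map_genes(pp$truth$true_segments,
                                               pp$gene_model))
    ev2 <- suppressMessages(nominate_concurrent(gct2, pp$expression))
    tr <- pp$truth$outlier_events
    n_planted[i] <- nrow(tr)
    n_found[i] <- sum(vapply(seq_len(nrow(tr)), function(j)
      any(ev2$nominated & ev2$gene == tr$gene[j] &
            ev2$sample == tr$sample[j]), logical(1)))
  }
  list(sensitivity = sum(n_found) / sum(n_planted),
       clean_rate = mean(n_false == 0),
       n_false = n_false, n_found = n_found, n_planted = n_planted)
}

#' Mutation-spectrum and load-contrast benchmark
#'
#' Draws `n_draws` trinucleotide contexts from the configured signature
#' weights through the variant generator's representation (half emitted on
#' the purine strand), rebuilds the 96-bin spectrum and compares every bin
#' with its weight in binomial-SD units. Separately, generates a 10
#' hypermutator versus 20 baseline panel (loads 126 vs 18) and runs the
#' rank-sum load comparison and the load/CNA Spearman anti-correlation.
#'
#' @param seed RNG seed.
#' @param n_draws Number of context draws.
#' @param phenotype Signature column to draw from.
#' @return List with `max_abs_z`, `n_beyond_3sd`, `load_p`, `rho`.
#' @export
recovery_spectrum_loads <- function(seed, n_draws = 10000,
                                    phenotype = "MSI") {
  set.seed(seed)
  w <- default_signature_weights()[, phenotype]
  bins <- names(w)
  b <- sample(bins, n_draws, replace = TRUE, prob = w)
  ref <- substr(b, 3, 3); alt <- substr(b, 5, 5)
  ctx <- paste0(substr(b, 1, 1), ref, substr(b, 7, 7))
  flip <- stats::runif(n_draws) < 0.5
  ref[flip] <- chartr("CT", "GA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  sp <- mutation_spectrum(data.frame(ref = ref, alt = alt, context = ctx,
                                     stringsAsFactors = FALSE))
  z <- (sp$proportion - w) / sqrt(w * (1 - w) / n_draws)

  cfg <- panel_config(n_samples = 30,
                      phenotype_fractions = c(MSI = 1/3, MSS = 2/3, POLE = 0),
                      seed = seed)
  p <- generate_panel(cfg)
  kept <- filter_variants(p$variants)
  lo <- variant_load(kept, samples = p$annotations$sample_id)
  hyper <- p$annotations$phenotype == "MSI"
  test <- compare_loads(lo$n_nonsynonymous[hyper], lo$n_nonsynonymous[!hyper])
  pct <- genome_fraction_aberrant(p$truth$true_segments)
  rho <- load_cna_anticorrelation(
    stats::setNames(lo$n_nonsynonymous, lo$sample_id), pct)
  list(max_abs_z = max(abs(z)), n_beyond_3sd = sum(abs(z) >= 3),
       load_p = test$p.value, rho = rho$rho,
       load_medians = c(hyper = stats::median(lo$n_nonsynonymous[hyper]),
                        baseline = stats::median(lo$n_nonsynonymous[!hyper])))
}

#' Gene-protein correlation recovery benchmark
#'
#' For each seed, generates a 30-sample panel whose antibodies are split into
#' three families with target mRNA-protein correlations 0.2, 0.6 and 0.9,
#' computes all pair correlations and summarizes each family's median.
#'
#' @param seeds Integer vector of panel seeds.
#' @return List with `medians` (per family, median over seeds) and the
#'   per-seed family medians.
#' @export
recovery_protein <- function(seeds) {
  rho_families <- c(0.2, 0.6, 0.9)
  per_seed <- sapply(seeds, function(s) {
    p <- generate_panel(panel_config(
      n_samples = 30, n_genes = 1000, n_proteins = 150,
      protein_rho = rep(rho_families, each = 50),
      n_cis_genes = 0, n_outlier_events = 0,
      n_chrom = 4, probes_per_chrom = 100, seed = s))
    pc <- pair_and_correlate(p$expression, p$protein, p$antibody_map)
    rho <- p$truth$protein_rho[pc$pairs$antibody]
    vapply(split(pc$pairs$pearson_r, rho), stats::median, numeric(1))
  })
  list(medians = apply(per_seed, 1, stats::median), per_seed = per_seed)
}
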