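#' Default per-phenotype trinucleotide signature weights
#'
#' Three phenotype columns over the 96 pyrimidine-reference bins:
#' * `MSI`: mismatch-repair-deficiency-like, dominated by C>T at NpCpG;
#' * `MSS`: mostly flat background with a mild C>T-at-CpG component;
#' * `POLE`: polymerase-epsilon-like, elevated C>A at TpCpT, C>T at TpCpG
#'   and T>G at TpTpT.
#'
#' @return 96 x 3 matrix of probabilities; columns sum to 1.
#' @export
default_signature_weights <- function() {
  bins <- spectrum_bins()
  w <- matrix(0, length(bins), 3, dimnames = list(bins, c("MSI", "MSS", "POLE")))
  ncg <- paste0(c("A", "C", "G", "T"), "[C>T]G")
  w[, "MSI"] <- 0.30 / (96 - 4)
  w[ncg, "MSI"] <- 0.70 / 4
  w[, "MSS"] <- 0.80 / (96 - 4)
  w[ncg, "MSS"] <- 0.20 / 4
  pole <- c("T[C>A]T", "T[C>T]G", "T[T>G]T")
  w[, "POLE"] <- 0.35 / (96 - 3)
  w[pole, "POLE"] <- c(0.25, 0.20, 0.20)
  w
}

#' Synthetic panel configuration
#'
#' Defines the study conditions the generator emulates: sample composition,
#' hypermutator versus baseline variant loads, per-phenotype mutation
#' signatures and copy-number segment models, the two-cluster expression
#' structure, planted gene-dosage coupling, high-amplitude outlier events and
#' mRNA-protein correlation. Defaults mirror the cell-line panel the method
#' was developed on (median 126 non-synonymous variants in hypermutators vs
#' 18 in MSS lines; low CNA burden in MSI, high in MSS).
#'
#' @param n_samples Number of cell lines.
#' @param phenotype_fractions Named proportions over `MSI`, `MSS`, `POLE`
#'   (must sum to 1).
#' @param n_genes,n_mirnas,n_proteins Feature counts per layer.
#' @param hypermutator_load,baseline_load Mean non-synonymous variant counts.
#' @param signature_weights 96 x phenotype matrix of context probabilities.
#' @param polymorphism_fraction Fraction of emitted calls flagged as known
#'   polymorphisms (decoys exercising the filter).
#' @param subthreshold_fraction Fraction of emitted calls with fewer than 10
#'   alternative reads.
#' @param clinical_fraction Fraction of retained calls flagged as both known
#'   polymorphism and clinically associated (these survive filtering).
#' @param synonymous_rate Synonymous calls per non-synonymous call.
#' @param segment_model Per-phenotype list with `mean_segments` (per
#'   chromosome), `p_aberrant` and `mag_range` (absolute PCF magnitudes of
#'   base segmental aberrations; kept below the high-amplitude cutoff so
#'   that high-level events are only the explicitly planted ones).
#' @param n_chrom,probes_per_chrom,probe_spacing,gene_length Synthetic genome
#'   model (evenly spaced probes, evenly spaced genes).
#' @param cluster_effect Log2 shift applied to marker genes in the
#'   colon-like subgroup (2 standard deviations of the expression noise by
#'   default).
#' @param marker_set_size Number of marker genes.
#' @param colon_like_fraction Fraction of samples in the colon-like subgroup.
#' @param dosage_slope Log2 expression units per PCF unit for planted cis
#'   genes.
#' @param n_cis_genes Number of planted dosage-coupled genes.
#' @param cis_amplitude_range Absolute PCF amplitude range of planted cis
#'   aberrations.
#' @param cis_span_probes Probe span of a planted cis aberration.
#' @param cis_samples_range Range of the number of (MSS) samples carrying
#'   each planted cis aberration.
#' @param cis_gain_fraction Fraction of planted cis genes that are gains
#'   (the rest are losses).
#' @param n_outlier_events Number of auto-placed amplification/outlier
#'   events (ignored when `outlier_events` is supplied).
#' @param outlier_amplitude,outlier_shift PCF amplitude and expression shift
#'   (in within-sample standard deviations) of auto-placed events.
#' @param outlier_events Optional data frame `gene`, `sample`, `amplitude`,
#'   `shift` fixing the events explicitly.
#' @param protein_rho Target mRNA-protein correlation(s), recycled over
#'   antibodies.
#' @param noise_sd Named list with per-layer noise standard deviations:
#'   `expression`, `protein`, `probe` (log2 scale).
#' @param mirna Named list with `log_mean`, `log_sd`, `dispersion`,
#'   `n_de`, `log2fc`, `lib_range` for the negative-binomial miRNA layer.
#' @param seed Integer seed; fully determines the panel.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_samples = 30,
                         phenotype_fractions = c(MSI = 11/34, MSS = 22/34,
                                                 POLE = 1/34),
                         n_genes = 5000, n_mirnas = 400, n_proteins = 150,
                         hypermutator_load = 126, baseline_load = 18,
                         signature_weights = default_signature_weights(),
                         polymorphism_fraction = 0.15,
                         subthreshold_fraction = 0.10,
                         clinical_fraction = 0.05,
                         synonymous_rate = 0.25,
                         segment_model = list(
                           MSI = list(mean_segments = 3, p_aberrant = 0.08,
                                      mag_range = c(0.15, 0.4)),
                           MSS = list(mean_segments = 8, p_aberrant = 0.45,
                                      mag_range = c(0.15, 0.4)),
                           POLE = list(mean_segments = 3, p_aberrant = 0.08,
                                       mag_range = c(0.15, 0.4))),
                         n_chrom = 8, probes_per_chrom = 600,
                         probe_spacing = 10000, gene_length = 2500,
                         cluster_effect = 0.6, marker_set_size = 300,
                         colon_like_fraction = 18/33,
                         dosage_slope = 1.0, n_cis_genes = 100,
                         cis_amplitude_range = c(1.0, 1.4),
                         cis_span_probes = 25,
                         cis_samples_range = c(5, 8),
                         cis_gain_fraction = 0.7,
                         n_outlier_events = 3,
                         outlier_amplitude = 1.2, outlier_shift = 6,
                         outlier_events = NULL,
                         protein_rho = 0.6,
                         noise_sd = list(expression = 0.3, protein = 0.5,
                                         probe = 0.15),
                         mirna = list(log_mean = log(500), log_sd = 1,
                                      dispersion = 0.2, n_de = 30,
                                      log2fc = 1, lib_range = c(0.5, 2)),
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "panel_config"
  validate_panel_config(cfg)
  cfg
}

validate_panel_config <- function(cfg) {
  chk <- function(ok, field, what)
    if (!ok) stop("panel_config: invalid '", field, "': ", what, call. = FALSE)
  chk(cfg$n_samples >= 2, "n_samples", "need at least 2 samples")
  chk(abs(sum(cfg$phenotype_fractions) - 1) < 1e-8, "phenotype_fractions",
      "must sum to 1")
  chk(all(cfg$phenotype_fractions >= 0), "phenotype_fractions",
      "must be non-negative")
  chk(all(sort(names(cfg$phenotype_fractions)) == sort(colnames(cfg$signature_weights))),
      "signature_weights", "columns must match phenotype names")
  chk(all(abs(colSums(cfg$signature_weights) - 1) < 1e-8), "signature_weights",
      "each phenotype's weights must sum to 1")
  for (f in c("n_genes", "n_mirnas", "n_proteins", "n_chrom",
              "probes_per_chrom"))
    chk(cfg[[f]] > 0, f, "must be positive")
  chk(cfg$hypermutator_load >= 0 && cfg$baseline_load >= 0,
      "hypermutator_load/baseline_load", "must be non-negative")
  chk(all(unlist(cfg$noise_sd) >= 0), "noise_sd", "must be non-negative")
  chk(cfg$marker_set_size + cfg$n_cis_genes < cfg$n_genes, "marker_set_size",
      "marker and cis genes must leave spare genes")
  chk(cfg$cluster_effect >= 0, "cluster_effect", "must be non-negative")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed",
      "must be a single finite number")
  invisible(cfg)
}

## deterministic group sizes from fractions (largest remainder)
fraction_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

synth_genome <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  pos <- as.integer((seq_len(cfg$probes_per_chrom) - 1L) * cfg$probe_spacing)
  probes <- data.frame(chrom = rep(chroms, each = cfg$probes_per_chrom),
                       pos = rep(pos, cfg$n_chrom), stringsAsFactors = FALSE)
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  span <- (cfg$probes_per_chrom - 1L) * cfg$probe_spacing - cfg$gene_length
  pitch <- max(1L, span %/% per_chrom)
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    k <- min(per_chrom, cfg$n_genes - (ci - 1L) * per_chrom)
    if (k <= 0) return(NULL)
    start <- as.integer((seq_len(k) - 1L) * pitch)
    data.frame(gene = sprintf("G%05d", (ci - 1L) * per_chrom + seq_len(k)),
               chrom = chroms[ci], start = start,
               end = start + as.integer(cfg$gene_length),
               stringsAsFactors = FALSE)
  }))
  list(probes = probes, genes = genes)
}

## pick k genes pairwise separated by >= min_sep bases (same chromosome),
## also avoiding the neighbourhoods of already-taken genes
pick_separated_genes <- function(genes, k, min_sep, avoid = character(0)) {
  mid <- (genes$start + genes$end) / 2
  taken_mid <- mid[genes$gene %in% avoid]
  taken_chr <- genes$chrom[genes$gene %in% avoid]
  cand <- sample(seq_len(nrow(genes)))
  chosen <- integer(0)
  for (i in cand) {
    if (genes$gene[i] %in% avoid) next
    same <- c(taken_mid[taken_chr == genes$chrom[i]],
              mid[chosen][genes$chrom[chosen] == genes$chrom[i]])
    if (!length(same) || min(abs(same - mid[i])) >= min_sep) {
      chosen <- c(chosen, i)
      if (length(chosen) == k) break
    }
  }
  if (length(chosen) < k)
    stop("synth_panel: genome too small to place ", k,
         " planted genes at separation ", min_sep)
  genes$gene[chosen]
}

parse_bin <- function(bin) {
  data.frame(ref = substr(bin, 3, 3), alt = substr(bin, 5, 5),
             context = paste0(substr(bin, 1, 1), substr(bin, 3, 3),
                              substr(bin, 7, 7)),
             stringsAsFactors = FALSE)
}

#' Generate variant calls for an annotated sample set
#'
#' Draws per-sample non-synonymous variant counts around the phenotype's
#' load, trinucleotide contexts from the phenotype's signature weights, and
#' adds synonymous calls plus decoy calls (known polymorphisms and
#' sub-threshold alternative-read calls) so the filtering rules are
#' exercised. Half of the SNVs are emitted on the purine strand to exercise
#' strand collapsing. Operates on the current RNG state.
#'
#' @param annotations Data frame with `sample_id` and `phenotype`.
#' @param config A [panel_config()].
#' @param gene_model Optional gene model (generated from the config when
#'   omitted).
#' @return Data frame of variant calls.
#' @export
generate_variants <- function(annotations, config, gene_model = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("sample_id", "phenotype") %in% names(annotations)))
  w <- config$signature_weights
  if (any(abs(colSums(w) - 1) > 1e-8))
    stop("generate_variants: signature weights must sum to 1")
  if (is.null(gene_model)) gene_model <- synth_genome(config)$genes
  bins <- rownames(w)
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    s <- annotations$sample_id[i]
    ph <- annotations$phenotype[i]
    load <- if (ph %in% c("MSI", "POLE")) config$hypermutator_load else
      config$baseline_load
    n_ns <- stats::rpois(1, load)
    n_syn <- stats::rpois(1, config$synonymous_rate * load)
    lam_keep <- n_ns + n_syn
    n_poly <- stats::rpois(1, config$polymorphism_fraction /
                             (1 - config$polymorphism_fraction) * lam_keep)
    n_sub <- stats::rpois(1, config$subthreshold_fraction /
                            (1 - config$subthreshold_fraction) * lam_keep)
    n_tot <- n_ns + n_syn + n_poly + n_sub
    if (n_tot == 0) next
    cls <- c(sample(c("nonsynonymous_SNV", "stopgain_SNV", "stoploss_SNV",
                      "frameshift_indel"), n_ns, replace = TRUE,
                    prob = c(0.75, 0.10, 0.02, 0.13)),
             rep("synonymous_SNV", n_syn),
             sample(c("nonsynonymous_SNV", "synonymous_SNV"), n_poly + n_sub,
                    replace = TRUE))
    known <- c(stats::runif(n_ns + n_syn) < config$clinical_fraction,
               rep(TRUE, n_poly), rep(FALSE, n_sub))
    clinical <- known & c(rep(TRUE, n_ns + n_syn), rep(FALSE, n_poly + n_sub))
    alt_reads <- c(10L + stats::rpois(n_ns + n_syn + n_poly, 40),
                   if (n_sub > 0) sample(1:9, n_sub, replace = TRUE))
    gi <- sample(nrow(gene_model), n_tot, replace = TRUE)
    is_snv <- cls != "frameshift_indel"
    ref <- alt <- context <- rep(NA_character_, n_tot)
    if (any(is_snv)) {
      b <- parse_bin(sample(bins, sum(is_snv), replace = TRUE, prob = w[, ph]))
      flip <- stats::runif(sum(is_snv)) < 0.5
      b$ref[flip] <- chartr("CT", "GA", b$ref[flip])
      b$alt[flip] <- chartr("ACGT", "TGCA", b$alt[flip])
      b$context[flip] <- revcomp(b$context[flip])
      ref[is_snv] <- b$ref; alt[is_snv] <- b$alt; context[is_snv] <- b$context
    }
    if (any(!is_snv)) {
      ins <- stats::runif(sum(!is_snv)) < 0.5
      ref[!is_snv] <- ifelse(ins, "A", "AT")
      alt[!is_snv] <- ifelse(ins, "AT", "A")
    }
    out[[s]] <- data.frame(
      sample_id = s, gene = gene_model$gene[gi], chrom = gene_model$chrom[gi],
      pos = gene_model$start[gi] +
        sample.int(config$gene_length, n_tot, replace = TRUE),
      ref = ref, alt = alt, variant_class = cls, alt_read_count = alt_reads,
      known_polymorphism = known, clinically_associated = clinical,
      context = context, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), gene = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), variant_class = character(),
               alt_read_count = integer(), known_polymorphism = logical(),
               clinically_associated = logical(), context = character())
  rownames(res) <- NULL
  res
}

#' Generate probe-level copy-number tracks with recorded truth
#'
#' Builds, per sample and chromosome, a true piecewise-constant signal
#' (phenotype-specific segment counts, aberration probabilities and
#' magnitudes), overlays the planted cis-gene aberrations and high-amplitude
#' outlier events, and adds Gaussian probe noise. Operates on the current
#' RNG state.
#'
#' @param annotations Data frame with `sample_id` and `phenotype`.
#' @param config A [panel_config()].
#' @return List with `probes` (chrom/pos), `values` (probes x samples
#'   observed matrix), `true_values` (noise-free matrix), `true_segments`
#'   (a `copy_segments` data frame), `gene_model`, `gene_pcf_true`
#'   (genes x samples), `cis_genes`, `cis_events` and `outlier_events`.
#' @export
generate_copy_tracks <- function(annotations, config) {
  if (any(unlist(config$noise_sd) < 0))
    stop("generate_copy_tracks: noise SD must be non-negative")
  genome <- synth_genome(config)
  probes <- genome$probes
  genes <- genome$genes
  samples <- annotations$sample_id
  np <- nrow(probes)
  true_v <- matrix(0, np, length(samples), dimnames = list(NULL, samples))
  chroms <- unique(probes$chrom)
  ppc <- config$probes_per_chrom
  for (i in seq_along(samples)) {
    sm <- config$segment_model[[annotations$phenotype[i]]]
    for (ci in seq_along(chroms)) {
      k <- 1L + stats::rpois(1, sm$mean_segments)
      cuts <- if (k > 1L) sort(sample(ppc - 1L, min(k - 1L, ppc - 1L))) else integer(0)
      starts <- c(1L, cuts + 1L); ends <- c(cuts, ppc)
      vals <- ifelse(stats::runif(length(starts)) < sm$p_aberrant,
                     sample(c(-1, 1), length(starts), replace = TRUE) *
                       stats::runif(length(starts), sm$mag_range[1L],
                                    sm$mag_range[2L]),
                     0)
      off <- (ci - 1L) * ppc
      true_v[off + unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE)), i] <-
        rep(vals, ends - starts + 1L)
    }
  }
  mid <- (genes$start + genes$end) / 2
  plant <- function(gene, sample, amplitude) {
    gi <- match(gene, genes$gene)
    ci <- match(genes$chrom[gi], chroms)
    center <- round(mid[gi] / config$probe_spacing) + 1L
    half <- config$cis_span_probes %/% 2L
    idx <- max(1L, center - half):min(ppc, center + half)
    true_v[(ci - 1L) * ppc + idx, sample] <<- amplitude
  }
  ## planted dosage-coupled genes (in MSS samples, the eligible pool)
  min_sep <- (config$cis_span_probes + 2L) * config$probe_spacing
  cis_genes <- character(0); cis_events <- NULL
  pool <- samples[annotations$phenotype == "MSS"]
  if (!length(pool)) pool <- samples
  if (config$n_cis_genes > 0) {
    cis_genes <- pick_separated_genes(genes, config$n_cis_genes, min_sep)
    cis_dir <- ifelse(stats::runif(length(cis_genes)) < config$cis_gain_fraction,
                      1, -1)
    ev <- list()
    for (j in seq_along(cis_genes)) {
      k <- sample(seq(config$cis_samples_range[1L], config$cis_samples_range[2L]), 1)
      carriers <- sample(pool, min(k, length(pool)))
      amp <- cis_dir[j] * stats::runif(length(carriers),
                                       config$cis_amplitude_range[1L],
                                       config$cis_amplitude_range[2L])
      for (m in seq_along(carriers)) plant(cis_genes[j], carriers[m], amp[m])
      ev[[j]] <- data.frame(gene = cis_genes[j], sample = carriers,
                            amplitude = amp, stringsAsFactors = FALSE)
    }
    cis_events <- do.call(rbind, ev)
  }
  ## planted high-amplitude outlier events
  outlier_events <- config$outlier_events
  if (is.null(outlier_events) && config$n_outlier_events > 0) {
    og <- pick_separated_genes(genes, config$n_outlier_events, min_sep,
                               avoid = cis_genes)
    outlier_events <- data.frame(
      gene = og, sample = sample(pool, config$n_outlier_events, replace = TRUE),
      amplitude = config$outlier_amplitude, shift = config$outlier_shift,
      stringsAsFactors = FALSE)
  }
  if (!is.null(outlier_events))
    for (j in seq_len(nrow(outlier_events)))
      plant(outlier_events$gene[j], outlier_events$sample[j],
            outlier_events$amplitude[j])
  values <- true_v + stats::rnorm(length(true_v), 0, config$noise_sd$probe)
  dimnames(values) <- dimnames(true_v)
  ## record true segments from runs of the noise-free signal
  segs <- list()
  for (i in seq_along(samples)) {
    for (ci in seq_along(chroms)) {
      idx <- (ci - 1L) * ppc + seq_len(ppc)
      r <- rle(true_v[idx, i])
      ends_i <- cumsum(r$lengths)
      starts_i <- c(1L, ends_i[-length(ends_i)] + 1L)
      pos <- probes$pos[idx]
      bounds <- c(pos[1L],
                  if (length(starts_i) > 1L)
                    (pos[starts_i[-1L] - 1L] + pos[starts_i[-1L]]) %/% 2 + 1L,
                  pos[ppc] + 1L)
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = samples[i], chrom = chroms[ci],
        start = bounds[-length(bounds)], end = bounds[-1L],
        n_probes = r$lengths, pcf_value = r$values, stringsAsFactors = FALSE)
    }
  }
  true_segments <- do.call(rbind, segs)
  rownames(true_segments) <- NULL
  class(true_segments) <- c("copy_segments", class(true_segments))
  ## true gene value = true signal at the probe nearest the gene midpoint
  probe_idx <- (match(genes$chrom, chroms) - 1L) * ppc +
    pmin(ppc, round(mid / config$probe_spacing) + 1L)
  gene_pcf_true <- true_v[probe_idx, , drop = FALSE]
  rownames(gene_pcf_true) <- genes$gene
  list(probes = probes, values = values, true_values = true_v,
       true_segments = true_segments, gene_model = genes,
       gene_pcf_true = gene_pcf_true, cis_genes = cis_genes,
       cis_events = cis_events, outlier_events = outlier_events)
}

#' Generate a complete synthetic cell-line panel with recorded ground truth
#'
#' Produces jointly consistent variant calls, probe-level copy-number tracks,
#' mRNA/miRNA/protein matrices, an antibody map and gene sets, together with
#' a `truth` record of everything planted. The seed in the configuration
#' fully determines the output.
#'
#' @param config A [panel_config()].
#' @return An object of class `synthetic_panel`.
#' @export
generate_panel <- function(config = panel_config()) {
  validate_panel_config(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  counts <- fraction_counts(config$phenotype_fractions, config$n_samples)
  annotations <- data.frame(
    sample_id = sprintf("CL%02d", seq_len(config$n_samples)),
    phenotype = rep(names(counts), counts), stringsAsFactors = FALSE)
  n_colon <- max(1L, round(config$colon_like_fraction * config$n_samples))
  annotations$subgroup <- "undifferentiated"
  annotations$subgroup[sample(config$n_samples, n_colon)] <- "colon_like"

  tracks <- generate_copy_tracks(annotations, config)
  genes <- tracks$gene_model
  variants <- generate_variants(annotations, config, gene_model = genes)

  ## expression: baseline + subgroup marker shift + dosage + outliers + noise
  planted <- c(tracks$cis_genes,
               if (!is.null(tracks$outlier_events)) tracks$outlier_events$gene)
  markers <- sample(setdiff(genes$gene, planted), config$marker_set_size)
  baseline <- stats::rnorm(nrow(genes), 7, 1.5)
  names(baseline) <- genes$gene
  expr <- matrix(baseline, nrow(genes), config$n_samples) +
    stats::rnorm(nrow(genes) * config$n_samples, 0, config$noise_sd$expression)
  dimnames(expr) <- list(genes$gene, annotations$sample_id)
  colon <- annotations$subgroup == "colon_like"
  expr[markers, colon] <- expr[markers, colon] + config$cluster_effect
  if (length(tracks$cis_genes))
    expr[tracks$cis_genes, ] <- expr[tracks$cis_genes, ] +
      config$dosage_slope * tracks$gene_pcf_true[tracks$cis_genes, ]
  if (!is.null(tracks$outlier_events)) {
    for (j in seq_len(nrow(tracks$outlier_events))) {
      ev <- tracks$outlier_events[j, ]
      s <- ev$sample
      shift <- if (ev$amplitude >= 0) ev$shift else -ev$shift
      expr[ev$gene, s] <- mean(expr[, s]) + shift * stats::sd(expr[, s])
    }
  }

  ## miRNA: negative-binomial counts with library-size variation
  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirnas))
  log_mu <- stats::rnorm(config$n_mirnas, config$mirna$log_mean,
                         config$mirna$log_sd)
  lfc <- numeric(config$n_mirnas)
  n_de <- min(config$mirna$n_de, config$n_mirnas)
  if (n_de > 0)
    lfc[seq_len(n_de)] <- config$mirna$log2fc *
      rep_len(c(1, -1), n_de)
  lib <- stats::runif(config$n_samples, config$mirna$lib_range[1L],
                      config$mirna$lib_range[2L])
  mu <- exp(log_mu) %o% lib * 2^(lfc %o% as.numeric(colon))
  mirna <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$mirna$dispersion),
                  config$n_mirnas, config$n_samples,
                  dimnames = list(mirna_ids, annotations$sample_id))

  ## protein: linear transform of cognate mRNA calibrated to the target rho
  out_genes <- if (!is.null(tracks$outlier_events))
    unique(tracks$outlier_events$gene) else character(0)
  n_marker_ab <- min(40L, config$n_proteins - length(out_genes))
  targets <- c(out_genes, sample(markers, n_marker_ab))
  n_rest <- config$n_proteins - length(targets)
  if (n_rest > 0)
    targets <- c(targets, sample(setdiff(genes$gene, targets), n_rest))
  targets <- targets[seq_len(config$n_proteins)]
  phospho <- c(rep(FALSE, length(targets)))
  phospho[sample(length(targets), round(0.1 * length(targets)))] <- TRUE
  antibody_map <- data.frame(
    antibody = paste0(targets, ifelse(phospho, "_p", "_ab")),
    gene = targets, phospho = phospho, stringsAsFactors = FALSE)
  rho <- rep_len(config$protein_rho, config$n_proteins)
  protein <- t(vapply(seq_len(config$n_proteins), function(i) {
    m <- expr[targets[i], ]
    zm <- (m - mean(m)) / stats::sd(m)
    p <- (rho[i] * zm + sqrt(1 - rho[i]^2) * stats::rnorm(length(zm))) *
      config$noise_sd$protein
    p - stats::median(p)
  }, numeric(config$n_samples)))
  dimnames(protein) <- list(antibody_map$antibody, annotations$sample_id)

  gene_sets <- c(list(GI_MARKERS = markers),
                 stats::setNames(lapply(1:15, function(i)
                   sample(genes$gene, 100)), sprintf("RANDOM_%02d", 1:15)))

  truth <- list(subgroup = stats::setNames(annotations$subgroup,
                                           annotations$sample_id),
                phenotype = stats::setNames(annotations$phenotype,
                                            annotations$sample_id),
                marker_genes = markers,
                cis_genes = tracks$cis_genes,
                cis_events = tracks$cis_events,
                outlier_events = tracks$outlier_events,
                signature_weights = config$signature_weights,
                true_segments = tracks$true_segments,
                gene_pcf_true = tracks$gene_pcf_true,
                protein_rho = stats::setNames(rho, antibody_map$antibody))

  structure(list(annotations = annotations, variants = variants,
                 probes = tracks$probes, probe_values = tracks$values,
                 expression = expr, mirna = mirna, protein = protein,
                 antibody_map = antibody_map, gene_sets = gene_sets,
                 gene_model = genes, truth = truth, config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("Synthetic cell-line panel\n")
  cat("  samples:  ", nrow(x$annotations), " (",
      paste(names(table(x$annotations$phenotype)),
            table(x$annotations$phenotype), collapse = ", ", sep = ":"),
      ")\n", sep = "")
  cat("  variants: ", nrow(x$variants), "\n", sep = "")
  cat("  genes:    ", nrow(x$expression), "; miRNAs: ", nrow(x$mirna),
      "; antibodies: ", nrow(x$protein), "\n", sep = "")
  cat("  probes:   ", nrow(x$probes), " on ",
      length(unique(x$probes$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}
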