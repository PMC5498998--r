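#' Standardize ssGSEA scores across samples
#'
#' Per gene set (row), subtracts the cross-sample mean and divides by the
#' cross-sample standard deviation, so entries express how many standard
#' deviations a sample's score lies above or below the panel mean. Sets with
#' zero variance are dropped with a message.
#'
#' @param ssgsea_matrix Numeric matrix, gene sets x samples (>= 2 samples).
#' @return The standardized matrix.
#' @export
standardize_scores <- function(ssgsea_matrix) {
  stopifnot(is.matrix(ssgsea_matrix))
  if (ncol(ssgsea_matrix) < 2)
    stop("standardize_scores: need at least 2 samples")
  sds <- apply(ssgsea_matrix, 1, stats::sd)
  drop <- sds == 0
  if (any(drop))
    message("standardize_scores: dropping ", sum(drop),
            " constant gene set(s)")
  x <- ssgsea_matrix[!drop, , drop = FALSE]
  (x - rowMeans(x)) / sds[!drop]
}

default_run_config <- function() {
  list(seed = 1L, outdir = "crcpanel_out", simulate = list(),
       inputs = NULL,
       stages = list(variants = TRUE, cna = TRUE, subtype = TRUE,
                     cis = TRUE, outliers = TRUE, protein = TRUE,
                     report = TRUE),
       thresholds = list(gamma = 100, gain = 0.15, loss = -0.15,
                         cis_gain = 0.3, cis_loss = -0.3,
                         amplitude_factor = 4, z_cut = 3,
                         min_alt_reads = 10, iqr_min = 0.7,
                         mean_quantile_cut = 0.25, min_aberrant_samples = 3,
                         fdr = 0.05, rho_cut = 0.7, fc_p_cut = 0.1,
                         top_n_genes = 1000, ssgsea_alpha = 0.25))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file (or takes a list) and fills unspecified keys with the
#' defaults; every analysis threshold is an explicit config key.
#'
#' @param config Path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @return A complete run-configuration list.
#' @export
load_run_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop("load_run_config: config must be a path, a list or NULL")
  cfg <- merge_config(default_run_config(), user)
  th <- cfg$thresholds
  if (!(th$loss < 0 && 0 < th$gain) || th$gamma <= 0 || th$z_cut <= 0)
    stop("load_run_config: thresholds out of range")
  cfg
}

log_stage <- function(log_path, stage, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "\t", stage, "\t",
                 paste(..., sep = "\t"))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the integrated multi-omics pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic panel
#' (simulated from `config$simulate` overrides) or on files named in
#' `config$inputs`, writing every stage output plus a per-sample report to
#' `config$outdir`. A run log records the thresholds used and one line per
#' completed stage. A stage failure aborts with the stage name and cause,
#' leaving completed outputs plus a `FAILED_<stage>` marker file.
#'
#' @param config Run configuration (path, list, or `NULL`); see
#'   [load_run_config()].
#' @return Invisibly, a list bundle with every stage's results.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run_log.tsv")
  cat("", file = log_path)
  log_stage(log_path, "config",
            paste(names(unlist(cfg$thresholds)), unlist(cfg$thresholds),
                  sep = "=", collapse = ";"), paste0("seed=", cfg$seed))
  set.seed(cfg$seed)
  th <- cfg$thresholds
  thresholds <- aberration_thresholds(gain = th$gain, loss = th$loss,
                                      cis_gain = th$cis_gain,
                                      cis_loss = th$cis_loss,
                                      amplitude_factor = th$amplitude_factor)
  bundle <- list(config = cfg)
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      cat("", file = file.path(cfg$outdir, paste0("FAILED_", stage)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- inputs ----
  bundle <- run_stage("input", function() {
    if (is.null(cfg$inputs)) {
      pc <- do.call(panel_config, c(cfg$simulate, list(seed = cfg$seed)))
      panel <- generate_panel(pc)
      bundle$annotations <- panel$annotations
      bundle$variants_raw <- panel$variants
      bundle$probes <- panel$probes
      bundle$probe_values <- panel$probe_values
      bundle$expression <- panel$expression
      bundle$mirna <- panel$mirna
      bundle$protein <- panel$protein
      bundle$antibody_map <- panel$antibody_map
      bundle$gene_sets <- panel$gene_sets
      bundle$gene_model <- panel$gene_model
      bundle$panel <- panel
      log_stage(log_path, "input", "simulated panel",
                paste0("n_samples=", nrow(panel$annotations)))
    } else {
      ins <- cfg$inputs
      bundle$annotations <- utils::read.delim(ins$samples,
                                              stringsAsFactors = FALSE)
      bundle$variants_raw <- read_variants_tsv(ins$variants)
      tr <- read_probe_tracks(ins$probe_tracks)
      bundle$probes <- tr$probes; bundle$probe_values <- tr$values
      bundle$expression <- read_matrix_tsv(ins$expression)
      bundle$mirna <- if (!is.null(ins$mirna)) read_matrix_tsv(ins$mirna)
      bundle$protein <- if (!is.null(ins$protein)) read_matrix_tsv(ins$protein)
      bundle$antibody_map <- if (!is.null(ins$antibody_map))
        utils::read.delim(ins$antibody_map, stringsAsFactors = FALSE)
      bundle$gene_sets <- if (!is.null(ins$gene_sets)) read_gmt(ins$gene_sets)
      bundle$gene_model <- utils::read.delim(ins$gene_model,
                                             stringsAsFactors = FALSE)
      log_stage(log_path, "input", "loaded files",
                paste(tools::md5sum(unlist(ins)), collapse = ","))
    }
    bundle
  })
  ann <- bundle$annotations
  mss <- ann$sample_id[ann$phenotype == "MSS"]

  ## ---- variant profiles ----
  if (isTRUE(cfg$stages$variants)) bundle <- run_stage("variants", function() {
    kept <- filter_variants(bundle$variants_raw, th$min_alt_reads)
    bundle$variants <- kept
    bundle$loads <- variant_load(kept, samples = ann$sample_id)
    hyper <- ann$phenotype %in% c("MSI", "POLE")
    bundle$spectra <- lapply(split(kept, ann$phenotype[match(
      kept$sample_id, ann$sample_id)]), mutation_spectrum)
    if (any(hyper) && any(!hyper))
      bundle$load_test <- compare_loads(
        bundle$loads$n_nonsynonymous[hyper],
        bundle$loads$n_nonsynonymous[!hyper])
    utils::write.table(bundle$loads, file.path(cfg$outdir, "variant_loads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ph in names(bundle$spectra))
      utils::write.table(bundle$spectra[[ph]],
                         file.path(cfg$outdir, paste0("spectrum_", ph, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(log_path, "variants", paste0("kept=", nrow(kept)))
    bundle
  })

  ## ---- copy number ----
  if (isTRUE(cfg$stages$cna)) bundle <- run_stage("cna", function() {
    segs <- do.call(rbind, lapply(ann$sample_id, function(s)
      pcf_segment(data.frame(bundle$probes, value = bundle$probe_values[, s]),
                  gamma = th$gamma, sample_id = s)))
    class(segs) <- c("copy_segments", class(segs))
    bundle$segments <- segs
    bundle$pct_aberrant <- genome_fraction_aberrant(segs, thresholds)
    bundle$sro <- compute_sro(segs)
    bundle$gene_copy <- filter_genes_all_samples(
      map_genes(segs, bundle$gene_model, thresholds, use_cis = FALSE))
    bundle$gene_copy_cis <- filter_genes_all_samples(
      map_genes(segs, bundle$gene_model, thresholds, use_cis = TRUE))
    if (!is.null(bundle$loads) && length(unique(bundle$pct_aberrant)) > 1)
      bundle$load_cna <- load_cna_anticorrelation(
        stats::setNames(bundle$loads$n_nonsynonymous, bundle$loads$sample_id),
        bundle$pct_aberrant)
    write_seg(segs, file.path(cfg$outdir, "segments.seg"))
    write_matrix_tsv(bundle$gene_copy$values,
                     file.path(cfg$outdir, "gene_copy_values.tsv"), "gene")
    log_stage(log_path, "cna", paste0("segments=", nrow(segs)))
    bundle
  })

  ## ---- expression subtyping ----
  if (isTRUE(cfg$stages$subtype)) bundle <- run_stage("subtype", function() {
    top <- select_variable_genes(bundle$expression, min(th$top_n_genes,
                                                        nrow(bundle$expression)))
    marker_set <- bundle$gene_sets[[1L]]
    pca <- pca_scores(top, marker_set = marker_set)
    split <- bimodal_split(stats::setNames(pca$scores[, 1L],
                                           rownames(pca$scores)))
    bundle$pca <- pca
    bundle$subtypes <- split
    if (!is.null(bundle$gene_sets)) {
      bundle$ssgsea <- t(vapply(bundle$gene_sets, function(gs)
        ssgsea_score(bundle$expression, gs, alpha = th$ssgsea_alpha),
        numeric(ncol(bundle$expression))))
      write_matrix_tsv(bundle$ssgsea, file.path(cfg$outdir, "ssgsea.tsv"),
                       "gene_set")
    }
    if (isTRUE(attr(split, "bimodality_ok"))) {
      labels <- factor(split$label, levels = c("colon_like",
                                               "undifferentiated"))
      bundle$de_mrna <- differential_expression(bundle$expression, labels)
      utils::write.table(bundle$de_mrna, file.path(cfg$outdir, "de_mrna.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(bundle$gene_sets))
        bundle$gene_set_test <- competitive_gene_set_test(bundle$de_mrna,
                                                          bundle$gene_sets)
      if (!is.null(bundle$mirna)) {
        logcpm <- normalize_mirna(bundle$mirna)
        bundle$de_mirna <- differential_expression(logcpm, labels)
      }
      if (!is.null(bundle$protein))
        bundle$de_protein <- differential_expression(bundle$protein, labels)
    } else message("run_pipeline: PC1 density unimodal; no subgroup labels")
    utils::write.table(split, file.path(cfg$outdir, "subtypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(log_path, "subtype",
              paste0("bimodal=", attr(split, "bimodality_ok")))
    bundle
  })

  ## ---- in-cis integration ----
  if (isTRUE(cfg$stages$cis) && !is.null(bundle$gene_copy_cis))
    bundle <- run_stage("cis", function() {
      ccfg <- cis_config(mean_quantile_cut = th$mean_quantile_cut,
                         iqr_min = th$iqr_min,
                         min_aberrant_samples = th$min_aberrant_samples,
                         fdr_cut = th$fdr, spearman_cut = th$rho_cut,
                         eligible_samples = if (length(mss) >= 4) mss else NULL)
      genes <- filter_expression_for_cis(bundle$expression, ccfg)
      bundle$cis <- test_cis(bundle$expression, bundle$gene_copy_cis, ccfg,
                             genes = genes)
      bundle$cis_corr <- correlate_cis(bundle$expression,
                                       bundle$gene_copy_cis, ccfg,
                                       genes = genes)
      bundle$cis_summary <- if (nrow(bundle$cis))
        cis_association_summary(bundle$cis, bundle$cis_corr)
      utils::write.table(bundle$cis, file.path(cfg$outdir, "cis_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage(log_path, "cis", paste0("tested=", nrow(bundle$cis)))
      bundle
    })

  ## ---- outlier nomination ----
  if (isTRUE(cfg$stages$outliers) && !is.null(bundle$gene_copy))
    bundle <- run_stage("outliers", function() {
      events <- nominate_concurrent(bundle$gene_copy, bundle$expression,
                                    thresholds,
                                    samples = if (length(mss) >= 2) mss,
                                    z_cut = th$z_cut)
      events <- protein_corroborate(events, bundle$protein,
                                    bundle$antibody_map)
      bundle$outliers <- events
      utils::write.table(events, file.path(cfg$outdir, "outlier_events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage(log_path, "outliers",
                paste0("nominated=", sum(events$nominated)))
      bundle
    })

  ## ---- gene-protein concordance ----
  if (isTRUE(cfg$stages$protein) && !is.null(bundle$protein))
    bundle <- run_stage("protein", function() {
      bundle$protein_pairs <- pair_and_correlate(bundle$expression,
                                                 bundle$protein,
                                                 bundle$antibody_map)
      if (!is.null(bundle$de_mrna) && !is.null(bundle$de_protein))
        bundle$fc_concordance <- tryCatch(
          fc_concordance(bundle$de_mrna, bundle$de_protein,
                         bundle$antibody_map, p_cut = th$fc_p_cut),
          error = function(e) NULL)
      utils::write.table(bundle$protein_pairs$pairs,
                         file.path(cfg$outdir, "protein_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage(log_path, "protein",
                paste0("median_r=",
                       round(bundle$protein_pairs$summary$median, 3)))
      bundle
    })

  ## ---- per-sample report ----
  if (isTRUE(cfg$stages$report)) bundle <- run_stage("report", function() {
    rep <- data.frame(sample_id = ann$sample_id, phenotype = ann$phenotype,
                      stringsAsFactors = FALSE)
    rep$subgroup <- if (!is.null(bundle$subtypes))
      bundle$subtypes$label[match(rep$sample_id, bundle$subtypes$sample_id)]
    else NA_character_
    rep$pct_genome_aberrant <- if (!is.null(bundle$pct_aberrant))
      round(bundle$pct_aberrant[rep$sample_id], 1) else NA_real_
    rep$n_nonsynonymous <- if (!is.null(bundle$loads))
      bundle$loads$n_nonsynonymous[match(rep$sample_id,
                                         bundle$loads$sample_id)]
    else NA_integer_
    if (!is.null(bundle$outliers)) {
      nom <- bundle$outliers[bundle$outliers$nominated, , drop = FALSE]
      rep$notable_events <- vapply(rep$sample_id, function(s)
        paste(nom$gene[nom$sample == s], collapse = ","), "")
    }
    if (!is.null(bundle$ssgsea)) {
      z <- standardize_scores(bundle$ssgsea)
      rep <- cbind(rep, t(round(z[, rep$sample_id, drop = FALSE], 2)))
    }
    bundle$report <- rep
    utils::write.table(rep, file.path(cfg$outdir, "sample_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(log_path, "report", paste0("samples=", nrow(rep)))
    bundle
  })

  invisible(bundle)
}
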