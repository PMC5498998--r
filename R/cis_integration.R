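#' Configuration for the in-cis copy-number/expression analysis
#'
#' Defaults follow the panel analysis: genes in the lower quartile of mean
#' expression are excluded, only genes with cross-sample IQR strictly above
#' 0.7 are retained, a gene must be aberrant (at the cis thresholds +/-0.3)
#' in more than 2 eligible samples to be tested, Wilcoxon verdicts use
#' Benjamini-Hochberg q < 0.05, and the Spearman flag requires rho strictly
#' above 0.7.
#'
#' @param mean_quantile_cut Quantile of gene mean expression below which (and
#'   at which) genes are excluded.
#' @param iqr_min Minimum cross-sample IQR (strict).
#' @param min_aberrant_samples Minimum number of eligible samples in the
#'   aberrant category ("> 2 cell lines" = 3).
#' @param fdr_cut FDR cutoff for the Wilcoxon verdict.
#' @param spearman_cut Spearman rho cutoff (strict).
#' @param eligible_samples Optional identifiers of the samples the analysis
#'   is restricted to (e.g. the unique MSS lines); `NULL` means all samples.
#' @return An object of class `cis_config`.
#' @export
cis_config <- function(mean_quantile_cut = 0.25, iqr_min = 0.7,
                       min_aberrant_samples = 3, fdr_cut = 0.05,
                       spearman_cut = 0.7, eligible_samples = NULL) {
  if (!(mean_quantile_cut > 0 && mean_quantile_cut < 1))
    stop("cis_config: mean_quantile_cut must be in (0, 1)")
  if (min_aberrant_samples < 1)
    stop("cis_config: min_aberrant_samples must be >= 1")
  structure(list(mean_quantile_cut = mean_quantile_cut, iqr_min = iqr_min,
                 min_aberrant_samples = min_aberrant_samples,
                 fdr_cut = fdr_cut, spearman_cut = spearman_cut,
                 eligible_samples = eligible_samples),
            class = "cis_config")
}

eligible_cols <- function(x, config) {
  if (is.null(config$eligible_samples)) return(colnames(x))
  miss <- setdiff(config$eligible_samples, colnames(x))
  if (length(miss))
    stop("eligible sample(s) not found: ", paste(miss, collapse = ", "))
  config$eligible_samples
}

#' Expression filters for the in-cis analysis
#'
#' Removes genes whose mean expression (over the eligible samples) lies at or
#' below the configured quantile of gene means, then keeps genes whose
#' cross-sample IQR is strictly above `iqr_min`.
#'
#' @param x Log2 expression matrix, genes x samples.
#' @param config A [cis_config()].
#' @return Character vector of retained gene ids (empty, with a warning, if
#'   nothing survives).
#' @export
filter_expression_for_cis <- function(x, config = cis_config()) {
  stopifnot(is.matrix(x), inherits(config, "cis_config"))
  x <- x[, eligible_cols(x, config), drop = FALSE]
  m <- rowMeans(x)
  keep <- m > stats::quantile(m, config$mean_quantile_cut)
  iqr <- apply(x[keep, , drop = FALSE], 1, stats::IQR)
  out <- rownames(x)[keep][iqr > config$iqr_min]
  if (!length(out)) warning("filter_expression_for_cis: no genes retained")
  out
}

#' Genes eligible for in-cis testing in a given direction
#'
#' A gene is eligible for direction `gain` (`loss`) when at least
#' `min_aberrant_samples` eligible samples carry the gain (loss) category at
#' the strict cis thresholds. Eligibility in the two directions is computed
#' independently; a gene can be eligible for both.
#'
#' @param gct A `gene_copy_table` built with `use_cis = TRUE` (categories at
#'   the +/-0.3 thresholds).
#' @param config A [cis_config()].
#' @param direction `"gain"` or `"loss"`.
#' @return Character vector of eligible gene ids.
#' @export
eligible_genes <- function(gct, config = cis_config(),
                           direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(inherits(gct, "gene_copy_table"))
  if (!isTRUE(gct$use_cis))
    stop("eligible_genes: gene_copy_table must be built with use_cis = TRUE")
  cats <- gct$categories[, eligible_cols(gct$categories, config), drop = FALSE]
  n_ab <- rowSums(cats == direction)
  rownames(cats)[n_ab >= config$min_aberrant_samples]
}

#' Wilcoxon in-cis association tests
#'
#' For each eligible gene and direction, expression in the aberrant samples
#' (gain, respectively loss, at the cis thresholds) is compared against all
#' remaining eligible samples (neutral plus the opposite aberration) with a
#' two-sided rank-sum test; p-values are Benjamini-Hochberg adjusted within
#' each direction's tested family. Genes with fewer than 2 samples on either
#' side are skipped with a message.
#'
#' @param x Log2 expression matrix, genes x samples.
#' @param gct A `gene_copy_table` built with `use_cis = TRUE`.
#' @param config A [cis_config()].
#' @param genes Optional gene subset (e.g. from
#'   [filter_expression_for_cis()]); defaults to all genes shared between
#'   `x` and `gct`.
#' @return Object of class `cis_result`: data frame with `gene`, `direction`,
#'   `n_aberrant`, `p`, `q`, `wilcoxon_associated`.
#' @export
test_cis <- function(x, gct, config = cis_config(), genes = NULL) {
  stopifnot(is.matrix(x), inherits(gct, "gene_copy_table"))
  cols <- intersect(eligible_cols(x, config),
                    eligible_cols(gct$categories, config))
  shared <- intersect(rownames(x), rownames(gct$categories))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  rows <- list()
  n_skipped <- 0L
  for (direction in c("gain", "loss")) {
    elig <- intersect(eligible_genes(gct, config, direction), shared)
    if (!length(elig)) next
    p <- rep(NA_real_, length(elig)); n_ab <- integer(length(elig))
    for (i in seq_along(elig)) {
      g <- elig[i]
      ab <- gct$categories[g, cols] == direction
      miss <- gct$categories[g, cols] == "missing"
      ab_v <- x[g, cols][ab]
      rest_v <- x[g, cols][!ab & !miss]
      n_ab[i] <- sum(ab)
      if (sum(ab) < 2 || length(rest_v) < 2) {
        n_skipped <- n_skipped + 1L
        next
      }
      p[i] <- compare_loads(ab_v, rest_v)$p.value
    }
    ok <- !is.na(p)
    if (!any(ok)) next
    rows[[direction]] <- data.frame(
      gene = elig[ok], direction = rep(direction, sum(ok)),
      n_aberrant = n_ab[ok],
      p = p[ok], q = stats::p.adjust(p[ok], method = "BH"),
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    message("test_cis: skipped ", n_skipped,
            " gene/direction pair(s) with fewer than 2 samples on a side")
  if (!length(rows))
    return(structure(data.frame(gene = character(), direction = character(),
                                n_aberrant = integer(), p = numeric(),
                                q = numeric(),
                                wilcoxon_associated = logical()),
                     class = c("cis_result", "data.frame")))
  out <- do.call(rbind, rows)
  out$wilcoxon_associated <- out$q < config$fdr_cut
  rownames(out) <- NULL
  structure(out, class = c("cis_result", class(out)))
}

#' Gene-wise Spearman correlation of copy number and expression
#'
#' Computes, per gene, the Spearman correlation between the gene's
#' copy-number (PCF) values and its expression across the eligible samples.
#' Genes whose correlation is strictly above the configured cutoff are
#' flagged as showing an association. Genes with a constant copy-number
#' vector have an undefined correlation and are flagged `FALSE` with a
#' message.
#'
#' @param x Log2 expression matrix, genes x samples.
#' @param gct A `gene_copy_table`.
#' @param config A [cis_config()].
#' @param genes Optional gene subset; defaults to all shared genes.
#' @return Data frame with `gene`, `rho`, `n`, `correlation_associated`.
#' @export
correlate_cis <- function(x, gct, config = cis_config(), genes = NULL) {
  stopifnot(is.matrix(x), inherits(gct, "gene_copy_table"))
  cols <- intersect(eligible_cols(x, config),
                    eligible_cols(gct$values, config))
  shared <- intersect(rownames(x), rownames(gct$values))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  n_const <- 0L
  rows <- lapply(shared, function(g) {
    cn <- gct$values[g, cols]; ex <- x[g, cols]
    ok <- !is.na(cn) & !is.na(ex)
    if (sum(ok) < 4)
      return(data.frame(gene = g, rho = NA_real_, n = sum(ok),
                        correlation_associated = FALSE,
                        stringsAsFactors = FALSE))
    if (stats::sd(cn[ok]) == 0) {
      n_const <<- n_const + 1L
      return(data.frame(gene = g, rho = NA_real_, n = sum(ok),
                        correlation_associated = FALSE,
                        stringsAsFactors = FALSE))
    }
    rho <- stats::cor(cn[ok], ex[ok], method = "spearman")
    data.frame(gene = g, rho = rho, n = sum(ok),
               correlation_associated = rho > config$spearman_cut,
               stringsAsFactors = FALSE)
  })
  if (n_const > 0L)
    message("correlate_cis: ", n_const,
            " gene(s) with constant copy-number vector (rho undefined)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rounded percentage of a count over a total
#'
#' Reporting arithmetic used by the in-cis summary (e.g. 298 associated of
#' 1148 eligible gained genes is 26%).
#'
#' @param n Numerator count.
#' @param d Denominator count (> 0).
#' @param digits Decimal places (default 0, matching reported percentages).
#' @return Numeric percentage.
#' @export
percent_of <- function(n, d, digits = 0) {
  if (any(d <= 0)) stop("percent_of: denominator must be positive")
  round(100 * n / d, digits)
}

#' Summarize in-cis association results per direction
#'
#' @param cis A `cis_result` from [test_cis()].
#' @param corr Optional output of [correlate_cis()]; when given, the summary
#'   also counts Wilcoxon-associated genes whose Spearman correlation is
#'   above the cutoff.
#' @return Data frame with one row per direction: eligible and associated
#'   counts, percentage associated, and (if `corr` given) the count and
#'   percentage of associated genes with strong correlation.
#' @export
cis_association_summary <- function(cis, corr = NULL) {
  stopifnot(inherits(cis, "cis_result"))
  out <- do.call(rbind, lapply(split(cis, cis$direction), function(d) {
    n_elig <- nrow(d)
    n_assoc <- sum(d$wilcoxon_associated)
    row <- data.frame(direction = d$direction[1L], n_eligible = n_elig,
                      n_associated = n_assoc,
                      pct_associated = if (n_elig > 0) percent_of(n_assoc, n_elig)
                                       else NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(corr)) {
      sig <- d$gene[d$wilcoxon_associated]
      n_corr <- sum(corr$correlation_associated[corr$gene %in% sig], na.rm = TRUE)
      row$n_correlated <- n_corr
      row$pct_correlated <- if (n_assoc > 0) percent_of(n_corr, n_assoc)
                            else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out
}
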