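#' Gene-protein pair correlations with a variation filter
#'
#' Computes the Pearson correlation across shared samples for every antibody
#' paired with its cognate gene's mRNA. Pairs whose cross-sample variation
#' (variance by default, IQR optionally) lies in the lowest quartile of
#' either layer are flagged and excluded from the summary statistics.
#'
#' @param x Log2 expression matrix, genes x samples.
#' @param protein Protein abundance matrix, antibodies x samples.
#' @param antibody_map Data frame with columns `antibody`, `gene`; each
#'   antibody forms its own pair (phospho and total antibodies against the
#'   same gene are separate pairs).
#' @param variation Variation measure for the quartile filter.
#' @return List with `pairs` (data frame: `antibody`, `gene`, `pearson_r`,
#'   `mrna_low_variation`, `protein_low_variation`, `retained`) and
#'   `summary` (median, IQR bounds and retained count over retained pairs).
#' @export
pair_and_correlate <- function(x, protein, antibody_map,
                               variation = c("variance", "IQR")) {
  variation <- match.arg(variation)
  stopifnot(is.matrix(x), is.matrix(protein), is.data.frame(antibody_map),
            all(c("antibody", "gene") %in% names(antibody_map)))
  shared <- intersect(colnames(x), colnames(protein))
  if (length(shared) < 4)
    stop("pair_and_correlate: need at least 4 shared samples")
  map <- antibody_map[antibody_map$antibody %in% rownames(protein) &
                        antibody_map$gene %in% rownames(x), , drop = FALSE]
  if (!nrow(map)) stop("pair_and_correlate: no mapped gene-protein pairs")
  vfun <- if (variation == "variance") stats::var else stats::IQR
  mv <- apply(x[map$gene, shared, drop = FALSE], 1, vfun)
  pv <- apply(protein[map$antibody, shared, drop = FALSE], 1, vfun)
  r <- vapply(seq_len(nrow(map)), function(i)
    stats::cor(x[map$gene[i], shared], protein[map$antibody[i], shared]),
    numeric(1))
  low_m <- mv <= stats::quantile(mv, 0.25)
  low_p <- pv <= stats::quantile(pv, 0.25)
  pairs <- data.frame(antibody = map$antibody, gene = map$gene,
                      pearson_r = r,
                      mrna_low_variation = unname(low_m),
                      protein_low_variation = unname(low_p),
                      retained = unname(!low_m & !low_p),
                      stringsAsFactors = FALSE)
  kept <- pairs$pearson_r[pairs$retained]
  qs <- stats::quantile(kept, c(0.25, 0.5, 0.75), na.rm = TRUE)
  list(pairs = pairs,
       summary = list(median = unname(qs[2L]), iqr_low = unname(qs[1L]),
                      iqr_high = unname(qs[3L]), n_retained = length(kept),
                      n_total = nrow(pairs)))
}

#' mRNA versus protein fold-change concordance
#'
#' Joins the differential-expression results of the mRNA and protein layers
#' via the antibody map, retains pairs with adjusted p-value below `p_cut`
#' in either layer, and reports the squared Pearson correlation of the paired
#' log2 fold-changes.
#'
#' @param de_mrna A `de_result` on the gene level.
#' @param de_protein A `de_result` on the antibody level (same grouping).
#' @param antibody_map Data frame with columns `antibody`, `gene`.
#' @param p_cut Adjusted p-value cutoff applied with the "either layer" rule.
#' @return List with `pairs` (data frame: `antibody`, `gene`, `log2FC_mrna`,
#'   `log2FC_protein`, `q_mrna`, `q_protein`) and `r_squared`.
#' @export
fc_concordance <- function(de_mrna, de_protein, antibody_map, p_cut = 0.1) {
  stopifnot(inherits(de_mrna, "de_result"), inherits(de_protein, "de_result"))
  map <- antibody_map[antibody_map$antibody %in% de_protein$feature &
                        antibody_map$gene %in% de_mrna$feature, , drop = FALSE]
  if (!nrow(map)) stop("fc_concordance: no mapped gene-protein pairs")
  im <- match(map$gene, de_mrna$feature)
  ip <- match(map$antibody, de_protein$feature)
  pairs <- data.frame(antibody = map$antibody, gene = map$gene,
                      log2FC_mrna = de_mrna$log2FC[im],
                      log2FC_protein = de_protein$log2FC[ip],
                      q_mrna = de_mrna$q[im], q_protein = de_protein$q[ip],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q_mrna < p_cut | pairs$q_protein < p_cut, , drop = FALSE]
  if (!nrow(pairs)) stop("fc_concordance: no pairs pass the p_cut filter")
  r2 <- stats::cor(pairs$log2FC_mrna, pairs$log2FC_protein)^2
  list(pairs = pairs, r_squared = r2)
}
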