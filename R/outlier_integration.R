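#' Within-sample expression outlier z-scores
#'
#' Standardizes each sample's expression values against the mean and standard
#' deviation across all genes of that sample; values strictly outside 3
#' standard deviations are considered outliers.
#'
#' @param x Log2 expression matrix, genes x samples (>= 10 genes).
#' @return Matrix of z-scores with the dimensions of `x`.
#' @export
expression_outlier_z <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 10) stop("expression_outlier_z: need at least 10 genes")
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  if (any(sd_ == 0)) stop("expression_outlier_z: zero within-sample SD")
  sweep(sweep(x, 2, mu), 2, sd_, "/")
}

#' Nominate concurrent high-amplitude CNA and expression-outlier events
#'
#' For each gene, the sample carrying the maximum (minimum) gene PCF value is
#' a candidate amplification (deletion) event when that value is beyond
#' `amplitude_factor` times the base gain (loss) threshold (4 x 0.15 = 0.6 by
#' default). The event is nominated when the same sample also carries the
#' maximum (minimum) expression value for the gene and the expression
#' z-score is strictly outside `z_cut`. Exact ties in the arg-extreme are
#' treated as non-concurrent and logged. All candidates passing the
#' amplitude gate are returned, with the concurrence and outlier gates
#' reported individually.
#'
#' @param gct A `gene_copy_table` (base thresholds).
#' @param x Log2 expression matrix, genes x samples; z-scores are computed
#'   over all genes of `x`.
#' @param thresholds An [aberration_thresholds()] object.
#' @param samples Optional sample subset (e.g. unique CIN cell lines);
#'   defaults to the samples shared between `gct` and `x`.
#' @param z_cut Expression z-score cutoff (strict).
#' @return Data frame with `gene`, `sample`, `direction`, `pcf_value`,
#'   `expression_z`, `concurrent`, `outlier`, `nominated`.
#' @export
nominate_concurrent <- function(gct, x, thresholds = aberration_thresholds(),
                                samples = NULL, z_cut = 3) {
  stopifnot(inherits(gct, "gene_copy_table"), is.matrix(x))
  cols <- intersect(colnames(gct$values), colnames(x))
  if (!is.null(samples)) {
    miss <- setdiff(samples, cols)
    if (length(miss))
      stop("nominate_concurrent: sample(s) not found: ",
           paste(miss, collapse = ", "))
    cols <- samples
  }
  genes <- intersect(rownames(gct$values), rownames(x))
  z <- expression_outlier_z(x[, cols, drop = FALSE])
  amp_gain <- thresholds$amplitude_factor * thresholds$gain
  amp_loss <- thresholds$amplitude_factor * thresholds$loss
  n_ties <- 0L
  rows <- list()
  for (g in genes) {
    cn <- gct$values[g, cols]
    ex <- x[g, cols]
    ok <- !is.na(cn)
    if (sum(ok) < 2) next
    for (direction in c("amplified_high", "deleted_low")) {
      if (direction == "amplified_high") {
        v <- max(cn[ok])
        if (v < amp_gain) next
        s_cn <- names(cn[ok])[cn[ok] == v]
        s_ex <- names(ex)[ex == max(ex)]
      } else {
        v <- min(cn[ok])
        if (v > amp_loss) next
        s_cn <- names(cn[ok])[cn[ok] == v]
        s_ex <- names(ex)[ex == min(ex)]
      }
      if (length(s_cn) > 1L || length(s_ex) > 1L) {
        n_ties <- n_ties + 1L
        concurrent <- FALSE
        s_star <- s_cn[1L]
      } else {
        concurrent <- identical(s_cn, s_ex)
        s_star <- s_cn
      }
      zval <- z[g, s_star]
      outlier <- if (direction == "amplified_high") zval > z_cut else zval < -z_cut
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s_star, direction = direction, pcf_value = v,
        expression_z = zval, concurrent = concurrent, outlier = outlier,
        nominated = concurrent && outlier, stringsAsFactors = FALSE)
    }
  }
  if (n_ties > 0L)
    message("nominate_concurrent: ", n_ties,
            " tie(s) in arg-extreme treated as non-concurrent")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), sample = character(),
               direction = character(), pcf_value = numeric(),
               expression_z = numeric(), concurrent = logical(),
               outlier = logical(), nominated = logical())
  rownames(out) <- NULL
  out
}

#' Append protein-level corroboration to outlier events
#'
#' For events whose gene has one or more mapped antibodies, a protein
#' z-score is computed within the event's sample across all antibodies
#' (analogous to the expression z-score) and the antibody with the largest
#' absolute z is reported. Unmapped genes, or a missing protein matrix,
#' leave `protein_z` missing.
#'
#' @param events Output of [nominate_concurrent()].
#' @param protein Protein abundance matrix, antibodies x samples, or `NULL`.
#' @param antibody_map Data frame with columns `antibody`, `gene`.
#' @return `events` with `protein_z` (and `antibody`) columns appended.
#' @export
protein_corroborate <- function(events, protein, antibody_map) {
  stopifnot(is.data.frame(events))
  events$protein_z <- NA_real_
  events$antibody <- NA_character_
  if (is.null(protein) || nrow(events) == 0L) return(events)
  stopifnot(is.matrix(protein), is.data.frame(antibody_map),
            all(c("antibody", "gene") %in% names(antibody_map)))
  mu <- colMeans(protein)
  sd_ <- apply(protein, 2, stats::sd)
  for (i in seq_len(nrow(events))) {
    abs_ <- antibody_map$antibody[antibody_map$gene == events$gene[i]]
    abs_ <- intersect(abs_, rownames(protein))
    s <- events$sample[i]
    if (!length(abs_) || !s %in% colnames(protein) || sd_[s] == 0) next
    zs <- (protein[abs_, s] - mu[s]) / sd_[s]
    k <- which.max(abs(zs))
    events$protein_z[i] <- zs[k]
    events$antibody[i] <- abs_[k]
  }
  events
}
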