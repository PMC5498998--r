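## shared fixtures and independent oracles, built in code

make_segments <- function(sample_id, chrom, start, end, value,
                          n_probes = rep(1L, length(start))) {
  d <- data.frame(sample_id = sample_id, chrom = chrom, start = start,
                  end = end, n_probes = n_probes, pcf_value = value,
                  stringsAsFactors = FALSE)
  class(d) <- c("copy_segments", class(d))
  d
}

## exhaustive-search oracle for the penalized least-squares segmentation
brute_force_pcf_cost <- function(y, gamma) {
  n <- length(y)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    starts <- c(1L, which(bitwAnd(mask, 2^(0:(n - 2))) > 0) + 1L)
    ends <- c(starts[-1L] - 1L, n)
    cost <- sum(mapply(function(s, e) sum((y[s:e] - mean(y[s:e]))^2),
                       starts, ends)) + gamma * (length(starts) - 1L)
    if (cost < best) best <- cost
  }
  best
}

## position-wise lookup oracle for SRO values
sro_base_oracle <- function(segments, chrom, pos, sample) {
  seg <- segments[segments$sample_id == sample & segments$chrom == chrom &
                    segments$start <= pos & segments$end > pos, ]
  if (nrow(seg) == 0) NA_real_ else seg$pcf_value[1]
}

## adjusted Rand index between two label vectors
ari <- function(a, b) {
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

## small named expression matrix
toy_matrix <- function(values, n_genes = NULL, n_samples = NULL,
                       genes = NULL, samples = NULL) {
  if (is.null(n_genes)) n_genes <- length(values) / n_samples
  if (is.null(n_samples)) n_samples <- length(values) / n_genes
  m <- matrix(values, n_genes, n_samples)
  rownames(m) <- if (is.null(genes)) sprintf("g%03d", seq_len(n_genes)) else genes
  colnames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(n_samples)) else samples
  m
}

## quick small panel configuration for pipeline-level tests
small_panel_config <- function(seed = 1, cluster_effect = 1, n_cis_genes = 8,
                               n_outlier_events = 2, ...) {
  panel_config(n_samples = 20, n_genes = 600, n_mirnas = 60, n_proteins = 40,
               n_chrom = 4, probes_per_chrom = 150, marker_set_size = 60,
               cluster_effect = cluster_effect, n_cis_genes = n_cis_genes,
               n_outlier_events = n_outlier_events, seed = seed, ...)
}
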