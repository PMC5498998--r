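#' Aberration calling thresholds
#'
#' Container for the PCF-value thresholds used to call copy-number gains and
#' losses. The base thresholds (+/-0.15) are used for genome-wide aberration
#' load and frequency tracks; the stricter cis thresholds (+/-0.3) are used
#' when integrating copy number with expression; `amplitude_factor` times the
#' base threshold (4 x 0.15 = 0.6) defines high-amplitude events for outlier
#' nomination.
#'
#' @param gain Gain threshold, inclusive (value >= gain is a gain).
#' @param loss Loss threshold, inclusive (value <= loss is a loss).
#' @param cis_gain,cis_loss Stricter thresholds used for in-cis integration.
#' @param amplitude_factor Multiplier of the base thresholds defining
#'   high-amplitude events.
#' @return An object of class `aberration_thresholds`.
#' @export
aberration_thresholds <- function(gain = 0.15, loss = -0.15,
                                  cis_gain = 0.3, cis_loss = -0.3,
                                  amplitude_factor = 4) {
  if (!(loss < 0 && 0 < gain))
    stop("aberration_thresholds: need loss < 0 < gain")
  if (cis_gain < gain || cis_loss > loss)
    stop("aberration_thresholds: cis thresholds must be at least as extreme as base thresholds")
  if (amplitude_factor <= 0)
    stop("aberration_thresholds: amplitude_factor must be positive")
  structure(list(gain = gain, loss = loss, cis_gain = cis_gain,
                 cis_loss = cis_loss, amplitude_factor = amplitude_factor),
            class = "aberration_thresholds")
}

## exact minimizer of sum(SSE) + gamma * (#breakpoints) by O(n^2) dynamic
## programming; returns integer vector of segment start indices
pcf_dp <- function(y, gamma, min_probes = 1L) {
  n <- length(y)
  if (n == 1L) return(1L)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y * y))
  best <- numeric(n + 1L)
  best[1L] <- -gamma            # first segment carries no breakpoint penalty
  prev <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    if (min_probes > 1L) {
      ok <- (j - i + 1L) >= min_probes
      if (any(ok)) i <- i[ok]   # fall back to any split when j < min_probes
    }
    len <- j - i + 1L
    sse <- (cs2[j + 1L] - cs2[i]) - (cs[j + 1L] - cs[i])^2 / len
    cost <- best[i] + sse + gamma
    k <- which.min(cost)
    best[j + 1L] <- cost[k]
    prev[j] <- i[k]
  }
  starts <- integer(0)
  j <- n
  while (j >= 1L) {
    s <- prev[j]
    starts <- c(s, starts)
    j <- s - 1L
  }
  starts
}

## total penalized cost of a segmentation given by segment start indices
pcf_cost <- function(y, starts, gamma) {
  ends <- c(starts[-1L] - 1L, length(y))
  sse <- mapply(function(s, e) {
    v <- y[s:e]
    sum((v - mean(v))^2)
  }, starts, ends)
  sum(sse) + gamma * (length(starts) - 1L)
}

#' Piecewise-constant-fit segmentation of a probe-level log-ratio track
#'
#' Computes, per chromosome, the exact minimizer of
#' `sum of squared residuals + gamma * (number of breakpoints)` by dynamic
#' programming. The segment value is the mean of its member probes. By default
#' the penalty is applied on data standardized by a robust noise estimate
#' (median absolute deviation of first differences divided by sqrt(2)), so
#' that `gamma` is expressed in units of noise variance; this matches how
#' penalized least-squares segmentation is normally calibrated (the default
#' `gamma = 100` is the panel-analysis setting).
#'
#' Segment boundaries tile the probed span contiguously: each internal
#' boundary lies at the midpoint between the flanking probes, the first
#' segment starts at the first probe position and the last ends one base
#' after the last probe (0-based half-open coordinates).
#'
#' @param track Data frame with columns `chrom`, `pos` (0-based probe
#'   position, ordered within chromosome) and `value` (log-ratio).
#' @param gamma Positive penalty per breakpoint.
#' @param min_probes Minimum number of probes per segment.
#' @param standardize Apply the noise standardization described above.
#' @param sample_id Sample identifier stored on the output.
#' @return Data frame of class `copy_segments` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `n_probes`, `pcf_value`.
#' @export
pcf_segment <- function(track, gamma = 100, min_probes = 1L,
                        standardize = TRUE, sample_id = "sample") {
  stopifnot(is.data.frame(track), all(c("chrom", "pos", "value") %in% names(track)))
  if (gamma <= 0) stop("pcf_segment: gamma must be positive")
  drop <- !is.finite(track$value)
  if (any(drop)) {
    message("pcf_segment: dropping ", sum(drop), " non-finite probe value(s)")
    track <- track[!drop, , drop = FALSE]
  }
  if (nrow(track) == 0L) stop("pcf_segment: no probes")
  out <- lapply(split(track, track$chrom), function(tr) {
    if (is.unsorted(tr$pos, strictly = TRUE))
      stop("pcf_segment: probes not strictly ordered by position on chromosome ",
           tr$chrom[1L])
    y <- tr$value
    g <- gamma
    if (standardize && length(y) > 1L) {
      s <- stats::mad(diff(y)) / sqrt(2)
      if (is.finite(s) && s > 0) g <- gamma * s^2
    }
    starts <- pcf_dp(y, g, min_probes = as.integer(min_probes))
    ends <- c(starts[-1L] - 1L, length(y))
    ## contiguous tiling: boundaries at inter-probe midpoints
    bounds <- c(tr$pos[1L],
                if (length(starts) > 1L)
                  (tr$pos[starts[-1L] - 1L] + tr$pos[starts[-1L]]) %/% 2 + 1L,
                tr$pos[length(y)] + 1L)
    data.frame(sample_id = sample_id,
               chrom = tr$chrom[1L],
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               n_probes = ends - starts + 1L,
               pcf_value = mapply(function(s, e) mean(y[s:e]), starts, ends),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("copy_segments", class(res))
  res
}

#' Call gain/neutral/loss categories from PCF values
#'
#' Gains and losses are called inclusively: a value equal to the threshold is
#' aberrant. With `use_cis = TRUE` the stricter integration thresholds are
#' applied.
#'
#' @param pcf_value Numeric vector of segment or gene PCF values.
#' @param thresholds An [aberration_thresholds()] object.
#' @param use_cis Use the stricter cis thresholds.
#' @return Character vector with values `"gain"`, `"neutral"`, `"loss"`
#'   (`"missing"` for `NA` input).
#' @export
call_category <- function(pcf_value, thresholds = aberration_thresholds(),
                          use_cis = FALSE) {
  stopifnot(inherits(thresholds, "aberration_thresholds"))
  up <- if (use_cis) thresholds$cis_gain else thresholds$gain
  dn <- if (use_cis) thresholds$cis_loss else thresholds$loss
  out <- ifelse(is.na(pcf_value), "missing",
                ifelse(pcf_value >= up, "gain",
                       ifelse(pcf_value <= dn, "loss", "neutral")))
  as.character(out)
}

#' Percentage of covered genome with aberrant copy number
#'
#' The percentage of bases with aberrant copy number out of the total number
#' of bases with a copy-number value available; bases not covered by any
#' segment are excluded from the denominator.
#'
#' @param segments A `copy_segments` data frame (one or more samples).
#' @param thresholds An [aberration_thresholds()] object.
#' @param use_cis Use the stricter cis thresholds when calling aberrations.
#' @return Named numeric vector (per sample) of percentages in `[0, 100]`.
#' @export
genome_fraction_aberrant <- function(segments,
                                     thresholds = aberration_thresholds(),
                                     use_cis = FALSE) {
  stopifnot(is.data.frame(segments))
  out <- vapply(split(segments, segments$sample_id), function(seg) {
    check_non_overlapping(seg)
    covered <- sum(seg$end - seg$start)
    if (covered <= 0) stop("genome_fraction_aberrant: zero covered bases")
    cat_ <- call_category(seg$pcf_value, thresholds, use_cis)
    100 * sum((seg$end - seg$start)[cat_ != "neutral"]) / covered
  }, numeric(1))
  out
}

check_non_overlapping <- function(seg) {
  for (ch in split(seg, seg$chrom)) {
    o <- order(ch$start)
    if (any(ch$start[o] >= ch$end[o]) ||
        (nrow(ch) > 1L && any(ch$end[o][-nrow(ch)] > ch$start[o][-1L])))
      stop("segments overlap or are degenerate for sample ",
           ch$sample_id[1L], " chromosome ", ch$chrom[1L])
  }
  invisible(TRUE)
}

#' Smallest regions of overlap across samples
#'
#' Partitions each chromosome at the union of all samples' segment
#' breakpoints. Every resulting region inherits, per sample, the PCF value of
#' the single parent segment covering it (`NA` where the sample has no
#' coverage). Regions covered by no sample are dropped.
#'
#' @param segments A `copy_segments` data frame holding all samples.
#' @return Object of class `sro_table`: a list with `regions` (data frame
#'   `chrom`, `start`, `end`) and `values` (region x sample matrix).
#' @export
compute_sro <- function(segments) {
  stopifnot(is.data.frame(segments))
  samples <- unique(segments$sample_id)
  for (seg in split(segments, segments$sample_id)) check_non_overlapping(seg)
  regions <- list(); vals <- list()
  for (ch in split(segments, segments$chrom)) {
    bp <- sort(unique(c(ch$start, ch$end)))
    st <- bp[-length(bp)]; en <- bp[-1L]
    m <- matrix(NA_real_, length(st), length(samples),
                dimnames = list(NULL, samples))
    for (sid in unique(ch$sample_id)) {
      seg <- ch[ch$sample_id == sid, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      idx <- findInterval(st, seg$start)
      hit <- idx >= 1L & en <= ifelse(idx >= 1L, seg$end[pmax(idx, 1L)], -Inf)
      m[hit, sid] <- seg$pcf_value[idx[hit]]
    }
    keep <- rowSums(!is.na(m)) > 0L
    regions[[length(regions) + 1L]] <-
      data.frame(chrom = ch$chrom[1L], start = st[keep], end = en[keep],
                 stringsAsFactors = FALSE)
    vals[[length(vals) + 1L]] <- m[keep, , drop = FALSE]
  }
  structure(list(regions = do.call(rbind, regions),
                 values = do.call(rbind, vals)),
            class = "sro_table")
}

#' Map copy-number segments to genes
#'
#' Retrieves a gene x sample PCF value and category table by interval overlap
#' of each sample's segments with a gene model. A gene inside one segment
#' takes that segment's value and category. A gene spanning several segments
#' that all share one category keeps that category, with value equal to the
#' median of the overlapping segment values (a coverage-weighted mean is
#' available via `value_method`). A gene spanning mixed categories takes the
#' median PCF value, with its category re-derived from that median. A gene
#' with no overlap in a sample is missing there.
#'
#' @param segments A `copy_segments` data frame holding all samples.
#' @param gene_model Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param thresholds An [aberration_thresholds()] object.
#' @param use_cis Call categories at the stricter cis thresholds.
#' @param value_method Value for consistent-category multi-segment genes:
#'   `"median"` (default) or `"weighted_mean"` (coverage-weighted).
#' @param genes Optional subset of gene identifiers to map; an error lists
#'   any identifier absent from `gene_model`.
#' @return Object of class `gene_copy_table`: list with `values` and
#'   `categories` (gene x sample matrices), plus the thresholds used.
#' @export
map_genes <- function(segments, gene_model,
                      thresholds = aberration_thresholds(),
                      use_cis = FALSE,
                      value_method = c("median", "weighted_mean"),
                      genes = NULL) {
  value_method <- match.arg(value_method)
  stopifnot(is.data.frame(gene_model),
            all(c("gene", "chrom", "start", "end") %in% names(gene_model)))
  if (!is.null(genes)) {
    missing_ids <- setdiff(genes, gene_model$gene)
    if (length(missing_ids))
      stop("map_genes: gene(s) absent from model: ",
           paste(missing_ids, collapse = ", "))
    gene_model <- gene_model[gene_model$gene %in% genes, , drop = FALSE]
  }
  samples <- unique(segments$sample_id)
  values <- matrix(NA_real_, nrow(gene_model), length(samples),
                   dimnames = list(gene_model$gene, samples))
  categories <- matrix("missing", nrow(gene_model), length(samples),
                       dimnames = list(gene_model$gene, samples))
  gr_genes <- IRanges::IRanges(start = gene_model$start + 1L,
                               end = gene_model$end)
  for (sid in samples) {
    seg <- segments[segments$sample_id == sid, , drop = FALSE]
    for (ch in unique(gene_model$chrom)) {
      gi <- which(gene_model$chrom == ch)
      sc <- seg[seg$chrom == ch, , drop = FALSE]
      if (!length(gi) || !nrow(sc)) next
      hits <- IRanges::findOverlaps(
        gr_genes[gi],
        IRanges::IRanges(start = sc$start + 1L, end = sc$end))
      if (!length(hits)) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      multi <- tabulate(qh, nbins = length(gi)) > 1L
      single <- !multi[qh]
      if (any(single)) {
        g1 <- gi[qh[single]]
        values[cbind(g1, match(sid, samples))] <- sc$pcf_value[sh[single]]
        categories[cbind(g1, match(sid, samples))] <-
          call_category(sc$pcf_value[sh[single]], thresholds, use_cis)
      }
      for (k in unique(qh[!single])) {
        segs <- sh[qh == k]
        v <- sc$pcf_value[segs]
        cat_ <- call_category(v, thresholds, use_cis)
        g <- gi[k]
        if (length(unique(cat_)) == 1L) {
          values[g, sid] <- if (value_method == "median") stats::median(v) else {
            ov <- pmin(sc$end[segs], gene_model$end[g]) -
              pmax(sc$start[segs], gene_model$start[g])
            sum(v * ov) / sum(ov)
          }
          categories[g, sid] <- cat_[1L]
        } else {
          values[g, sid] <- stats::median(v)
          categories[g, sid] <- call_category(values[g, sid], thresholds, use_cis)
        }
      }
    }
  }
  structure(list(values = values, categories = categories,
                 thresholds = thresholds, use_cis = use_cis),
            class = "gene_copy_table")
}

#' Keep only genes with a copy-number value in every sample
#'
#' @param gct A `gene_copy_table`.
#' @return The filtered `gene_copy_table`.
#' @export
filter_genes_all_samples <- function(gct) {
  stopifnot(inherits(gct, "gene_copy_table"))
  keep <- rowSums(is.na(gct$values)) == 0L
  gct$values <- gct$values[keep, , drop = FALSE]
  gct$categories <- gct$categories[keep, , drop = FALSE]
  gct
}

#' Per-region aberration frequencies by sample group
#'
#' Computes, for each region (gene or SRO), the fraction of each group's
#' samples called gain and called loss, and for exactly two groups the
#' frequency differences (group 1 minus group 2).
#'
#' @param x A `gene_copy_table` or `sro_table`.
#' @param groups Named list of sample-identifier vectors.
#' @param thresholds,use_cis Used to call categories when `x` is an
#'   `sro_table` (a `gene_copy_table` already carries categories).
#' @return Data frame with one row per region and per-group `gain_`/`loss_`
#'   frequency columns (plus `gain_diff`/`loss_diff` for two groups).
#' @export
aberration_frequency <- function(x, groups,
                                 thresholds = aberration_thresholds(),
                                 use_cis = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  if (inherits(x, "gene_copy_table")) {
    cats <- x$categories
    info <- data.frame(region = rownames(cats), stringsAsFactors = FALSE)
  } else if (inherits(x, "sro_table")) {
    cats <- matrix(call_category(x$values, thresholds, use_cis),
                   nrow(x$values), dimnames = dimnames(x$values))
    info <- x$regions
  } else stop("aberration_frequency: x must be a gene_copy_table or sro_table")
  out <- info
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (!length(ids)) stop("aberration_frequency: empty group '", g, "'")
    if (!all(ids %in% colnames(cats)))
      stop("aberration_frequency: unknown sample(s) in group '", g, "'")
    sub <- cats[, ids, drop = FALSE]
    out[[paste0("gain_", g)]] <- rowMeans(sub == "gain")
    out[[paste0("loss_", g)]] <- rowMeans(sub == "loss")
  }
  if (length(groups) == 2L) {
    g <- names(groups)
    out$gain_diff <- out[[paste0("gain_", g[1L])]] - out[[paste0("gain_", g[2L])]]
    out$loss_diff <- out[[paste0("loss_", g[1L])]] - out[[paste0("loss_", g[2L])]]
  }
  out
}
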