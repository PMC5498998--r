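#' Recognized variant functional classes
#' @export
VARIANT_CLASSES <- c("nonsynonymous_SNV", "stopgain_SNV", "stoploss_SNV",
                     "frameshift_indel", "nonframeshift_indel",
                     "synonymous_SNV", "other")

#' Filter variant calls
#'
#' Retains calls with at least `min_alt_reads` alternative reads and discards
#' calls flagged as known polymorphisms unless they are also flagged as
#' clinically associated (clinically associated known polymorphisms are
#' kept).
#'
#' @param calls Data frame of variant calls with at least the columns
#'   `alt_read_count`, `known_polymorphism` and `clinically_associated`.
#' @param min_alt_reads Minimum number of alternative reads (inclusive).
#' @return The filtered data frame.
#' @export
filter_variants <- function(calls, min_alt_reads = 10) {
  stopifnot(is.data.frame(calls))
  for (f in c("alt_read_count", "known_polymorphism", "clinically_associated"))
    if (!f %in% names(calls))
      stop("filter_variants: missing required field '", f, "'")
  keep <- calls$alt_read_count >= min_alt_reads &
    (!calls$known_polymorphism | calls$clinically_associated)
  calls[keep, , drop = FALSE]
}

#' Is a variant non-synonymous?
#'
#' Non-synonymous variants are exactly: non-synonymous SNVs, stopgain SNVs,
#' stoploss SNVs and frameshift indels. Non-frameshift indels, synonymous
#' SNVs and other classes are not.
#'
#' @param variant_class Character vector of variant classes (see
#'   [VARIANT_CLASSES]).
#' @return Logical vector.
#' @export
is_nonsynonymous <- function(variant_class) {
  bad <- setdiff(unique(variant_class), VARIANT_CLASSES)
  if (length(bad))
    stop("is_nonsynonymous: unknown variant class(es): ",
         paste(bad, collapse = ", "))
  variant_class %in% c("nonsynonymous_SNV", "stopgain_SNV", "stoploss_SNV",
                       "frameshift_indel")
}

#' Per-sample non-synonymous variant loads
#'
#' @param calls Data frame of (already filtered) variant calls with columns
#'   `sample_id` and `variant_class`; optionally `phenotype`.
#' @param samples Optional character vector fixing the sample universe (so
#'   samples with zero retained variants report a load of 0).
#' @param target_bp Size in basepairs of the sequenced target region, used
#'   for the per-megabase rate. Required for rates; loads alone need none.
#' @return Data frame with `sample_id`, `n_nonsynonymous` and (if
#'   `target_bp` given) `rate_per_mb`.
#' @export
variant_load <- function(calls, samples = NULL, target_bp = NULL) {
  stopifnot(is.data.frame(calls))
  ns <- calls[is_nonsynonymous(calls$variant_class), , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  n <- vapply(samples, function(s) sum(ns$sample_id == s), integer(1))
  out <- data.frame(sample_id = samples, n_nonsynonymous = n,
                    stringsAsFactors = FALSE)
  if (!is.null(target_bp)) {
    if (target_bp <= 0) stop("variant_load: target_bp must be positive")
    out$rate_per_mb <- out$n_nonsynonymous / (target_bp / 1e6)
  }
  rownames(out) <- NULL
  out
}

#' The 96 trinucleotide substitution bins in COSMIC order
#'
#' Six pyrimidine-reference substitutions (C>A, C>G, C>T, T>A, T>C, T>G),
#' each in 16 flanking-base contexts ordered A, C, G, T at the 5' then 3'
#' position; labels look like `"A[C>T]G"`.
#'
#' @param pyrimidine_only If `FALSE`, also return the 96 purine-reference
#'   bins (for uncollapsed spectra).
#' @return Character vector of bin labels.
#' @export
spectrum_bins <- function(pyrimidine_only = TRUE) {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (!pyrimidine_only)
    subs <- c(subs, "G>T", "G>C", "G>A", "A>T", "A>G", "A>C")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(b) paste(rev(b), collapse = ""), ""))
}

#' 96-context mutation spectrum
#'
#' Counts single-nucleotide variants into the 96 trinucleotide substitution
#' bins. Contexts are given on the reference strand; purine-reference
#' substitutions are reverse-complemented into the pyrimidine convention when
#' `collapse_strand = TRUE` (with `FALSE`, a 192-bin spectrum is returned;
#' see [collapse_spectrum()]). Indels and other non-SNV calls are skipped,
#' with the number of skips recorded in the `n_skipped` attribute.
#'
#' @param calls Data frame with columns `ref`, `alt` and `context`.
#' @param collapse_strand Fold purine-reference substitutions into the
#'   pyrimidine-reference bins.
#' @return Object of class `mutation_spectrum`: data frame with `bin`,
#'   `count`, `proportion`; attribute `n_skipped`.
#' @export
mutation_spectrum <- function(calls, collapse_strand = TRUE) {
  stopifnot(is.data.frame(calls), all(c("ref", "alt", "context") %in% names(calls)))
  is_snv <- !is.na(calls$ref) & !is.na(calls$alt) &
    nchar(calls$ref) == 1L & nchar(calls$alt) == 1L &
    calls$ref %in% c("A", "C", "G", "T") & calls$alt %in% c("A", "C", "G", "T") &
    calls$ref != calls$alt
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L)
    message("mutation_spectrum: skipped ", n_skipped, " non-SNV call(s)")
  snv <- calls[is_snv, , drop = FALSE]
  if (nrow(snv)) {
    bad <- is.na(snv$context) | nchar(snv$context) != 3L |
      substr(snv$context, 2, 2) != snv$ref
    if (any(bad))
      stop("mutation_spectrum: ", sum(bad),
           " SNV call(s) with invalid trinucleotide context")
  }
  ref <- snv$ref; alt <- snv$alt; ctx <- snv$context
  if (collapse_strand && nrow(snv)) {
    pur <- ref %in% c("A", "G")
    ref[pur] <- chartr("ACGT", "TGCA", snv$ref[pur])
    alt[pur] <- chartr("ACGT", "TGCA", snv$alt[pur])
    ctx[pur] <- revcomp(snv$context[pur])
  }
  labels <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  bins <- spectrum_bins(pyrimidine_only = collapse_strand)
  counts <- table(factor(labels, levels = bins))
  total <- sum(counts)
  out <- data.frame(bin = bins, count = as.integer(counts),
                    proportion = if (total > 0) as.numeric(counts) / total else 0,
                    stringsAsFactors = FALSE)
  structure(out, n_skipped = n_skipped,
            class = c("mutation_spectrum", class(out)))
}

#' Collapse a spectrum to the pyrimidine-reference convention
#'
#' Folds purine-reference bins of a 192-bin spectrum into their
#' reverse-complement pyrimidine bins. Applying it to an already collapsed
#' 96-bin spectrum is the identity (the operation is an involution after one
#' application). Counts are conserved.
#'
#' @param spectrum A `mutation_spectrum`.
#' @return A 96-bin `mutation_spectrum`.
#' @export
collapse_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  bins96 <- spectrum_bins()
  counts <- stats::setNames(numeric(length(bins96)), bins96)
  for (i in seq_len(nrow(spectrum))) {
    b <- spectrum$bin[i]
    ref <- substr(b, 3, 3)
    if (ref %in% c("A", "G")) {
      alt <- substr(b, 5, 5)
      ctx <- paste0(substr(b, 1, 1), ref, substr(b, 7, 7))
      rc <- revcomp(ctx)
      b <- paste0(substr(rc, 1, 1), "[", chartr("AG", "TC", ref), ">",
                  chartr("ACGT", "TGCA", alt), "]", substr(rc, 3, 3))
    }
    counts[b] <- counts[b] + spectrum$count[i]
  }
  total <- sum(counts)
  out <- data.frame(bin = bins96, count = as.integer(counts),
                    proportion = if (total > 0) as.numeric(counts) / total else 0,
                    stringsAsFactors = FALSE)
  structure(out, n_skipped = attr(spectrum, "n_skipped"),
            class = c("mutation_spectrum", class(out)))
}

#' Compare variant loads between two groups (Wilcoxon rank-sum)
#'
#' Uses the exact two-sided rank-sum distribution when the combined sample
#' size is at most `exact_max_n` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param loads_a,loads_b Numeric vectors of per-sample loads.
#' @param exact_max_n Largest combined size for the exact test.
#' @return An object of class `htest` (see `stats::wilcox.test`).
#' @export
compare_loads <- function(loads_a, loads_b, exact_max_n = 25) {
  if (!length(loads_a) || !length(loads_b))
    stop("compare_loads: both groups must be non-empty")
  pooled <- c(loads_a, loads_b)
  if (all(pooled == pooled[1L]))  # degenerate: no evidence either way
    return(structure(list(statistic = c(W = NA_real_), p.value = 1,
                          method = "Wilcoxon rank sum test (degenerate)",
                          data.name = "loads_a and loads_b"),
                     class = "htest"))
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= exact_max_n) && !ties
  suppressWarnings(
    stats::wilcox.test(loads_a, loads_b, exact = exact, correct = TRUE))
}

#' Anti-correlation between variant load and copy-number aberration burden
#'
#' Spearman correlation of per-sample variant loads against per-sample
#' percentages of genome with aberrant copy number, with an exact permutation
#' p-value for n <= 9 (no ties) and the t-approximation otherwise.
#'
#' @param load_per_sample,cna_fraction_per_sample Numeric vectors over the
#'   same samples (matched by names when both are named).
#' @return List with `rho`, `p.value` and `n`.
#' @export
load_cna_anticorrelation <- function(load_per_sample, cna_fraction_per_sample) {
  x <- load_per_sample; y <- cna_fraction_per_sample
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (length(x) != length(y) || length(x) < 4)
    stop("load_cna_anticorrelation: need >= 4 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("load_cna_anticorrelation: constant vector, rho undefined")
  exact <- length(x) <= 9 && anyDuplicated(x) == 0L && anyDuplicated(y) == 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
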