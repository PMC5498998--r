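#' Read and write SEG files
#'
#' SEG files are tab-separated with columns sample, chromosome, start, end,
#' number of probes and segment mean, using 1-based inclusive coordinates;
#' they are converted to the internal 0-based half-open convention on read
#' and back on write.
#'
#' @param path File path.
#' @return `read_seg` returns a `copy_segments` data frame.
#' @export
read_seg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- c("sample_id", "chrom", "start", "end", "n_probes", "pcf_value")
  d$start <- d$start - 1L  # 1-based inclusive -> 0-based half-open
  class(d) <- c("copy_segments", class(d))
  d
}

#' @rdname read_seg
#' @param segments A `copy_segments` data frame.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(ID = segments$sample_id, chrom = segments$chrom,
                    loc.start = segments$start + 1L, loc.end = segments$end,
                    num.mark = segments$n_probes,
                    seg.mean = segments$pcf_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene set files
#'
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(out) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  out
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write feature x sample matrices as TSV
#'
#' First column holds feature identifiers; remaining columns are samples.
#'
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}

#' @rdname read_matrix_tsv
#' @param x Numeric matrix with row and column names.
#' @param feature_col Name of the identifier column on write.
#' @export
write_matrix_tsv <- function(x, path, feature_col = "feature") {
  d <- data.frame(rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- feature_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GCT expression matrix
#'
#' Supports the common version-1.2 layout (two header lines, then Name /
#' Description columns followed by samples).
#'
#' @param path File path.
#' @return Numeric matrix, features x samples.
#' @export
read_gct <- function(path) {
  d <- utils::read.delim(path, skip = 2, stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}

#' Read a variant call TSV
#'
#' Expects the columns produced by the panel generator (sample_id, gene,
#' chrom, pos, ref, alt, variant_class, alt_read_count, known_polymorphism,
#' clinically_associated, context).
#'
#' @param path File path.
#' @return Data frame of variant calls.
#' @export
read_variants_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(context = "character"))
}

#' Write a synthetic panel to disk in the pipeline's input formats
#'
#' Emits the sample annotation, variant TSV, probe-track TSV, true-segment
#' SEG, expression/miRNA/protein matrices, antibody map and gene sets (GMT),
#' so the pipeline can be run file-in/file-out.
#'
#' @param panel A `synthetic_panel`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(panel$annotations, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$variants, p("variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tracks <- data.frame(panel$probes, panel$probe_values, check.names = FALSE)
  utils::write.table(tracks, p("probe_tracks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seg(panel$truth$true_segments, p("true_segments.seg"))
  write_matrix_tsv(panel$expression, p("expression.tsv"), "gene")
  write_matrix_tsv(panel$mirna, p("mirna_counts.tsv"), "mirna")
  write_matrix_tsv(panel$protein, p("protein.tsv"), "antibody")
  utils::write.table(panel$antibody_map, p("antibody_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(panel$gene_sets, p("gene_sets.gmt"))
  utils::write.table(panel$gene_model, p("gene_model.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read probe tracks written by [write_panel()]
#'
#' @param path File path of a probe-track TSV (chrom, pos, then one column
#'   per sample).
#' @return List with `probes` (chrom/pos data frame) and `values` matrix.
#' @export
read_probe_tracks <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  list(probes = d[, c("chrom", "pos")],
       values = as.matrix(d[, -(1:2), drop = FALSE]))
}
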