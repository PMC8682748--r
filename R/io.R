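#' @name table-io
#' @title Tab-separated readers and writers for the pipeline's file formats
#'
#' @description
#' All files are plain TSV with headers and 1-based inclusive coordinates:
#'
#' * call tables: `chromosome, strand, start, end, read_name, log_lik_ratio,
#'   num_motifs, sequence` (the de-facto methylation-caller output layout);
#' * per-site tables: `position, called_reads, methylated_reads, frequency,
#'   masked, blacklist_hit`;
#' * variant tables (VCF-like): `CHROM, POS, REF, ALT, VAF, DP, QS`;
#' * read summaries: `read_name, length, mean_q, strand, is_supplementary,
#'   target, start, end`.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @param chrom Chromosome name used when writing variant tables.
NULL

tsv_write <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname table-io
#' @export
write_call_table <- function(x, path) tsv_write(x, path)

#' @rdname table-io
#' @export
read_call_table <- function(path) tsv_read(path)

#' @rdname table-io
#' @export
write_site_table <- function(x, path) tsv_write(x, path)

#' @rdname table-io
#' @export
read_site_table <- function(path) tsv_read(path)

#' @rdname table-io
#' @export
write_read_summary <- function(x, path) tsv_write(x, path)

#' @rdname table-io
#' @export
read_read_summary <- function(path) tsv_read(path)

#' @rdname table-io
#' @export
write_variant_table <- function(x, path, chrom = "chrM") {
  out <- data.frame(
    CHROM = chrom,
    POS = x$position,
    REF = x$ref_allele,
    ALT = x$alt_allele,
    VAF = x$vaf,
    DP = x$depth,
    QS = x$qs
  )
  tsv_write(out, path)
}

#' @rdname table-io
#' @export
read_variant_table <- function(path) {
  raw <- tsv_read(path)
  data.frame(
    position = raw$POS,
    ref_allele = raw$REF,
    alt_allele = raw$ALT,
    vaf = raw$VAF,
    depth = raw$DP,
    qs = raw$QS,
    stringsAsFactors = FALSE
  )
}
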