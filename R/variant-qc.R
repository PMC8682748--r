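#' Variant retention filter configuration
#'
#' Defaults follow the long-read variant-retention rules: depth >= 30,
#' variant allele fraction >= 10%, quality score >= 10 (all inclusive).
#' Two homoplasmy cutoffs coexist deliberately: >= 95% for concordance
#' classification, >= 0.9 for consensus/haplogroup use.
#'
#' @param min_depth Minimum read depth (default 30).
#' @param min_vaf Minimum variant allele fraction (default 0.10).
#' @param min_qs Minimum quality score (default 10).
#' @param homoplasmy_cutoff Allele fraction at or above which a variant is
#'   homoplasmic for concordance purposes (default 0.95).
#' @param consensus_cutoff Allele fraction at or above which a variant feeds
#'   the consensus sequence (default 0.9).
#' @return Object of class `variant_filter_config`.
#' @export
variant_filter_config <- function(min_depth = 30L, min_vaf = 0.10,
                                  min_qs = 10, homoplasmy_cutoff = 0.95,
                                  consensus_cutoff = 0.9) {
  stopifnot(min_vaf > 0, min_vaf <= homoplasmy_cutoff, homoplasmy_cutoff <= 1)
  structure(
    list(min_depth = min_depth, min_vaf = min_vaf, min_qs = min_qs,
         homoplasmy_cutoff = homoplasmy_cutoff,
         consensus_cutoff = consensus_cutoff),
    class = "variant_filter_config"
  )
}

#' Apply variant retention filters
#'
#' Retains single-nucleotide variants with `depth >= min_depth`,
#' `vaf >= min_vaf` and `qs >= min_qs` (all boundaries inclusive). Non-SNV
#' rows are dropped; their count is attached as attribute `n_non_snv`.
#' The filter is idempotent and order-independent.
#'
#' @param variants Variant table (columns `position`, `ref_allele`,
#'   `alt_allele`, `vaf`, `depth`, `qs`).
#' @param cfg A [variant_filter_config()].
#' @return Retained subset.
#' @export
filter_variants <- function(variants, cfg = variant_filter_config()) {
  snv <- nchar(variants$ref_allele) == 1L & nchar(variants$alt_allele) == 1L &
    variants$ref_allele != variants$alt_allele
  out <- variants[snv & variants$depth >= cfg$min_depth &
                    variants$vaf >= cfg$min_vaf &
                    variants$qs >= cfg$min_qs, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_non_snv") <- sum(!snv)
  out
}

#' Classify variants as homoplasmic or heteroplasmic
#'
#' @param vaf Numeric allele fractions in [0, 1].
#' @param cutoff Homoplasmy cutoff (default 0.95, boundary inclusive).
#' @return Character vector, `"homoplasmic"` or `"heteroplasmic"`.
#' @export
classify_homoplasmy <- function(vaf, cutoff = 0.95) {
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  ifelse(vaf >= cutoff, "homoplasmic", "heteroplasmic")
}

#' Concordance of a test variant set against a truth set
#'
#' Variants are keyed by (position, alt allele); a call at the right position
#' with the wrong allele counts as a miss. When `class_filter` is
#' `"homoplasmic"` the truth set is first restricted to variants with
#' `vaf >= cutoff`.
#'
#' @param truth,test Variant tables (columns `position`, `alt_allele`, and
#'   `vaf` for the class filter).
#' @param class_filter `"homoplasmic"` (default) or `"all"`.
#' @param cutoff Homoplasmy cutoff for the class filter (default 0.95).
#' @return List with `n_truth`, `n_detected` and `fraction`
#'   (`NA` with a warning when the filtered truth set is empty).
#' @export
concordance <- function(truth, test, class_filter = c("homoplasmic", "all"),
                        cutoff = 0.95) {
  class_filter <- match.arg(class_filter)
  if (class_filter == "homoplasmic") {
    truth <- truth[truth$vaf >= cutoff, , drop = FALSE]
  }
  key <- function(v) paste(v$position, v$alt_allele)
  n_truth <- nrow(truth)
  if (!n_truth) {
    warning("empty truth set: concordance undefined")
    return(list(n_truth = 0L, n_detected = 0L, fraction = NA_real_))
  }
  n_detected <- sum(key(truth) %in% key(test))
  list(n_truth = n_truth, n_detected = n_detected,
       fraction = n_detected / n_truth)
}
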