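#' Classify a sample's per-strand mapping bias group
#'
#' Samples are called `"Biased"` when at least 55% of reads align to one
#' strand, else `"LowBias"`. The rule is applied to the majority strand, so it
#' is symmetric under strand relabelling: an L-strand majority of 60% is
#' Biased just as an H-strand majority would be.
#'
#' @param h_fraction Fraction of reads mapped to the H strand, in [0, 1].
#' @param cutoff Majority-strand fraction at or above which a sample is
#'   Biased (default 0.55, boundary inclusive).
#' @return `"Biased"` or `"LowBias"` (vectorized).
#' @export
classify_bias_group <- function(h_fraction, cutoff = 0.55) {
  if (any(h_fraction < 0 | h_fraction > 1 | is.na(h_fraction))) {
    stop("h_fraction must lie in [0, 1]")
  }
  ifelse(pmax(h_fraction, 1 - h_fraction) >= cutoff, "Biased", "LowBias")
}

#' Coverage breadth: percent of positions covered by at least min_reads
#'
#' @param depth_by_position Integer vector of per-position depths for one
#'   strand (length = genome length).
#' @param min_reads Minimum depth for a position to count as covered
#'   (default 5, boundary inclusive).
#' @return Breadth in percent, in [0, 100].
#' @export
coverage_breadth <- function(depth_by_position, min_reads = 5L) {
  if (!length(depth_by_position)) stop("empty depth vector")
  100 * mean(depth_by_position >= min_reads)
}

#' Spearman correlation between read depth and methylation level
#'
#' Rank correlation with ties mid-ranked. The p-value is exact for n <= 9
#' with no ties, and uses the t approximation otherwise.
#'
#' @param depth Numeric vector of per-site depths.
#' @param methylation_pct Numeric vector of per-site methylation levels.
#' @return List with `rho`, `p` (two-sided) and `n`.
#' @export
depth_methylation_correlation <- function(depth, methylation_pct) {
  ok <- is.finite(depth) & is.finite(methylation_pct)
  depth <- depth[ok]
  methylation_pct <- methylation_pct[ok]
  n <- length(depth)
  if (n < 4L) stop("need at least 4 sites")
  if (stats::sd(depth) == 0 || stats::sd(methylation_pct) == 0) {
    stop("correlation undefined for constant input")
  }
  ties <- anyDuplicated(depth) > 0L || anyDuplicated(methylation_pct) > 0L
  ct <- suppressWarnings(stats::cor.test(
    depth, methylation_pct,
    method = "spearman", exact = (n <= 9L && !ties)
  ))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Per-strand bias report for one bisulfite sample
#'
#' Combines read-fraction bias classification, per-strand coverage breadth,
#' mean depth and per-strand depth-versus-methylation Spearman correlations
#' into a one-sample report.
#'
#' @param wgbs List as returned by [simulate_wgbs_counts()] (elements
#'   `coverage` and `cpg`), or an equivalently shaped list read from disk.
#' @param min_reads Breadth threshold (default 5 reads).
#' @return Object of class `strand_bias_report`: a list with
#'   `h_read_fraction`, `l_read_fraction`, `h_breadth`, `l_breadth`,
#'   `mean_depth`, `group` and `correlations` (per-strand list of
#'   [depth_methylation_correlation()] results, `NULL` where undefined).
#' @export
wgbs_bias_report <- function(wgbs, min_reads = 5L) {
  cov <- wgbs$coverage
  total <- sum(cov$h_depth) + sum(cov$l_depth)
  if (total == 0) stop("no coverage")
  h_frac <- sum(cov$h_depth) / total
  cors <- lapply(c(H = "H", L = "L"), function(s) {
    rows <- wgbs$cpg[wgbs$cpg$strand == s & wgbs$cpg$depth > 0, , drop = FALSE]
    tryCatch(
      depth_methylation_correlation(rows$depth, rows$methylation_pct),
      error = function(e) NULL
    )
  })
  structure(
    list(
      h_read_fraction = h_frac,
      l_read_fraction = 1 - h_frac,
      h_breadth = coverage_breadth(cov$h_depth, min_reads),
      l_breadth = coverage_breadth(cov$l_depth, min_reads),
      mean_depth = mean(cov$h_depth + cov$l_depth),
      group = classify_bias_group(h_frac),
      correlations = cors
    ),
    class = "strand_bias_report"
  )
}

#' @export
print.strand_bias_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<strand_bias_report> group: %s\n",
      "  reads H/L: %.1f%% / %.1f%%   breadth H/L: %.1f%% / %.1f%%\n",
      "  mean depth: %.1fx\n"
    ),
    x$group, 100 * x$h_read_fraction, 100 * x$l_read_fraction,
    x$h_breadth, x$l_breadth, x$mean_depth
  ))
  for (s in names(x$correlations)) {
    co <- x$correlations[[s]]
    if (!is.null(co)) {
      cat(sprintf("  depth~methylation (%s): rho = %.3f, p = %.3g (n = %d)\n",
                  s, co$rho, co$p, co$n))
    }
  }
  invisible(x)
}
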