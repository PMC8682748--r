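#' Simulate per-strand bisulfite coverage and methylation counts
#'
#' Emulates the strand-asymmetric coverage loss seen in bisulfite libraries of
#' the mitochondrial genome, where the cytosine-rich light (L) strand is
#' selectively degraded. Per-position depths are Poisson: mean `depth_h` on the
#' H strand, mean `depth_l * (1 - loss_l)` on the L strand. At CpG sites,
#' methylated read counts are Binomial(depth, `meth_truth`) plus an optional
#' Poisson(`noise_reads`) count of spurious methylated reads (capped at depth),
#' which yields the depth-dependent apparent methylation typical of noisy
#' low-coverage sites.
#'
#' @param genome A [circular_genome()].
#' @param depth_h,depth_l Mean per-position depth per strand before loss.
#' @param loss_l Fraction in [0, 1] of L-strand coverage lost.
#' @param seed Integer seed.
#' @param meth_truth True methylation fraction at every CpG (default 0).
#' @param noise_reads Expected spurious methylated reads per CpG row
#'   (default 0).
#' @return List with elements `coverage` (data.frame: `position`, `h_depth`,
#'   `l_depth`, one row per genome position) and `cpg` (data.frame: `position`,
#'   `strand`, `depth`, `methylated`, `methylation_pct`, two rows per CpG).
#' @export
simulate_wgbs_counts <- function(genome, depth_h = 100, depth_l = 100,
                                 loss_l = 0, seed = NULL,
                                 meth_truth = 0, noise_reads = 0) {
  stopifnot(
    inherits(genome, "circular_genome"),
    depth_h > 0, depth_l > 0, loss_l >= 0, loss_l <= 1,
    meth_truth >= 0, meth_truth <= 1, noise_reads >= 0
  )
  if (!is.null(seed)) set.seed(seed)
  L <- genome$length
  h_depth <- stats::rpois(L, depth_h)
  l_depth <- stats::rpois(L, depth_l * (1 - loss_l))
  coverage <- data.frame(position = seq_len(L), h_depth = h_depth,
                         l_depth = l_depth)

  cpg <- genome$cpg_positions
  n <- length(cpg)
  depth <- c(h_depth[cpg], l_depth[cpg])
  meth <- stats::rbinom(2L * n, depth, meth_truth)
  if (noise_reads > 0) {
    meth <- pmin(depth, meth + stats::rpois(2L * n, noise_reads))
  }
  cpg_tab <- data.frame(
    position = rep(cpg, 2L),
    strand = rep(c("H", "L"), each = n),
    depth = depth,
    methylated = meth,
    methylation_pct = ifelse(depth > 0, 100 * meth / depth, NA_real_),
    stringsAsFactors = FALSE
  )
  list(coverage = coverage, cpg = cpg_tab)
}
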