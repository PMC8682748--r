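#' Specification of the per-read LLR emission model
#'
#' Signal-level methylation callers emit, per read and per CpG group, a
#' log-likelihood ratio (LLR); positive values favour methylation. The
#' simulator draws LLRs from two Gaussians: `N(mu_meth, sigma)` for calls on
#' truly methylated molecules and `N(mu_unmeth, sigma)` otherwise. Two artifact
#' channels are available:
#'
#' * `fp_positions`/`fp_rate` — a fixed set of CpG positions whose calls are
#'   forced methylated with probability `fp_rate` irrespective of truth. This
#'   emulates recurrent sequence-specific false positives observed in
#'   unmethylated controls.
#' * `noise_m`, `noise_t`, `noise_b` — a global background channel whose
#'   per-call false-methylation probability is
#'   `(noise_m * exp(-noise_t * depth) + noise_b) / 100`, evaluated at the
#'   dataset's realized mean depth. This reproduces the empirically observed
#'   inverse relation between read depth and apparent methylation in
#'   unmethylated data; the decay law is taken as a simulation input because
#'   the physical mechanism of the noise is unknown.
#'
#' @param mu_meth,mu_unmeth Class means (require `mu_meth > mu_unmeth`).
#' @param sigma Common class standard deviation (> 0).
#' @param fp_positions Integer vector of 1-based CpG positions with inflated
#'   methylated-call probability.
#' @param fp_rate Probability in [0, 1] of an artifactual methylated call at
#'   `fp_positions`.
#' @param noise_m,noise_t,noise_b Background-noise decay parameters (percent
#'   scale); all zero disables the channel.
#' @return An object of class `llr_dist_spec`.
#' @export
llr_dist_spec <- function(mu_meth = 8, mu_unmeth = -8, sigma = 2,
                          fp_positions = integer(), fp_rate = 0,
                          noise_m = 0, noise_t = 0, noise_b = 0) {
  stopifnot(
    mu_meth > mu_unmeth, sigma > 0,
    fp_rate >= 0, fp_rate <= 1,
    noise_m >= 0, noise_t >= 0, noise_b >= 0
  )
  structure(
    list(
      mu_meth = mu_meth, mu_unmeth = mu_unmeth, sigma = sigma,
      fp_positions = as.integer(fp_positions), fp_rate = fp_rate,
      noise_m = noise_m, noise_t = noise_t, noise_b = noise_b
    ),
    class = "llr_dist_spec"
  )
}

#' Group neighbouring CpG sites as a joint-calling caller would
#'
#' Successive CpGs whose C positions are closer than `gap` bases are merged
#' into one group and receive a single LLR per read. Grouping is computed on
#' the linear coordinate order; the wrap-around pair is not merged.
#'
#' @param genome A [circular_genome()].
#' @param gap Grouping gap in bases (default 10).
#' @return data.frame with columns `group`, `start` (first C, 1-based),
#'   `end` (last G, 1-based inclusive), `num_motifs`, plus a list column
#'   `sites` of the member C positions.
#' @export
cpg_groups <- function(genome, gap = 10L) {
  p <- genome$cpg_positions
  if (!length(p)) {
    return(data.frame(group = integer(), start = integer(), end = integer(),
                      num_motifs = integer()))
  }
  new_group <- c(TRUE, diff(p) >= gap)
  gid <- cumsum(new_group)
  sites <- split(p, gid)
  out <- data.frame(
    group = seq_along(sites),
    start = vapply(sites, min, integer(1)),
    end = vapply(sites, max, integer(1)) + 1L,
    num_motifs = lengths(sites)
  )
  out$sites <- unname(sites)
  rownames(out) <- NULL
  out
}

#' Simulate per-read, per-CpG-group methylation calls
#'
#' For every read covering a CpG group in full, one call row is emitted. The
#' molecule's methylation state at the group is Bernoulli with probability
#' equal to the mean of `site_truth` over the group's member sites; artifact
#' channels of the [llr_dist_spec()] can force a methylated state. The LLR is
#' then drawn from the corresponding class Gaussian.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param genome A [circular_genome()].
#' @param site_truth Either a single fraction in [0, 1] applied to every CpG,
#'   or a numeric vector named by CpG position (1-based); unnamed vectors of
#'   length equal to the number of CpGs are matched positionally.
#' @param dist An [llr_dist_spec()].
#' @param seed Integer seed.
#' @param grouping_gap Grouping gap passed to [cpg_groups()].
#' @return data.frame call table with columns `chromosome`, `strand`, `start`,
#'   `end` (1-based inclusive group span), `read_name`, `log_lik_ratio`,
#'   `num_motifs`, `sequence`.
#' @export
simulate_methylation_calls <- function(reads, genome, site_truth, dist,
                                       seed = NULL, grouping_gap = 10L) {
  stopifnot(inherits(genome, "circular_genome"), inherits(dist, "llr_dist_spec"))
  cpg <- genome$cpg_positions
  truth <- normalize_site_truth(site_truth, cpg)
  if (!is.null(seed)) set.seed(seed)

  grp <- cpg_groups(genome, gap = grouping_gap)
  empty <- data.frame(
    chromosome = character(), strand = character(), start = integer(),
    end = integer(), read_name = character(), log_lik_ratio = numeric(),
    num_motifs = integer(), sequence = character(), stringsAsFactors = FALSE
  )
  if (!nrow(grp) || !nrow(reads)) return(empty)

  L <- genome$length
  grp$p_truth <- vapply(grp$sites, function(s) {
    mean(truth[as.character(s)])
  }, numeric(1))
  grp$has_fp <- vapply(grp$sites, function(s) {
    any(s %in% dist$fp_positions)
  }, logical(1))
  grp$span <- grp$end - grp$start  # bases beyond the first

  # realized mean depth drives the global background-noise probability
  mean_depth <- sum(pmin(reads$length, L)) / L
  q_noise <- (dist$noise_m * exp(-dist$noise_t * mean_depth) + dist$noise_b) / 100
  q_noise <- min(q_noise, 1)

  n_reads <- nrow(reads)
  n_grp <- nrow(grp)
  # read r (start s, length len) fully covers group g iff the group's span fits
  # inside the covered arc: offset of the group start from the read start,
  # measured forward around the circle, plus the span, within len - 1.
  off <- outer(grp$start, reads$start, function(gs, rs) (gs - rs) %% L)
  fits <- sweep(off, 1L, grp$span, `+`) <=
    matrix(pmin(reads$length, L) - 1L, nrow = n_grp, ncol = n_reads, byrow = TRUE)
  idx <- which(fits, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  gi <- idx[, 1L]
  ri <- idx[, 2L]
  n <- length(gi)

  p_state <- grp$p_truth[gi]
  meth <- stats::runif(n) < p_state
  if (dist$fp_rate > 0 && any(grp$has_fp)) {
    meth <- meth | (grp$has_fp[gi] & stats::runif(n) < dist$fp_rate)
  }
  if (q_noise > 0) {
    meth <- meth | (stats::runif(n) < q_noise)
  }
  llr <- stats::rnorm(n,
                      mean = ifelse(meth, dist$mu_meth, dist$mu_unmeth),
                      sd = dist$sigma)

  out <- data.frame(
    chromosome = genome$name,
    strand = reads$strand[ri],
    start = grp$start[gi],
    end = grp$end[gi],
    read_name = reads$read_name[ri],
    log_lik_ratio = llr,
    num_motifs = grp$num_motifs[gi],
    sequence = substring(genome$sequence, grp$start[gi], grp$end[gi]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$read_name, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# resolve the user-facing site_truth argument to a vector named by CpG position
normalize_site_truth <- function(site_truth, cpg_positions) {
  if (any(site_truth < 0 | site_truth > 1)) {
    stop("site_truth fractions must lie in [0, 1]")
  }
  if (length(site_truth) == 1L && is.null(names(site_truth))) {
    truth <- rep(as.numeric(site_truth), length(cpg_positions))
    names(truth) <- cpg_positions
    return(truth)
  }
  if (!is.null(names(site_truth))) {
    keys <- as.integer(names(site_truth))
    if (!all(keys %in% cpg_positions)) {
      stop("site_truth names must be CpG positions of the genome")
    }
    truth <- rep(0, length(cpg_positions))
    names(truth) <- cpg_positions
    truth[as.character(keys)] <- as.numeric(site_truth)
    return(truth)
  }
  if (length(site_truth) != length(cpg_positions)) {
    stop("unnamed site_truth must have one entry per CpG position")
  }
  truth <- as.numeric(site_truth)
  names(truth) <- cpg_positions
  truth
}
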