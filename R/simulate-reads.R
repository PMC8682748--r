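#' Specification of a simulated read population
#'
#' Two library regimes are modelled. `random_fragmentation` emulates shearing:
#' read starts uniform on the circle, lengths uniform within `length_range`.
#' `single_cut` emulates linearisation by a single-cutter restriction enzyme
#' (the mtDNA-enrichment strategy): every read starts at `cut_site` and a
#' fraction `full_length_fraction` of molecules are near-full-length
#' (>= 15,000 bases on a 16.6 kb genome).
#'
#' @param regime `"random_fragmentation"` or `"single_cut"`.
#' @param mean_depth Target mean per-position read depth.
#' @param cut_site 1-based start position used by the `single_cut` regime;
#'   default 14259 mirrors the reference origin rotation used for
#'   enzyme-linearised mtDNA libraries.
#' @param length_range Two-element numeric, min < max (bases).
#' @param quality_mean Mean per-read Phred quality.
#' @param full_length_fraction Fraction of `single_cut` reads drawn from the
#'   full-length mode (length >= `full_length_min`).
#' @param full_length_min Length (bases) above which a read counts as
#'   full-length.
#' @param strand_bias Probability that a read is assigned to the H strand.
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(regime = c("random_fragmentation", "single_cut"),
                          mean_depth = 50,
                          cut_site = 14259L,
                          length_range = c(4000, 17000),
                          quality_mean = 12,
                          full_length_fraction = 0.42,
                          full_length_min = 15000L,
                          strand_bias = 0.5,
                          seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(
    mean_depth > 0,
    length(length_range) == 2L, length_range[1L] < length_range[2L],
    full_length_fraction >= 0, full_length_fraction <= 1,
    strand_bias >= 0, strand_bias <= 1
  )
  structure(
    list(
      regime = regime, mean_depth = mean_depth, cut_site = as.integer(cut_site),
      length_range = length_range, quality_mean = quality_mean,
      full_length_fraction = full_length_fraction,
      full_length_min = as.integer(full_length_min),
      strand_bias = strand_bias, seed = seed
    ),
    class = "read_sim_spec"
  )
}

#' Simulate a read population on a circular genome
#'
#' Reads are emitted as alignment-style summaries. `start` is 1-based in
#' `[1, L]`; a read covers `length` consecutive positions along the circle, so
#' `end = start + length - 1` may exceed the genome length, which flags an
#' origin-spanning molecule. Per-read quality is Normal(`quality_mean`, 1.5)
#' truncated at zero; strand is Bernoulli(`strand_bias`).
#'
#' @param genome A [circular_genome()].
#' @param spec A [read_sim_spec()].
#' @return data.frame (one row per read) with columns `read_name`, `length`,
#'   `mean_q`, `strand`, `target`, `is_supplementary`, `orientation`,
#'   `start`, `end`.
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(genome, "circular_genome"), inherits(spec, "read_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- genome$length

  draw_lengths <- function(k) {
    if (spec$regime == "random_fragmentation") {
      len <- round(stats::runif(k, spec$length_range[1L], spec$length_range[2L]))
    } else {
      fl_lo <- min(spec$full_length_min, L)
      frag_hi <- min(spec$length_range[2L], spec$full_length_min - 1L)
      frag_lo <- min(spec$length_range[1L], frag_hi)
      full <- stats::runif(k) < spec$full_length_fraction
      len <- numeric(k)
      len[full] <- round(stats::runif(sum(full), fl_lo, L))
      len[!full] <- round(stats::runif(sum(!full), frag_lo, frag_hi))
    }
    pmin(as.integer(len), L)  # a read cannot exceed the circular molecule
  }
  # accumulate reads until the aligned bases meet the depth target, so the
  # realized mean depth tracks mean_depth to within one read's contribution
  target_bases <- spec$mean_depth * L
  len <- integer(0)
  repeat {
    batch <- max(16L, ceiling((target_bases - sum(len)) / mean(spec$length_range)))
    len <- c(len, draw_lengths(batch))
    csum <- cumsum(as.numeric(len))
    if (csum[length(len)] >= target_bases) {
      n <- which(csum >= target_bases)[1L]
      len <- len[seq_len(n)]
      break
    }
  }
  n <- length(len)
  start <- if (spec$regime == "random_fragmentation") {
    sample.int(L, n, replace = TRUE)
  } else {
    rep(spec$cut_site, n)
  }

  strand <- ifelse(stats::runif(n) < spec$strand_bias, "H", "L")
  data.frame(
    read_name = sprintf("read_%06d", seq_len(n)),
    length = as.integer(len),
    mean_q = pmax(0, stats::rnorm(n, spec$quality_mean, 1.5)),
    strand = strand,
    target = "mito",
    is_supplementary = FALSE,
    orientation = ifelse(strand == "H", "forward", "reverse"),
    start = as.integer(start),
    end = as.integer(start + len - 1L),
    stringsAsFactors = FALSE
  )
}

#' Per-position depth of a read set on the circle
#'
#' @param reads data.frame as returned by [simulate_reads()].
#' @param genome_length Circle length in bases.
#' @return Integer vector of length `genome_length`; element p is the number of
#'   reads covering position p.
#' @export
read_depth_profile <- function(reads, genome_length) {
  L <- as.integer(genome_length)
  if (!nrow(reads)) return(integer(L))
  s <- ((reads$start - 1L) %% L) + 1L
  e <- s + pmin(reads$length, L) - 1L
  wrap <- e > L
  starts <- c(s, rep(1L, sum(wrap)))
  ends <- c(ifelse(wrap, L, e), e[wrap] - L)
  ends <- pmin(ends, L)
  delta <- numeric(L + 1L)
  add_s <- tabulate(starts, nbins = L)
  add_e <- tabulate(ends + 1L, nbins = L + 1L)
  delta[seq_len(L)] <- add_s
  delta <- delta - add_e
  as.integer(cumsum(delta)[seq_len(L)])
}
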