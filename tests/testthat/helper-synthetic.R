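# Shared fixtures: small genomes and call tables built in code.

# tiny deterministic genome with CpGs at known positions
tiny_genome <- function() {
  # CpGs (C positions) at 3, 11, 21; no other CG dinucleotides, no wrap CG
  circular_genome("ATCGATTAATCGTTTTAAAACGTTAATTAATT", name = "tiny")
}

# mid-size random genome reused across tests
test_genome <- function(seed = 42, length = 4000, density = 0.03) {
  generate_genome(length, density, seed = seed)
}

# call table with every site at a common truth, convenient depth
make_calls <- function(genome, truth, depth = 60, seed = 1,
                       dist = llr_dist_spec(), regime = "single_cut") {
  spec <- read_sim_spec(regime, mean_depth = depth, seed = seed,
                        cut_site = 1L, quality_mean = 12)
  reads <- simulate_reads(genome, spec)
  simulate_methylation_calls(reads, genome, truth, dist, seed = seed + 1)
}

# manual grouped call rows for exact-arithmetic tests
call_row <- function(start, end, llr, num_motifs = 1L, read = "r1",
                     strand = "H") {
  data.frame(
    chromosome = "tiny", strand = strand, start = start, end = end,
    read_name = read, log_lik_ratio = llr, num_motifs = num_motifs,
    sequence = "", stringsAsFactors = FALSE
  )
}
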