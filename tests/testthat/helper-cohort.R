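# CpG positions that form their own calling group (no neighbour within the
# grouping gap); artifacts planted there stay confined to one site.
singleton_cpgs <- function(genome, gap = 10L) {
  grp <- cpg_groups(genome, gap = gap)
  grp$start[grp$num_motifs == 1L]
}

# Cohort sharing one reference genome: an unmethylated negative control with
# recurrent false-positive sites, null samples with variant-adjacent
# artifacts (reference-based and consensus-based call tables), and one
# half-methylated titration sample.
build_cohort <- function(seed = 101, depth = 60) {
  g <- generate_genome(8000, 0.03, seed = seed)
  single <- singleton_cpgs(g)
  fp <- sort(sample(single, 13))
  lone <- setdiff(single, fp)
  noise <- list(m = 2, t = 0.05, b = 0.3)

  nc_dist <- llr_dist_spec(fp_positions = fp, fp_rate = 0.5,
                           noise_m = noise$m, noise_t = noise$t,
                           noise_b = noise$b)
  nc_calls <- make_calls(g, 0, depth = depth, seed = seed + 1, dist = nc_dist)

  make_null_sample <- function(s) {
    hom_cpg <- lone[10 + s]
    het_cpg <- lone[40 + s]
    vpos <- c(hom_cpg + 3L, het_cpg - 2L)
    variants <- data.frame(
      position = vpos,
      ref_allele = substring(g$sequence, vpos, vpos),
      alt_allele = "N", vaf = c(1.0, 0.5), depth = 500, qs = 30,
      stringsAsFactors = FALSE
    )
    for (i in 1:2) {
      variants$alt_allele[i] <- setdiff(c("A", "T"),
                                        variants$ref_allele[i])[1]
    }
    # reference-based calls: artifacts at recurrent sites plus both
    # variant-adjacent CpGs
    ref_dist <- llr_dist_spec(fp_positions = c(fp, hom_cpg, het_cpg),
                              fp_rate = 0.5, noise_m = noise$m,
                              noise_t = noise$t, noise_b = noise$b)
    calls <- make_calls(g, 0, depth = depth, seed = seed + 10 * s,
                        dist = ref_dist)
    # consensus-based calls: the homoplasmic-variant artifact disappears
    cons <- build_consensus(g, variants, major_cutoff = 0.9 - 1e-9)
    cons_dist <- llr_dist_spec(fp_positions = c(fp, het_cpg), fp_rate = 0.5,
                               noise_m = noise$m, noise_t = noise$t,
                               noise_b = noise$b)
    cons_calls <- make_calls(cons, 0, depth = depth, seed = seed + 10 * s + 1,
                             dist = cons_dist)
    list(calls = calls, variants = variants, consensus_calls = cons_calls)
  }

  titration <- list(calls = make_calls(
    g, 0.5, depth = depth, seed = seed + 99,
    dist = llr_dist_spec(noise_m = noise$m, noise_t = noise$t,
                         noise_b = noise$b)))

  list(genome = g, fp = fp, nc_calls = nc_calls,
       samples = list(null_1 = make_null_sample(1),
                      null_2 = make_null_sample(2),
                      half = titration))
}
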