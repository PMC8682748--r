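test_that("generated genomes are deterministic and CpG positions survive a rescan", {
  g1 <- generate_genome(16569, 0.03, seed = 7)
  g2 <- generate_genome(16569, 0.03, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$cpg_positions, g2$cpg_positions)
  expect_equal(g1$length, 16569)
  # ~cpg_density * length sites
  expect_equal(length(g1$cpg_positions), round(0.03 * 16569))

  g3 <- generate_genome(1000, 0.05, seed = 3)
  # brute-force rescan of the emitted sequence
  expect_true(all(substring(g3$sequence, g3$cpg_positions,
                            g3$cpg_positions + 1) == "CG"))
  expect_identical(g3$cpg_positions, find_cpg_sites(g3$sequence))
  expect_true(all(diff(g3$cpg_positions) >= 2))
})

test_that("zero-density genomes contain no CpG dinucleotides, including the wrap pair", {
  g <- generate_genome(100, 0.0, seed = 1)
  expect_length(g$cpg_positions, 0)
  expect_false(grepl("CG", g$sequence))
  expect_false(substring(g$sequence, 100, 100) == "C" &&
                 substring(g$sequence, 1, 1) == "G")
  expect_error(generate_genome(50, 0.03), "length")
  expect_error(generate_genome(1000, 0.4), "cpg_density")
})

test_that("plant_variants respects counts, fractions and CpG proximity", {
  g <- test_genome()
  v <- plant_variants(g, 5, 2, c(0.5, 0.3), seed = 11)
  expect_equal(nrow(v), 7)
  expect_equal(sum(v$true_fraction == 1.0), 5)
  expect_setequal(v$true_fraction[v$true_fraction < 1], c(0.5, 0.3))
  expect_false(any(duplicated(v$position)))
  expect_true(all(v$ref_allele != v$alt_allele))
  expect_true(all(substring(g$sequence, v$position, v$position) == v$ref_allele))

  # single homoplasmic variant lies within 5 nt (circular) of some CpG
  v1 <- plant_variants(g, 1, 0, seed = 2)
  d <- min(circular_distance(v1$position, g$cpg_positions, g$length))
  expect_lte(d, 5)

  v2 <- plant_variants(g, 0, 1, c(0.5), seed = 3)
  expect_equal(v2$true_fraction, 0.5)
  expect_error(plant_variants(g, 0, 2, c(0.5), seed = 1), "length")
  expect_error(plant_variants(g, g$length + 1, 0, seed = 1), "more variants")
})

test_that("single-cut reads carry the requested full-length mode", {
  g <- generate_genome(16569, 0.02, seed = 9)
  spec <- read_sim_spec("single_cut", mean_depth = 100,
                        full_length_fraction = 0.42, seed = 21)
  reads <- simulate_reads(g, spec)
  expect_true(all(reads$start == spec$cut_site))
  expect_gte(mean(reads$length >= 15000), 0.30)
  # matching titration of the enzymatic protocol: ~42% +/- sampling error
  expect_lt(abs(mean(reads$length >= 15000) - 0.42), 0.12)
})

test_that("random fragmentation respects the length range and target depth", {
  g <- test_genome()
  spec <- read_sim_spec("random_fragmentation", mean_depth = 50,
                        length_range = c(800, 1200), seed = 5)
  reads <- simulate_reads(g, spec)
  expect_equal(sum(reads$length >= 4000), 0)
  expect_true(all(reads$length >= 800 & reads$length <= 1200))
  # total aligned bases / genome length within 10% of requested depth
  realized <- sum(pmin(reads$length, g$length)) / g$length
  expect_lt(abs(realized - 50) / 50, 0.1)
})

test_that("realized depth tracks the requested depth across seeds and regimes", {
  g <- test_genome()
  for (s in 1:10) {
    spec <- read_sim_spec("random_fragmentation", mean_depth = 30,
                          length_range = c(500, 1500), seed = s)
    reads <- simulate_reads(g, spec)
    dp <- read_depth_profile(reads, g$length)
    expect_lt(abs(mean(dp) - 30) / 30, 0.1)
  }
})

test_that("unmethylated truth yields essentially no methylated calls", {
  g <- test_genome()
  calls <- make_calls(g, 0, depth = 60, seed = 8)
  frac_meth <- mean(calls$log_lik_ratio >= 5)
  # Gaussian tail: P(N(-8, 2) >= 5) ~ 4e-11
  expect_lt(frac_meth, 0.001)
  sites <- call_table_frequencies(calls, g)
  expect_lt(genome_mean_methylation(sites), 0.5)
})

test_that("saturated truth yields near-unit frequencies", {
  g <- test_genome()
  calls <- make_calls(g, 1, depth = 40, seed = 12)
  sites <- call_table_frequencies(calls, g)
  expect_gt(genome_mean_methylation(sites), 99)
})

test_that("call tables are deterministic under a fixed seed and conserve identity", {
  g <- test_genome()
  c1 <- make_calls(g, 0.5, depth = 20, seed = 31)
  c2 <- make_calls(g, 0.5, depth = 20, seed = 31)
  expect_identical(c1, c2)
  spec <- read_sim_spec("single_cut", mean_depth = 20, seed = 31, cut_site = 1L)
  reads <- simulate_reads(g, spec)
  expect_true(all(c1$read_name %in% reads$read_name))
  grp <- cpg_groups(g)
  expect_true(all(c1$start %in% grp$start))
})

test_that("grouped calls merge CpGs closer than the grouping gap", {
  g <- tiny_genome()  # CpGs at 3, 11 (gap 8) and 21 (gap 10)
  grp <- cpg_groups(g, gap = 10)
  expect_equal(nrow(grp), 2)
  expect_equal(grp$num_motifs, c(2L, 1L))
  expect_equal(grp$start, c(3L, 21L))
  expect_equal(grp$end, c(12L, 22L))
  # a wider gap merges everything
  expect_equal(nrow(cpg_groups(g, gap = 11)), 1)
})

test_that("wgbs counts reproduce the requested strand asymmetry", {
  g <- test_genome()
  w <- simulate_wgbs_counts(g, depth_h = 100, depth_l = 100, loss_l = 0.9,
                            seed = 14)
  expect_lt(abs(mean(w$coverage$l_depth) - 10), 2)
  expect_lt(abs(mean(w$coverage$h_depth) - 100), 5)
  expect_error(simulate_methylation_calls(data.frame(), g, 1.5,
                                          llr_dist_spec()),
               "site_truth")
})
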