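mk_sites <- function(positions, frequencies, called = 100L) {
  data.frame(
    position = as.integer(positions),
    called_reads = called,
    methylated_reads = as.integer(round(frequencies * called)),
    frequency = frequencies,
    masked = FALSE,
    blacklist_hit = FALSE
  )
}

mk_variant <- function(position, vaf, ref = "A", alt = "G", depth = 100,
                       qs = 30) {
  data.frame(position = as.integer(position), ref_allele = ref,
             alt_allele = alt, vaf = vaf, depth = depth, qs = qs,
             stringsAsFactors = FALSE)
}

test_that("blacklist uses the sample sd and a strict cutoff", {
  # all-zero control: sd = 0, nothing strictly above the mean
  bl0 <- build_blacklist(mk_sites(1:10, rep(0, 10)))
  expect_length(bl0$positions, 0)

  # frequencies [0 x 9, 1.0]: mean 0.1, sd sqrt(0.1), cutoff ~ 0.732
  bl <- build_blacklist(mk_sites(1:10, c(rep(0, 9), 1.0)))
  expect_equal(bl$nc_mean, 0.1)
  expect_equal(bl$nc_sd, sqrt(0.1))
  expect_equal(bl$cutoff, 0.1 + 2 * sqrt(0.1))
  expect_equal(bl$positions, 10L)

  # a site exactly at the cutoff survives (strictly greater)
  f <- c(rep(0, 9), 1.0)
  cut <- mean(f) + 2 * sd(f)
  sites <- mk_sites(1:11, c(f, cut))
  bl2 <- build_blacklist(mk_sites(1:10, f))
  flagged <- apply_blacklist(sites, bl2)
  expect_false(flagged$blacklist_hit[11])
  expect_error(build_blacklist(mk_sites(1, 0)), "2 negative-control sites")
})

test_that("recurrent false-positive positions are recovered by the blacklist", {
  g <- test_genome(length = 8000, density = 0.03)
  set.seed(18)
  # artifacts at CpGs that form their own calling group, so the inflation
  # stays confined to exactly those sites
  fp <- sort(sample(singleton_cpgs(g), 13))
  dist <- llr_dist_spec(fp_positions = fp, fp_rate = 0.5)
  calls <- make_calls(g, 0, depth = 100, seed = 19, dist = dist)
  nc_sites <- call_table_frequencies(calls, g)
  bl <- build_blacklist(nc_sites)
  expect_setequal(bl$positions, fp)
})

test_that("proximity masking is window-inclusive, vaf-strict and circular", {
  L <- 16569
  expect_equal(proximity_mask(100L, mk_variant(105, 0.5), genome_length = L),
               100L)
  expect_length(proximity_mask(100L, mk_variant(106, 0.5), genome_length = L),
                0)
  # heteroplasmy cutoff is strict: vaf = 0.9 is not masked
  expect_length(proximity_mask(100L, mk_variant(105, 0.9), genome_length = L),
                0)
  # circular wrap: CpG 3 vs variant 16568 -> distance 4
  expect_equal(proximity_mask(3L, mk_variant(16568, 0.3), genome_length = L),
               3L)
})

test_that("proximity masking agrees with a brute-force circular scan", {
  set.seed(23)
  L <- 16569L
  cpg <- sort(sample.int(L, 400))
  vars <- mk_variant(sample.int(L, 30), runif(30))
  got <- proximity_mask(cpg, vars, genome_length = L)
  het <- vars$position[vars$vaf < 0.9]
  want <- integer()
  for (p in cpg) {
    for (v in het) {
      d <- min(abs(p - v), L - abs(p - v))
      if (d <= 5) { want <- c(want, p); break }
    }
  }
  expect_identical(got, want)
})

test_that("consensus substitution carries major alleles and rescans CpGs", {
  g <- tiny_genome()  # CpGs at 3, 11, 21
  # C->T at position 11 with vaf 1.0 destroys that CpG
  cons <- build_consensus(g, mk_variant(11, 1.0, ref = "C", alt = "T"))
  expect_equal(cons$length, g$length)
  expect_setequal(cons$cpg_positions, c(3L, 21L))
  expect_equal(substring(cons$sequence, 11, 11), "T")

  # minor allele is ignored
  same <- build_consensus(g, mk_variant(11, 0.3, ref = "C", alt = "T"))
  expect_identical(same$sequence, g$sequence)

  # no variants: identity
  none <- build_consensus(g, mk_variant(11, 1.0)[0, ])
  expect_identical(none$sequence, g$sequence)

  # idempotence: applying the same variants to the consensus changes nothing
  # (the ref allele no longer matches, which warns, but the sequence is stable)
  expect_identical(suppressWarnings(
    build_consensus(cons, mk_variant(11, 1.0, ref = "C", alt = "T"))$sequence),
    cons$sequence)

  conflict <- rbind(mk_variant(11, 1.0, ref = "C", alt = "T"),
                    mk_variant(11, 0.95, ref = "C", alt = "A"))
  expect_error(build_consensus(g, conflict), "conflicting")
})

test_that("masking and blacklisting only set flags, never alter frequencies", {
  sites <- mk_sites(c(10, 20, 30), c(0.1, 0.5, 0.9))
  out <- apply_mask(apply_blacklist(sites, c(20L)), c(30L))
  expect_identical(out$frequency, sites$frequency)
  expect_identical(out$called_reads, sites$called_reads)
  expect_equal(out$blacklist_hit, c(FALSE, TRUE, FALSE))
  expect_equal(out$masked, c(FALSE, FALSE, TRUE))
})

test_that("consensus recalling clears variant-adjacent false positives", {
  g <- test_genome(length = 6000)
  # homoplasmic variant 4 nt from a CpG
  cpg <- g$cpg_positions[20]
  vpos <- cpg + 4L
  ref_base <- substring(g$sequence, vpos, vpos)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  variants <- data.frame(position = vpos, ref_allele = ref_base,
                         alt_allele = alt, vaf = 1.0, depth = 500, qs = 30,
                         stringsAsFactors = FALSE)

  # reference-based calling: variant-induced LLR inflation at the nearby CpG
  dist_ref <- llr_dist_spec(fp_positions = cpg, fp_rate = 0.9)
  calls_ref <- make_calls(g, 0, depth = 80, seed = 31, dist = dist_ref)
  sites_ref <- call_table_frequencies(calls_ref, g)

  # consensus-based calling: artifact gone
  cons <- build_consensus(g, variants)
  calls_cons <- make_calls(cons, 0, depth = 80, seed = 32)
  sites_cons <- call_table_frequencies(calls_cons, cons)

  chk <- consensus_recall_check(sites_ref, sites_cons, variants,
                                cutoff = 0.1, genome_length = g$length)
  expect_true(cpg %in% chk$flagged$cpg_position)
  expect_true(all(chk$flagged$resolved))
  expect_gte(chk$n_removed, 1)

  # heteroplasmic variants are the mask's job, not the recall's
  het <- variants
  het$vaf <- 0.5
  chk_het <- consensus_recall_check(sites_ref, sites_cons, het,
                                    cutoff = 0.1, genome_length = g$length)
  expect_equal(nrow(chk_het$flagged), 0)
  expect_true(cpg %in% proximity_mask(g$cpg_positions, het,
                                      genome_length = g$length))

  # no variants: empty report
  none <- consensus_recall_check(sites_ref, sites_cons, variants[0, ],
                                 cutoff = 0.1, genome_length = g$length)
  expect_equal(nrow(none$flagged), 0)
})
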