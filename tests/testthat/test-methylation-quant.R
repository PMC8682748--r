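test_that("binarization is inclusive at the threshold and symmetric", {
  expect_equal(binarize_call(5.0, 5), "methylated")
  expect_equal(binarize_call(-5.0, 5), "unmethylated")
  expect_equal(binarize_call(2.5, 5), "uncalled")
  expect_equal(binarize_call(2.5, 2.5), "methylated")  # caller default threshold
  expect_equal(binarize_call(0, 5, mode = "two_way"), "unmethylated")
  expect_equal(binarize_call(5, 5, mode = "two_way"), "methylated")
  expect_error(binarize_call(1, 0), "threshold")
})

test_that("group splitting fans out to member CpGs and preserves evidence", {
  cpg <- c(100L, 107L, 114L, 300L)
  call3 <- call_row(100, 115, llr = 8, num_motifs = 3)
  out <- split_groups(call3, cpg)
  expect_equal(out$position, c(100L, 107L, 114L))
  expect_equal(out$log_lik_ratio, rep(8, 3))
  expect_true(all(binarize_call(out$log_lik_ratio) == "methylated"))

  # num_motifs = 1 is the identity
  call1 <- call_row(300, 301, llr = -9)
  out1 <- split_groups(call1, cpg)
  expect_equal(out1$position, 300L)

  # evidence conservation over a mixed table
  mixed <- rbind(call3, call1, call_row(100, 115, llr = -2, num_motifs = 3,
                                        read = "r2"))
  expect_equal(nrow(split_groups(mixed, cpg)), sum(mixed$num_motifs))

  # motif-count mismatch is a data-integrity error
  bad <- call_row(100, 115, llr = 1, num_motifs = 2)
  expect_error(split_groups(bad, cpg), "num_motifs")
})

test_that("a group of two close CpGs called unmethylated yields two unmethylated sites", {
  cpg <- c(10L, 16L)
  out <- split_groups(call_row(10, 17, llr = -9, num_motifs = 2), cpg)
  expect_equal(out$position, c(10L, 16L))
  expect_true(all(binarize_call(out$log_lik_ratio) == "unmethylated"))
})

test_that("site frequencies equal exact fractions and drop uncalled evidence", {
  calls <- data.frame(
    position = rep(50L, 12),
    read_name = paste0("r", 1:12),
    strand = "H",
    log_lik_ratio = c(rep(8, 3), rep(-8, 7), 2, -2),  # 2 uncalled
    stringsAsFactors = FALSE
  )
  s <- site_frequency(calls, threshold = 5)
  expect_equal(s$called_reads, 10L)
  expect_equal(s$methylated_reads, 3L)
  expect_equal(s$frequency, 0.30)

  s0 <- site_frequency(data.frame(position = rep(1L, 12),
                                  read_name = paste0("r", 1:12), strand = "H",
                                  log_lik_ratio = rep(-8, 12)))
  expect_equal(s0$frequency, 0)
})

test_that("site frequencies match a brute-force recount of the raw call table", {
  g <- test_genome()
  calls <- make_calls(g, 0.4, depth = 15, seed = 77)
  sites <- call_table_frequencies(calls, g, threshold = 5)

  # independent oracle: expand every group row by scanning the genome string
  oracle <- new.env()
  for (i in seq_len(nrow(calls))) {
    span <- calls$start[i]:calls$end[i]
    cs <- span[substring(g$sequence, span, span + 1) == "CG"]
    for (p in cs) {
      llr <- calls$log_lik_ratio[i]
      st <- if (llr >= 5) "m" else if (llr <= -5) "u" else next
      key <- as.character(p)
      cur <- mget(key, envir = oracle, ifnotfound = list(c(m = 0, u = 0)))[[1]]
      cur[st] <- cur[st] + 1
      assign(key, cur, envir = oracle)
    }
  }
  for (j in seq_len(nrow(sites))) {
    cnt <- get(as.character(sites$position[j]), envir = oracle)
    expect_equal(sites$called_reads[j], unname(cnt["m"] + cnt["u"]))
    expect_equal(sites$methylated_reads[j], unname(cnt["m"]))
  }
  expect_equal(nrow(sites), length(ls(oracle)))
})

test_that("raising the threshold never increases any site's called reads", {
  g <- test_genome()
  calls <- make_calls(g, 0.5, depth = 20, seed = 55,
                      dist = llr_dist_spec(mu_meth = 4, mu_unmeth = -4,
                                           sigma = 3))
  split <- split_groups(calls, g$cpg_positions)
  s_lo <- site_frequency(split, threshold = 2.5)
  s_hi <- site_frequency(split, threshold = 5)
  common <- intersect(s_lo$position, s_hi$position)
  expect_true(all(
    s_hi$called_reads[match(common, s_hi$position)] <=
      s_lo$called_reads[match(common, s_lo$position)]
  ))
  expect_true(all(s_hi$position %in% s_lo$position))
})

test_that("genome mean methylation filters masked and blacklisted sites", {
  sites <- data.frame(
    position = c(10L, 20L, 30L),
    called_reads = c(10L, 10L, 10L),
    methylated_reads = c(0L, 0L, 3L),
    frequency = c(0, 0, 0.3),
    masked = FALSE, blacklist_hit = FALSE
  )
  expect_equal(genome_mean_methylation(sites), 10)
  sites$blacklist_hit[3] <- TRUE
  expect_equal(genome_mean_methylation(sites), 0)
  expect_equal(genome_mean_methylation(sites, include_masked = TRUE), 10)
  sites$masked <- TRUE
  sites$blacklist_hit <- TRUE
  expect_error(genome_mean_methylation(sites), "no unmasked sites")
})

test_that("known mixtures are recovered within binomial sampling error", {
  g <- test_genome(length = 3000)
  calls <- make_calls(g, 0.25, depth = 1000, seed = 99)
  sites <- call_table_frequencies(calls, g)
  expect_gte(min(sites$called_reads), 500)
  expect_true(all(abs(sites$frequency - 0.25) < 0.09))
  expect_lt(abs(genome_mean_methylation(sites) - 25), 1)
})
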