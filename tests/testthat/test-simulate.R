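test_that("generated panels implant exactly the requested diagnostic sites", {
  gen0 <- generate_panel(c(A = 2, B = 2), genome_len = 4000, n_sites = 0,
                         within_group_snps = 10, seed = 1)
  expect_equal(nrow(gen0$sites), 0)
  # with no fixed differences the caller finds nothing
  aln0 <- align_to_anchor(gen0$panel, gen0$anchor_id)
  expect_equal(nrow(call_diagnostic_sites(aln0, "A", "B")), 0)

  gen <- generate_panel(c(A = 5, B = 5), genome_len = 120000, n_sites = 157,
                        within_group_snps = 20, seed = 1)
  expect_equal(nrow(gen$sites), 157)
  expect_false(is.unsorted(gen$sites$anchor_pos, strictly = TRUE))
  expect_true(all(gen$sites$allele_A != gen$sites$allele_B))
  expect_error(generate_panel(c(A = 2, B = 2), genome_len = 1000,
                              n_sites = 200, seed = 1),
               "genome_len/10")
})

test_that("fragment sampling is deterministic, length-calibrated and within bounds", {
  g <- random_genome(30000, seed = 5)
  fr1 <- sample_fragments(g, 10000, meanlog = log(75), sdlog = 0.3, seed = 2)
  fr2 <- sample_fragments(g, 10000, meanlog = log(75), sdlog = 0.3, seed = 2)
  expect_identical(fr1, fr2)
  expect_true(all(fr1$len >= 20 & fr1$len <= 500))
  expect_true(all(fr1$start >= 1 & fr1$start + fr1$len - 1 <= 30000))
  # empirical mean within 3 SE of the truncated-lognormal mean
  x <- exp(log(75) + 0.3^2 / 2) # truncation barely matters at these bounds
  se <- sd(fr1$len) / sqrt(nrow(fr1))
  expect_lt(abs(mean(fr1$len) - x), 3 * se + 0.5) # +0.5 for rounding to bp
  expect_equal(nrow(sample_fragments(g, 0, seed = 1)), 0)
  # strand-resolved sequence matches the source coordinates
  i <- which(fr1$strand == "-")[1]
  expect_equal(fr1$seq[i],
               revcomp(substr(g, fr1$start[i], fr1$start[i] + fr1$len[i] - 1)))
})

test_that("deamination follows e + d0*exp(-lambda*i) at both termini", {
  g <- random_genome(30000, seed = 6)
  fr0 <- sample_fragments(g, 50000, seed = 7)
  fr <- apply_damage(fr0, d0 = 0.3, lambda = 0.3, e = 0.01, seq_error = 0,
                     seed = 8)
  ref <- substring(g, fr0$start, fr0$start + fr0$len - 1)
  ref[fr0$strand == "-"] <- revcomp(ref[fr0$strand == "-"])
  rate_at <- function(pos) {
    rb <- substr(ref, pos + 1, pos + 1)
    qb <- substr(fr$seq, pos + 1, pos + 1)
    k <- sum(rb == "C" & qb == "T"); n <- sum(rb == "C")
    c(k / n, n)
  }
  for (pos in c(0, 10)) {
    p_true <- 0.01 + 0.3 * exp(-0.3 * pos)
    obs <- rate_at(pos)
    se <- sqrt(p_true * (1 - p_true) / obs[2])
    expect_lt(abs(obs[1] - p_true), 3 * se)
  }
  # 3' G->A mirror at the terminal base
  last_ref <- substr(ref, fr0$len, fr0$len)
  last_read <- substr(fr$seq, fr0$len, fr0$len)
  pg <- mean(last_read[last_ref == "G"] == "A")
  expect_lt(abs(pg - 0.31), 3 * sqrt(0.31 * 0.69 / sum(last_ref == "G")))
  # identity when all rates are zero
  fr_id <- apply_damage(fr0, d0 = 0, lambda = 0.3, e = 0, seq_error = 0,
                        seed = 9)
  expect_identical(fr_id$seq, fr0$seq)
  expect_true(all(fr_id$n_damage_5p == 0))
})

test_that("paired reads carry adapter on read-through and round-trip through merging", {
  frag80 <- random_genome(80, seed = 10)
  frag500 <- random_genome(500, seed = 11)
  reads <- to_paired_reads(
    data.frame(seq = c(frag80, frag500), stringsAsFactors = FALSE),
    read_len = 250
  )
  # short insert: both mates end in adapter sequence
  expect_equal(substr(reads$mate1[1], 81, 100), substr(SIM_ADAPTER, 1, 20))
  expect_equal(substr(reads$mate2[1], 81, 100), substr(SIM_ADAPTER, 1, 20))
  # fragment of exactly 2x read_len: no adapter, no overlap
  expect_equal(reads$mate1[2], substr(frag500, 1, 250))
  expect_equal(reads$mate2[2], revcomp(substr(frag500, 251, 500)))
  mg <- merge_pairs(reads)
  expect_equal(mg$counts[["merged"]], 1L)
  expect_equal(mg$counts[["unmerged"]], 1L)
  expect_equal(mg$merged$seq[1], frag80) # exact reconstruction at zero error
})

test_that("repeat arrays have the configured length and divergence", {
  arr0 <- generate_repeat_array(173, 20, 0, seed = 12)
  expect_equal(arr0$array, strrep(arr0$consensus, 20))
  arr <- generate_repeat_array(173, 200, 0.05, seed = 13)
  expect_equal(nchar(arr$array), 173 * 200)
  copies <- substring(arr$array, 173 * (0:199) + 1, 173 * (1:200))
  hd <- vapply(copies, function(cp) {
    sum(strsplit(cp, "")[[1]] != strsplit(arr$consensus, "")[[1]])
  }, numeric(1))
  exp_hd <- 0.05 * 173
  se <- sqrt(173 * 0.05 * 0.95 / 200)
  expect_lt(abs(mean(hd) - exp_hd), 3 * se)
})

test_that("background fragments are labelled and empty draws return empty frames", {
  bg <- generate_background("random", 50, seed = 14)
  expect_equal(nrow(bg), 50)
  expect_true(all(bg$source_id == "background"))
  expect_equal(nrow(generate_background("random", 0, seed = 14)), 0)
})

test_that("a full simulated read set is byte-deterministic and truth-resolvable", {
  gen <- generate_panel(c(A = 2, B = 2), genome_len = 8000, n_sites = 40,
                        within_group_snps = 5, seed = 15)
  cfg <- simulation_config(seed = 16, n_fragments = 500,
                           mixture = c(A = 0.6, B = 0.4),
                           background_frac = 0.2, duplicate_rate = 0.2)
  s1 <- simulate_readset(cfg, gen$panel)
  s2 <- simulate_readset(cfg, gen$panel)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_readset(simulation_config(seed = 17, n_fragments = 500,
                                           mixture = c(A = 0.6, B = 0.4)),
                         gen$panel)
  expect_false(identical(s1$reads$mate1, s3$reads$mate1))
  # every read id resolves to exactly one truth record
  expect_setequal(s1$reads$read_id, s1$truth$read_id)
  expect_false(anyDuplicated(s1$truth$read_id) > 0)
  # mixture groups and background both present with plausible shares
  expect_setequal(setdiff(unique(s1$truth$group), "background"), c("A", "B"))
  # duplicates are exact copies of their parent fragment
  dups <- s1$truth$read_id[s1$truth$is_duplicate]
  parents <- sub("_dup1$", "", dups)
  expect_equal(s1$fragments$seq[match(dups, s1$fragments$read_id)],
               s1$fragments$seq[match(parents, s1$fragments$read_id)])
  # FASTQ round trip preserves ids and sequences
  d <- withr::local_tempdir()
  paths <- write_fastq_pairs(s1$reads, file.path(d, "s1"))
  back <- read_fastq_pairs(file.path(d, "s1_R1.fastq.gz"),
                           file.path(d, "s1_R2.fastq.gz"))
  expect_equal(back, s1$reads)
})

test_that("downstream deduplication removes approximately the duplicate fraction", {
  gen <- generate_panel(c(A = 1, B = 1), genome_len = 20000, n_sites = 0,
                        within_group_snps = 0, seed = 18)
  cfg <- simulation_config(seed = 19, n_fragments = 3000,
                           mixture = c(A = 1), background_frac = 0,
                           duplicate_rate = 0.2, d0 = 0, e = 0, seq_error = 0)
  sim <- simulate_readset(cfg, gen$panel)
  mg <- merge_pairs(sim$reads)
  al <- map_reads(mg$merged, gen$panel$seq[[1]])
  dd <- deduplicate(al)
  removed <- attr(dd, "n_duplicates")
  # every emitted duplicate whose molecule mapped shares coordinates and
  # sequence with its parent, so at least those are removed; independent
  # fragments may collide and add a few more
  n_dup_mapped <- sum(sim$truth$is_duplicate[match(al$read_id,
                                                   sim$truth$read_id)])
  expect_gte(removed, n_dup_mapped)
  expect_lt(abs(removed - 0.2 * 3000) / 3000, 3 * sqrt(0.2 * 0.8 / 3000) + 0.01)
})
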