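test_that("pair merging handles read-through, non-overlap and empty inserts", {
  frag <- random_genome(80, seed = 41)
  reads <- to_paired_reads(data.frame(seq = frag, stringsAsFactors = FALSE),
                           read_len = 250)
  mg <- merge_pairs(reads)
  expect_equal(mg$merged$seq, frag)
  # 0 bp insert (mates are pure adapter) is discarded as empty
  ad_reads <- data.frame(read_id = "empty1",
                         mate1 = strrep(SIM_ADAPTER, 3),
                         mate2 = strrep(SIM_ADAPTER, 3),
                         stringsAsFactors = FALSE)
  ad_reads$mate1 <- substr(ad_reads$mate1, 1, 60)
  ad_reads$mate2 <- substr(ad_reads$mate2, 1, 60)
  mg2 <- merge_pairs(ad_reads)
  expect_equal(mg2$counts[["discarded"]], 1L)
  # non-overlapping 500 bp fragment with 2 x 250 reads stays unmerged
  frag500 <- random_genome(500, seed = 42)
  mg3 <- merge_pairs(to_paired_reads(data.frame(seq = frag500), read_len = 250))
  expect_equal(mg3$counts[["unmerged"]], 1L)
  # count conservation: input = merged + unmerged + discarded
  all3 <- rbind(reads, ad_reads,
                to_paired_reads(data.frame(seq = frag500), read_len = 250))
  mgA <- merge_pairs(all3)
  expect_equal(mgA$counts[["input"]],
               sum(mgA$counts[c("merged", "unmerged", "discarded")]))
  # a mid-overlap sequencing mismatch is tolerated and mate 1 wins
  fragA <- random_genome(300, seed = 43)
  reads2 <- to_paired_reads(data.frame(seq = fragA), read_len = 250)
  substr(reads2$mate2, 100, 100) <- "A" # damage the second mate inside overlap
  mg4 <- merge_pairs(reads2)
  expect_equal(mg4$merged$seq, fragA)
})

test_that("mapping recovers exact coordinates, strands and mismatch counts", {
  g <- random_genome(20000, seed = 44)
  frag <- substr(g, 1000, 1070)
  al <- map_reads(c(fwd = frag, rev = revcomp(frag)), g)
  expect_equal(al$start, c(1000, 1000))
  expect_equal(al$end, c(1070, 1070))
  expect_equal(al$strand, c("+", "-"))
  expect_equal(al$nm, c(0L, 0L))
  # two substitutions: same span, nm = 2
  mut <- frag
  substr(mut, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(frag, 20, 20))[1]
  substr(mut, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(frag, 50, 50))[1]
  al2 <- map_reads(c(m = mut), g)
  expect_equal(al2$start, 1000)
  expect_equal(al2$end, 1070)
  expect_equal(al2$nm, 2L)
  # too-short and over-diverged fragments are dropped and counted
  al3 <- map_reads(c(s = substr(g, 1, 20), r = random_genome(60, seed = 45)),
                   g)
  cts <- attr(al3, "counts")
  expect_equal(unname(cts["too_short"]), 1L)
  expect_equal(nrow(al3) + cts[["too_short"]] + cts[["unmapped"]] +
                 cts[["diverged"]], 2L)
})

test_that("mapper edit distances equal full dynamic programming on windows", {
  set.seed(46)
  ref <- random_genome(500, seed = 46)
  cases <- list()
  for (i in 1:12) {
    start <- sample(1:420, 1)
    len <- sample(35:70, 1)
    r <- substr(ref, start, start + len - 1)
    rc <- strsplit(r, "")[[1]]
    nmut <- sample(0:3, 1)
    for (p in sample(seq_along(rc), nmut)) {
      rc[p] <- setdiff(c("A", "C", "G", "T"), rc[p])[sample.int(3, 1)]
    }
    # occasionally delete or insert a base
    if (i %% 3 == 0) rc <- rc[-sample(seq_along(rc), 1)]
    if (i %% 4 == 0) {
      at <- sample(seq_along(rc), 1)
      rc <- append(rc, sample(c("A", "C", "G", "T"), 1), after = at)
    }
    cases[[i]] <- paste(rc, collapse = "")
  }
  reads <- setNames(unlist(cases), paste0("w", 1:12))
  al <- map_reads(reads, ref, opts = assign_options(max_div = 0.5))
  for (i in seq_len(nrow(al))) {
    expect_equal(al$edits[i],
                 oracle_semiglobal_edits(al$seq_aln[i], ref),
                 info = paste("read", al$read_id[i]))
  }
})

test_that("deduplication keeps one representative per identical molecule and is idempotent", {
  g <- random_genome(5000, seed = 47)
  fr <- substring(g, c(100, 100, 100, 900), c(160, 160, 160, 960))
  # same span, different internal base: both kept
  var <- fr[4]
  substr(var, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(var, 30, 30))[1]
  al <- map_reads(setNames(c(fr, var), paste0("r", 1:5)), g)
  dd <- deduplicate(al)
  expect_equal(nrow(dd), 3) # one at 100-160, two distinct at 900-960
  expect_equal(attr(dd, "n_duplicates"), 2L)
  expect_equal(nrow(deduplicate(dd)), 3) # idempotent
})

test_that("site observation emits strand-resolved calls and skips deletions", {
  g <- random_genome(4000, seed = 48)
  # pin distinct bases around the deletion site so the optimal gap placement
  # is unique
  substr(g, 1018, 1021) <- "TACG"
  sites <- data.frame(anchor_pos = c(1020L, 1050L, 3000L),
                      allele_A = substring(g, c(1020, 1050, 3000),
                                           c(1020, 1050, 3000)),
                      allele_B = c("A", "C", "G"), stringsAsFactors = FALSE)
  # make allele_B different from allele_A at each site
  for (i in 1:3) {
    if (sites$allele_B[i] == sites$allele_A[i])
      sites$allele_B[i] <- setdiff(c("A", "C", "G", "T"), sites$allele_A[i])[1]
  }
  sites$is_transition <- paste(pmin(sites$allele_A, sites$allele_B),
                               pmax(sites$allele_A, sites$allele_B)) %in%
    c("C T", "A G")
  attr(sites, "groups") <- c(A = "gmel", B = "sib")
  frag <- substr(g, 1001, 1080) # covers sites 1 and 2, matches group A
  al <- map_reads(c(p = frag, m = revcomp(frag)), g)
  obs_p <- observe_sites(al[1, ], sites)
  obs_m <- observe_sites(al[2, ], sites)
  expect_equal(nrow(obs_p), 2)
  expect_equal(obs_p$call, c("gmel", "gmel"))
  expect_equal(obs_p$anchor_pos, c(1020L, 1050L))
  # strand invariance: identical observations apart from the read id
  expect_equal(obs_p[, -1], obs_m[, -1], ignore_attr = TRUE)
  # read covering no sites emits nothing
  far <- substr(g, 2001, 2080)
  expect_equal(nrow(observe_sites(map_reads(c(f = far), g), sites)), 0)
  # a deletion spanning a site suppresses that observation
  del <- paste0(substr(g, 1001, 1019), substr(g, 1021, 1080)) # drops 1020
  ald <- map_reads(c(d = del), g)
  expect_equal(ald$cigar, "19M1D60M")
  obsd <- observe_sites(ald, sites)
  expect_equal(obsd$anchor_pos, 1050L)
  # observed base at a B-allele read reports the B call
  swap <- frag
  substr(swap, 20, 20) <- sites$allele_B[1] # anchor_pos 1020 = frag offset 20
  obs_b <- observe_sites(map_reads(c(s = swap), g), sites)
  expect_equal(obs_b$call[obs_b$anchor_pos == 1020], "sib")
})

test_that("damage masking drops only terminal transition-site observations", {
  obs <- data.frame(
    read_id = c("r1", "r1", "r2", "r3"),
    anchor_pos = c(10L, 40L, 10L, 70L),
    observed_base = c("T", "G", "T", "C"),
    call = c("B", "A", "A", "A"),
    is_transition_site = c(TRUE, FALSE, TRUE, TRUE),
    dist_to_end = c(2L, 2L, 30L, 4L),
    stringsAsFactors = FALSE
  )
  attr(obs, "groups") <- c(A = "A", B = "B")
  # mask_m = 0 leaves everything
  expect_equal(nrow(damage_filter(obs, assign_options(mask_on = TRUE,
                                                      mask_m = 0))), 4)
  # masking off leaves everything
  expect_equal(nrow(damage_filter(obs, assign_options(mask_on = FALSE))), 4)
  kept <- damage_filter(obs, assign_options(mask_on = TRUE, mask_m = 5))
  expect_equal(attr(kept, "n_masked"), 2L)
  expect_equal(kept$anchor_pos, c(40L, 10L))
  expect_equal(kept$dist_to_end, c(2L, 30L))
})

test_that("aggregation tallies sites, votes reads by majority and conserves counts", {
  obs <- data.frame(
    read_id = c("r1", "r2", "r2", "r3", "r3", "r4"),
    anchor_pos = c(10L, 10L, 40L, 10L, 40L, 40L),
    observed_base = c("C", "C", "T", "C", "A", "G"),
    call = c("A", "A", "B", "A", "A", "other"),
    is_transition_site = FALSE,
    dist_to_end = 10L,
    stringsAsFactors = FALSE
  )
  attr(obs, "groups") <- c(A = "A", B = "B")
  m <- aggregate_assignments(obs, "s1")
  expect_equal(m$sites$anchor_pos, c(10L, 40L))
  expect_equal(m$sites$n_A, c(3L, 1L))
  expect_equal(m$sites$n_B, c(0L, 1L))
  expect_equal(m$sites$n_other, c(0L, 1L))
  expect_equal(m$sites$coverage, m$sites$n_A + m$sites$n_B + m$sites$n_other)
  # percentages sum to 100 at covered sites (within rounding)
  expect_true(all(abs(m$sites$pct_A + m$sites$pct_B +
                        round_half_up(100 * m$sites$n_other /
                                        m$sites$coverage) - 100) < 0.02))
  # r1: single A call -> A; r2: {A, B} tie -> unassigned; r3: majority A;
  # r4: only "other" -> unassigned
  expect_equal(m$totals$reads_A, 2L)
  expect_equal(m$totals$reads_B, 0L)
  expect_equal(m$totals$reads_unassigned, 2L)
  expect_equal(sum(m$totals[, c("reads_A", "reads_B", "reads_unassigned")]),
               length(unique(obs$read_id)))
})

test_that("negative-control screening reports overlap and subtracts counts", {
  obs <- data.frame(read_id = c("r1", "r2", "r3"), anchor_pos = c(10L, 10L, 40L),
                    observed_base = "C", call = c("A", "A", "B"),
                    is_transition_site = FALSE, dist_to_end = 10L,
                    stringsAsFactors = FALSE)
  attr(obs, "groups") <- c(A = "A", B = "B")
  smp <- aggregate_assignments(obs, "s1")
  empty_ctl <- aggregate_assignments(obs[0, ], "ctl")
  scr0 <- screen_controls(smp, empty_ctl, "subtract")
  expect_equal(scr0$adjusted$sites$n_A, smp$sites$n_A)
  expect_equal(unname(scr0$delta["removed_A"]), 0L)
  # control equal to the sample zeroes the matrix
  scr1 <- screen_controls(smp, smp, "subtract")
  expect_true(all(scr1$adjusted$sites$coverage == 0))
  # control with one read at one site decrements exactly one count
  ctl1 <- aggregate_assignments(obs[3, ], "ctl")
  scr2 <- screen_controls(smp, ctl1, "subtract")
  expect_equal(smp$sites$n_B - scr2$adjusted$sites$n_B, c(0L, 1L))
  expect_equal(unname(scr2$delta["sites_touched"]), 1L)
})

test_that("the mixture estimator is unbiased at p = 0.5 across seeds", {
  gen <- generate_panel(c(A = 1, B = 1), genome_len = 10000, n_sites = 60,
                        within_group_snps = 0, seed = 50)
  anchor <- gen$panel$seq[[gen$anchor_id]]
  props <- vapply(1:50, function(s) {
    cfg <- simulation_config(seed = 1000 + s, n_fragments = 700,
                             mixture = c(A = 0.5, B = 0.5),
                             background_frac = 0, duplicate_rate = 0,
                             d0 = 0, e = 0, seq_error = 0)
    sim <- simulate_readset(cfg, gen$panel)
    al <- map_reads(setNames(sim$fragments$seq, sim$fragments$read_id), anchor)
    m <- aggregate_assignments(observe_sites(al, gen$sites), "s")
    m$totals$reads_A / (m$totals$reads_A + m$totals$reads_B)
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.5), 0.01)
})
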