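test_that("build_panel ingests labelled FASTA, normalises and validates", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "g1.fa")
  writeLines(c(">g1 some description", "acguacgu", ">g2", "TTTTGGGG"), f1)
  panel <- build_panel(f1, c(g1 = "A", g2 = "B"), circular = FALSE)
  expect_s3_class(panel, "reference_panel")
  expect_equal(nrow(panel$info), 2)
  expect_setequal(panel$info$group, c("A", "B"))
  expect_equal(unname(panel$seq[["g1"]]), "ACGTACGT") # uppercased, U -> T

  # record id absent from the label map is a configuration error
  expect_error(build_panel(f1, c(g1 = "A")), "configuration error")
  # empty file is an input error
  f2 <- file.path(d, "empty.fa")
  writeLines(character(0), f2)
  expect_error(build_panel(f2, c(g1 = "A")), "input error|read")
  # >5% non-ACGT is rejected
  f3 <- file.path(d, "bad.fa")
  writeLines(c(">bad", "ACGTNNNNNN"), f3)
  expect_error(build_panel(f3, c(bad = "A")), "non-ACGT")
})

test_that("label maps read with and without a header line", {
  d <- withr::local_tempdir()
  p <- file.path(d, "labels.tsv")
  writeLines(c("id\tgroup", "x\tA", "y\tB"), p)
  expect_equal(read_label_map(p), c(x = "A", y = "B"))
  writeLines(c("x\tA", "y\tB"), p)
  expect_equal(read_label_map(p), c(x = "A", y = "B"))
})

test_that("published accession table lists 20 genomes in 2 groups with one anchor", {
  acc <- larix_accessions()
  expect_equal(nrow(acc), 20)
  expect_equal(sum(acc$group == "gmelinii"), 19)
  expect_equal(sum(acc$group == "sibirica"), 1)
  expect_equal(acc$accession[acc$anchor], "MK468637.1")
})

test_that("aligning identical genomes gives the identity alignment", {
  set.seed(1)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  panel <- make_panel(c(a = g, b = g, c = g), c(a = "A", b = "A", c = "B"))
  aln <- align_to_anchor(panel, "a")
  expect_equal(aln$anchor_map, seq_len(2000))
  expect_true(all(aln$rows == g))
  expect_equal(nrow(call_diagnostic_sites(aln, "A", "B")), 0)
})

test_that("a single substitution yields one mismatch column and no gaps", {
  set.seed(2)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  g2 <- g
  old <- substr(g2, 500, 500)
  substr(g2, 500, 500) <- setdiff(c("A", "C", "G", "T"), old)[1]
  panel <- make_panel(c(anchor = g, mut = g2), c(anchor = "A", mut = "B"))
  aln <- align_to_anchor(panel, "anchor")
  expect_false(grepl("-", aln$rows[["mut"]], fixed = TRUE))
  diff_cols <- which(strsplit(aln$rows[["anchor"]], "")[[1]] !=
                       strsplit(aln$rows[["mut"]], "")[[1]])
  expect_equal(diff_cols, 500)
  sites <- call_diagnostic_sites(aln, "A", "B")
  expect_equal(sites$anchor_pos, 500)
})

test_that("a 3-base deletion yields exactly 3 gap columns in that row", {
  set.seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g2 <- paste0(substr(g, 1, 1200), substr(g, 1204, 3000))
  panel <- make_panel(c(anchor = g, del = g2), c(anchor = "A", del = "B"))
  aln <- align_to_anchor(panel, "anchor")
  expect_equal(sum(strsplit(aln$rows[["del"]], "")[[1]] == "-"), 3)
  expect_equal(sum(strsplit(aln$rows[["anchor"]], "")[[1]] == "-"), 0)
  # no diagnostic site falls in a gap column
  sites <- call_diagnostic_sites(aln, "A", "B")
  expect_false(any(sites$anchor_pos %in% 1201:1203))
})

test_that("circular genomes are rotated to the anchor origin before alignment", {
  set.seed(4)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  rot <- paste0(substr(g, 1501, 4000), substr(g, 1, 1500))
  panel <- make_panel(c(anchor = g, rotated = rot),
                      c(anchor = "A", rotated = "B"), circular = TRUE)
  aln <- align_to_anchor(panel, "anchor")
  expect_equal(aln$rows[["rotated"]], g)
  expect_equal(nrow(call_diagnostic_sites(aln, "A", "B")), 0)
})

test_that("insertions relative to the anchor never yield sites and keep the anchor reconstructable", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g2 <- paste0(substr(g, 1, 1500), "ACGTA", substr(g, 1501, 3000))
  panel <- make_panel(c(anchor = g, ins = g2), c(anchor = "A", ins = "B"))
  aln <- align_to_anchor(panel, "anchor")
  expect_equal(sum(is.na(aln$anchor_map)), 5)
  expect_equal(gsub("-", "", aln$rows[["anchor"]]), g)
  expect_equal(gsub("-", "", aln$rows[["ins"]]), g2)
  expect_equal(nrow(call_diagnostic_sites(aln, "A", "B")), 0)
})

test_that("pairwise anchored alignment matches the edit-distance oracle on mutated genomes", {
  set.seed(6)
  for (rep in 1:3) {
    g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    gc <- strsplit(g, "")[[1]]
    # implant substitutions and a short indel
    for (p in sample(100:1900, 8)) {
      gc[p] <- setdiff(c("A", "C", "G", "T"), gc[p])[sample.int(3, 1)]
    }
    g2 <- paste(gc[-(1000:1001)], collapse = "")
    panel <- make_panel(c(anchor = g, mut = g2), c(anchor = "A", mut = "B"))
    aln <- align_to_anchor(panel, "anchor")
    a_row <- strsplit(aln$rows[["anchor"]], "")[[1]]
    m_row <- strsplit(aln$rows[["mut"]], "")[[1]]
    edits <- sum(a_row != m_row)
    # unit-cost global alignment oracle (base R Levenshtein)
    expect_equal(edits, as.integer(adist(g, g2)))
  }
})

test_that("site caller equals the brute-force column scan, including N/gap/polymorphic columns", {
  aln <- toy_alignment(
    rows = c(a1 = "ACGTACGTAC",
             a2 = "ACGTACGTAC",
             b1 = "ACKTTCGAAC",
             b2 = "ACNTTCGAAC"),
    groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  )
  # column 5 fixed A/T, column 8 fixed T/A; column 3 has N (excluded);
  # column 1,2,... identical
  got <- call_diagnostic_sites(aln, "A", "B")
  ora <- oracle_call_sites(aln, "A", "B")
  expect_equal(got$anchor_pos, ora$anchor_pos)
  expect_equal(got$allele_A, ora$allele_A)
  expect_equal(got$allele_B, ora$allele_B)
  expect_equal(got$is_transition, ora$is_transition)
  expect_equal(got$anchor_pos, c(5, 8))

  # and on a generated panel with within-group polymorphism
  gen <- generate_panel(c(A = 3, B = 2), genome_len = 5000, n_sites = 30,
                        within_group_snps = 15, seed = 11)
  aln2 <- align_to_anchor(gen$panel, gen$anchor_id)
  got2 <- call_diagnostic_sites(aln2, "A", "B")
  ora2 <- oracle_call_sites(aln2, "A", "B")
  expect_equal(got2$anchor_pos, ora2$anchor_pos)
  expect_equal(got2$allele_A, ora2$allele_A)
})

test_that("swapping the group labels swaps alleles but preserves positions", {
  gen <- generate_panel(c(A = 3, B = 3), genome_len = 5000, n_sites = 25,
                        within_group_snps = 5, seed = 12)
  aln <- align_to_anchor(gen$panel, gen$anchor_id)
  ab <- call_diagnostic_sites(aln, "A", "B")
  ba <- call_diagnostic_sites(aln, "B", "A")
  expect_equal(ab$anchor_pos, ba$anchor_pos)
  expect_equal(ab$allele_A, ba$allele_B)
  expect_equal(ab$allele_B, ba$allele_A)
  expect_equal(ab$is_transition, ba$is_transition)
})

test_that("adding a genome to a group can only shrink or preserve the site set", {
  gen <- generate_panel(c(A = 3, B = 3), genome_len = 5000, n_sites = 25,
                        within_group_snps = 5, seed = 13)
  aln_full <- align_to_anchor(gen$panel, gen$anchor_id)
  full <- call_diagnostic_sites(aln_full, "A", "B")
  # drop one group-B genome, then compare: the reduced panel's site set must
  # contain the full panel's
  keep <- gen$panel$info$id != "B_g03"
  sub <- make_panel(gen$panel$seq[keep],
                    setNames(gen$panel$info$group, gen$panel$info$id)[keep])
  reduced <- call_diagnostic_sites(align_to_anchor(sub, gen$anchor_id),
                                   "A", "B")
  expect_true(all(full$anchor_pos %in% reduced$anchor_pos))
})

test_that("diagnostic site tables are written 1-based with group-named columns", {
  gen <- generate_panel(c(A = 2, B = 2), genome_len = 3000, n_sites = 10,
                        within_group_snps = 0, seed = 14)
  d <- withr::local_tempdir()
  p <- file.path(d, "sites.tsv")
  write_diagnostic_sites(gen$sites, p)
  tab <- read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_named(tab, c("anchor_pos_1based", "allele_A", "allele_B",
                      "is_transition"))
  expect_equal(tab$anchor_pos_1based, gen$sites$anchor_pos)
  expect_false(is.unsorted(tab$anchor_pos_1based, strictly = TRUE))
})
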