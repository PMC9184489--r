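#' Assignment options
#'
#' @param min_len minimum usable molecule length in bp (default 30, the
#'   bioinformatic lower bound for target-enriched sedaDNA molecules).
#' @param max_div maximum fraction of edits (mismatches + indels) per aligned
#'   base; alignments above it are discarded. Default 0.1 admits terminal
#'   deamination plus interspecific divergence on short reads.
#' @param mask_m terminal mask width in bp for damage-confoundable
#'   observations.
#' @param mask_on whether the damage mask is applied (off by default; the
#'   masking is surfaced because transition-diagnostic sites are confoundable
#'   with deamination).
#' @param per_read_rule per-read species rule; only `"majority"` is defined.
#' @return list of class `assign_options`.
#' @export
assign_options <- function(min_len = 30L, max_div = 0.1, mask_m = 5L,
                           mask_on = FALSE, per_read_rule = "majority") {
  stopifnot(min_len >= 1, max_div >= 0, mask_m >= 0,
            per_read_rule == "majority")
  structure(list(min_len = min_len, max_div = max_div, mask_m = mask_m,
                 mask_on = mask_on, per_read_rule = per_read_rule),
            class = "assign_options")
}

#' Merge paired-end reads into fragments
#'
#' Adapter read-through is trimmed by exact adapter match; then the suffix of
#' mate 1 and the reverse-complemented prefix of mate 2 are scanned
#' longest-first for an overlap of at least `min_overlap` bases with at most
#' `max_mismatch_frac` mismatches (a read-through orientation is tried when
#' that fails). Mate 1 wins base conflicts, qualities being flat in this data
#' model. Pairs whose insert is empty after trimming are discarded.
#'
#' @param reads data frame with `read_id`, `mate1`, `mate2`.
#' @param min_overlap minimum overlap in bp.
#' @param max_mismatch_frac maximum mismatch fraction inside the overlap.
#' @param adapter adapter sequence.
#' @return list with `merged` (data frame `read_id`, `seq`, `overlap`),
#'   `unmerged` (original mates), `discarded` (read ids) and `counts`.
#' @export
merge_pairs <- function(reads, min_overlap = 10L, max_mismatch_frac = 0.1,
                        adapter = SIM_ADAPTER) {
  if (nrow(reads) == 0) {
    return(list(
      merged = data.frame(read_id = character(0), seq = character(0),
                          overlap = integer(0), stringsAsFactors = FALSE),
      unmerged = reads, discarded = character(0),
      counts = c(input = 0L, merged = 0L, unmerged = 0L, discarded = 0L)
    ))
  }
  res <- cpp_merge_pairs(reads$mate1, reads$mate2, adapter,
                         as.integer(min_overlap), max_mismatch_frac)
  st <- res$status
  merged <- data.frame(read_id = reads$read_id[st == "merged"],
                       seq = res$merged[st == "merged"],
                       overlap = res$overlap[st == "merged"],
                       stringsAsFactors = FALSE)
  unmerged <- reads[st == "unmerged", , drop = FALSE]
  rownames(unmerged) <- NULL
  list(
    merged = merged,
    unmerged = unmerged,
    discarded = reads$read_id[st == "empty"],
    counts = c(input = nrow(reads), merged = sum(st == "merged"),
               unmerged = sum(st == "unmerged"), discarded = sum(st == "empty"))
  )
}

#' Map fragments to the anchor genome
#'
#' Seeded semi-global alignment (the read aligns end to end, reference end
#' gaps are free) with unit edit costs; both strands are tried and the best
#' edit distance kept. Equal-score hits at distinct loci flag the read as
#' ambiguous (such reads are excluded from site calling). Fragments shorter
#' than `min_len` are dropped and counted; alignments with more than
#' `max_div` edits per aligned base are discarded.
#'
#' @param fragments data frame with `read_id` and `seq`, or a named character
#'   vector of sequences.
#' @param anchor anchor genome sequence (single string).
#' @param anchor_id reference name recorded in the alignments.
#' @param opts an [assign_options()] object.
#' @param seed_k seed k-mer length of the mapper.
#' @param pad window padding in bp around seed diagonals.
#' @return data frame of class `read_alignments`: `read_id`, `ref_id`,
#'   `start`, `end` (1-based, inclusive), `strand`, `cigar`, `edits`, `nm`,
#'   `aligned_len`, `ambiguous`, `seq_aln` (read in reference orientation).
#'   Per-stage counts are attached as `attr(, "counts")`.
#' @export
map_reads <- function(fragments, anchor, anchor_id = "anchor",
                      opts = assign_options(), seed_k = 16L, pad = 16L) {
  if (is.character(fragments)) {
    ids <- if (!is.null(names(fragments))) names(fragments) else
      sprintf("read%06d", seq_along(fragments))
    fragments <- data.frame(read_id = ids, seq = unname(fragments),
                            stringsAsFactors = FALSE)
  }
  lens <- nchar(fragments$seq)
  short <- lens < opts$min_len
  frag <- fragments[!short, , drop = FALSE]
  n_unmapped <- 0L; n_filtered <- 0L
  if (nrow(frag) > 0) {
    m <- cpp_map_reads(frag$seq, anchor, as.integer(seed_k), as.integer(pad),
                       8L)
    aligned_len <- nchar(frag$seq)
    pass <- m$mapped & !is.na(m$edits) & (m$edits / aligned_len <= opts$max_div)
    n_unmapped <- sum(!m$mapped)
    n_filtered <- sum(m$mapped & !pass)
    out <- data.frame(
      read_id = frag$read_id[pass],
      ref_id = rep(anchor_id, sum(pass)),
      start = m$start[pass], end = m$end[pass],
      strand = m$strand[pass], cigar = m$cigar[pass],
      edits = m$edits[pass], nm = m$nm[pass],
      aligned_len = aligned_len[pass],
      ambiguous = m$ambiguous[pass],
      seq_aln = m$seq_aln[pass],
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), cigar = character(0),
                      edits = integer(0), nm = integer(0),
                      aligned_len = integer(0), ambiguous = logical(0),
                      seq_aln = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "counts") <- c(input = nrow(fragments), too_short = sum(short),
                           unmapped = n_unmapped,
                           diverged = n_filtered, mapped = nrow(out))
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Remove PCR duplicates among alignments
#'
#' Among alignments sharing start, end, strand and an identical aligned
#' sequence, exactly one representative (the first) is kept. Idempotent.
#'
#' @param alignments alignment data frame from [map_reads()].
#' @return the deduplicated data frame; the number removed is in
#'   `attr(, "n_duplicates")`.
#' @export
deduplicate <- function(alignments) {
  key <- paste(alignments$start, alignments$end, alignments$strand,
               alignments$seq_aln, sep = "\r")
  keep <- !duplicated(key)
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts <- attr(alignments, "counts")
  attr(out, "counts") <- counts
  attr(out, "n_duplicates") <- sum(!keep)
  class(out) <- c("read_alignments", "data.frame")
  out
}

# (query offset, reference position) pairs of aligned (M) bases; qpos refers
# to seq_aln, which is the read in reference orientation
aligned_pairs <- function(start, cigar, seq_len) {
  if (grepl("^[0-9]+M$", cigar)) {
    n <- as.integer(sub("M$", "", cigar))
    return(list(qpos = seq_len(n), rpos = start + seq_len(n) - 1L))
  }
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  q <- 0L; r <- start - 1L
  qpos <- integer(0); rpos <- integer(0)
  for (i in seq_along(ops)) {
    l <- ops_len[i]
    if (ops[i] == "M") {
      qpos <- c(qpos, q + seq_len(l)); rpos <- c(rpos, r + seq_len(l))
      q <- q + l; r <- r + l
    } else if (ops[i] == "I") {
      q <- q + l
    } else {
      r <- r + l
    }
  }
  list(qpos = qpos, rpos = rpos)
}

#' Observe diagnostic sites covered by alignments
#'
#' For every diagnostic site falling inside an alignment where the read has
#' an aligned base (sites under read deletions emit nothing), emits the
#' strand-resolved base, its species call, and its distance to the nearest
#' molecule terminus. Ambiguous alignments are excluded.
#'
#' @param alignments alignment data frame from [map_reads()] (after
#'   [deduplicate()]).
#' @param sites diagnostic site table from [call_diagnostic_sites()] or
#'   [generate_panel()].
#' @param opts an [assign_options()] object (unused here beyond contract
#'   symmetry; masking is applied by [damage_filter()]).
#' @return data frame: `read_id`, `anchor_pos`, `observed_base`, `call` (the
#'   group label, or `"other"`), `is_transition_site`, `dist_to_end`; group
#'   labels in `attr(, "groups")`.
#' @export
observe_sites <- function(alignments, sites, opts = assign_options()) {
  groups <- attr(sites, "groups")
  if (is.null(groups)) groups <- c(A = "A", B = "B")
  empty <- data.frame(read_id = character(0), anchor_pos = integer(0),
                      observed_base = character(0), call = character(0),
                      is_transition_site = logical(0),
                      dist_to_end = integer(0), stringsAsFactors = FALSE)
  attr(empty, "groups") <- groups
  aln <- alignments[!alignments$ambiguous, , drop = FALSE]
  if (nrow(aln) == 0 || nrow(sites) == 0) return(empty)
  spos <- sites$anchor_pos
  res <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    lo <- findInterval(aln$start[i] - 1L, spos) + 1L
    hi <- findInterval(aln$end[i], spos)
    if (lo > hi) next
    pr <- aligned_pairs(aln$start[i], aln$cigar[i], nchar(aln$seq_aln[i]))
    hitsite <- lo:hi
    m <- match(spos[hitsite], pr$rpos)
    cov <- !is.na(m)
    if (!any(cov)) next
    hitsite <- hitsite[cov]
    qp <- pr$qpos[m[cov]]
    base <- substring(aln$seq_aln[i], qp, qp)
    len <- nchar(aln$seq_aln[i])
    call <- ifelse(base == sites$allele_A[hitsite], groups[["A"]],
                   ifelse(base == sites$allele_B[hitsite], groups[["B"]],
                          "other"))
    res[[i]] <- data.frame(
      read_id = aln$read_id[i],
      anchor_pos = spos[hitsite],
      observed_base = base,
      call = call,
      is_transition_site = sites$is_transition[hitsite],
      dist_to_end = pmin(qp - 1L, len - qp),
      stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}

#' Mask damage-confoundable site observations
#'
#' Deamination mimics C-to-T / G-to-A alleles, so when masking is on,
#' observations at transition-diagnostic sites within `mask_m` bases of a
#' molecule terminus are dropped.
#'
#' @param observations table from [observe_sites()].
#' @param opts an [assign_options()]; masking is applied iff `opts$mask_on`.
#' @return the filtered table; number of dropped observations in
#'   `attr(, "n_masked")`.
#' @export
damage_filter <- function(observations, opts = assign_options()) {
  groups <- attr(observations, "groups")
  if (!opts$mask_on || opts$mask_m == 0) {
    attr(observations, "n_masked") <- 0L
    return(observations)
  }
  drop <- observations$is_transition_site &
    observations$dist_to_end < opts$mask_m
  out <- observations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  attr(out, "n_masked") <- sum(drop)
  out
}

#' Aggregate site observations into the species-assignment matrices
#'
#' Per-site counts of group-A, group-B and other bases, plus per-read species
#' assignment by majority vote over the read's calls (`other` is ignored in
#' the vote; ties and zero informative calls leave the read unassigned), and
#' the per-sample species totals.
#'
#' @param observations table from [observe_sites()] / [damage_filter()].
#' @param sample_id sample name recorded in the matrices.
#' @param per_read_rule per-read rule; only `"majority"` is defined.
#' @return object of class `species_assignment`: list with `sites` (data
#'   frame `sample`, `anchor_pos`, `n_A`, `n_B`, `n_other`, `coverage`,
#'   `pct_A`, `pct_B`), `totals` (data frame `sample`, `reads_A`, `reads_B`,
#'   `reads_unassigned`) and `groups`.
#' @export
aggregate_assignments <- function(observations, sample_id = "sample1",
                                  per_read_rule = "majority") {
  stopifnot(per_read_rule == "majority")
  groups <- attr(observations, "groups")
  if (is.null(groups)) groups <- c(A = "A", B = "B")
  if (nrow(observations) == 0) {
    sites <- data.frame(sample = character(0), anchor_pos = integer(0),
                        n_A = integer(0), n_B = integer(0),
                        n_other = integer(0), coverage = integer(0),
                        pct_A = numeric(0), pct_B = numeric(0))
    totals <- data.frame(sample = sample_id, reads_A = 0L, reads_B = 0L,
                         reads_unassigned = 0L, stringsAsFactors = FALSE)
    return(structure(list(sites = sites, totals = totals, groups = groups),
                     class = "species_assignment"))
  }
  pos <- sort(unique(observations$anchor_pos))
  f <- factor(observations$anchor_pos, levels = pos)
  n_A <- as.integer(tapply(observations$call == groups[["A"]], f, sum))
  n_B <- as.integer(tapply(observations$call == groups[["B"]], f, sum))
  n_other <- as.integer(tapply(observations$call == "other", f, sum))
  coverage <- n_A + n_B + n_other
  sites <- data.frame(
    sample = sample_id, anchor_pos = pos, n_A = n_A, n_B = n_B,
    n_other = n_other, coverage = coverage,
    pct_A = round_half_up(100 * n_A / coverage),
    pct_B = round_half_up(100 * n_B / coverage),
    stringsAsFactors = FALSE
  )
  rf <- factor(observations$read_id, levels = unique(observations$read_id))
  vote_A <- tapply(observations$call == groups[["A"]], rf, sum)
  vote_B <- tapply(observations$call == groups[["B"]], rf, sum)
  reads_A <- sum(vote_A > vote_B)
  reads_B <- sum(vote_B > vote_A)
  totals <- data.frame(
    sample = sample_id,
    reads_A = as.integer(reads_A),
    reads_B = as.integer(reads_B),
    reads_unassigned = as.integer(length(vote_A) - reads_A - reads_B),
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, totals = totals, groups = groups),
            class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  cat("<species_assignment> sample ", x$totals$sample[1], ": ",
      nrow(x$sites), " covered sites; reads ", x$groups[["A"]], "=",
      x$totals$reads_A, ", ", x$groups[["B"]], "=", x$totals$reads_B,
      ", unassigned=", x$totals$reads_unassigned, "\n", sep = "")
  invisible(x)
}

#' Screen sample assignments against negative controls
#'
#' `mode = "report"` tabulates per-site overlap between a sample matrix and a
#' control matrix; `mode = "subtract"` additionally reduces the sample's
#' per-site counts by `min(sample, control)` in every category.
#'
#' @param sample_matrix,control_matrix `species_assignment` objects.
#' @param mode `"report"` or `"subtract"`.
#' @return list with `report` (per-site overlap counts), `delta` (summary of
#'   removed counts) and, for `mode = "subtract"`, `adjusted` (the adjusted
#'   `species_assignment`; read-level totals are not recomputable from site
#'   counts and are carried over unchanged).
#' @export
screen_controls <- function(sample_matrix, control_matrix,
                            mode = c("report", "subtract")) {
  mode <- match.arg(mode)
  s <- sample_matrix$sites
  ctl <- control_matrix$sites
  m <- match(s$anchor_pos, ctl$anchor_pos)
  ctl_A <- ifelse(is.na(m), 0L, ctl$n_A[m])
  ctl_B <- ifelse(is.na(m), 0L, ctl$n_B[m])
  ctl_other <- ifelse(is.na(m), 0L, ctl$n_other[m])
  report <- data.frame(
    anchor_pos = s$anchor_pos,
    sample_coverage = s$coverage,
    control_coverage = ctl_A + ctl_B + ctl_other,
    stringsAsFactors = FALSE
  )
  rem_A <- pmin(s$n_A, ctl_A)
  rem_B <- pmin(s$n_B, ctl_B)
  rem_other <- pmin(s$n_other, ctl_other)
  delta <- c(removed_A = sum(rem_A), removed_B = sum(rem_B),
             removed_other = sum(rem_other),
             sites_touched = sum(rem_A + rem_B + rem_other > 0))
  out <- list(report = report, delta = delta)
  if (mode == "subtract") {
    adj <- sample_matrix
    adj$sites$n_A <- s$n_A - rem_A
    adj$sites$n_B <- s$n_B - rem_B
    adj$sites$n_other <- s$n_other - rem_other
    adj$sites$coverage <- adj$sites$n_A + adj$sites$n_B + adj$sites$n_other
    cov <- adj$sites$coverage
    adj$sites$pct_A <- ifelse(cov > 0, round_half_up(100 * adj$sites$n_A / cov), NA)
    adj$sites$pct_B <- ifelse(cov > 0, round_half_up(100 * adj$sites$n_B / cov), NA)
    out$adjusted <- adj
  }
  out
}

#' Write the species-assignment matrices as TSV
#'
#' Emits `<prefix>_sites.tsv` (`sample`, `anchor_pos_1based`, `n_A`, `n_B`,
#' `n_other`, `pct_A`, `pct_B`; percentages to 2 decimals, half-up) and
#' `<prefix>_totals.tsv` (`sample`, `reads_A`, `reads_B`,
#' `reads_unassigned`).
#'
#' @param mat a `species_assignment`.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_assignment_matrix <- function(mat, prefix) {
  sites <- data.frame(
    sample = mat$sites$sample,
    anchor_pos_1based = mat$sites$anchor_pos,
    n_A = mat$sites$n_A, n_B = mat$sites$n_B, n_other = mat$sites$n_other,
    pct_A = sprintf("%.2f", mat$sites$pct_A),
    pct_B = sprintf("%.2f", mat$sites$pct_B),
    stringsAsFactors = FALSE
  )
  p1 <- paste0(prefix, "_sites.tsv")
  p2 <- paste0(prefix, "_totals.tsv")
  write_tsv(sites, p1)
  write_tsv(mat$totals, p2)
  invisible(c(p1, p2))
}

#' Export alignments as SAM
#'
#' Minimal single-reference SAM with the anchor length in the header and the
#' 0x10 flag for minus-strand alignments.
#'
#' @param alignments alignment data frame from [map_reads()].
#' @param anchor_len anchor genome length in bp.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, anchor_len, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  ref <- if (nrow(alignments) > 0) alignments$ref_id[1] else "anchor"
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", ref, "\tLN:", anchor_len))
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  body <- paste(alignments$read_id, flag, alignments$ref_id,
                alignments$start, 255L, alignments$cigar, "*", 0L, 0L,
                alignments$seq_aln, "*",
                paste0("NM:i:", alignments$edits), sep = "\t")
  writeLines(c(hdr, body), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
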