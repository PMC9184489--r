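#' Build a labelled reference panel from FASTA files
#'
#' Reads one or more (multi-)FASTA files of congeneric organelle genomes and
#' attaches a species-group label to every record. Sequences are uppercased
#' and `U` is normalised to `T`; records with more than 5% non-`ACGT`
#' characters are rejected.
#'
#' @param fasta_paths character vector of FASTA file paths.
#' @param label_map named character vector mapping record id (first token of
#'   the FASTA header) to a group label, or a data frame with columns `id`
#'   and `group` (see [read_label_map()]).
#' @param circular logical, whether the genomes are circular molecules
#'   (chloroplast GenBank records are); recycled over records.
#' @return An object of class `reference_panel`: a list with `info` (data
#'   frame of `id`, `group`, `circular`, `length`) and `seq` (named character
#'   vector of sequences).
#' @export
build_panel <- function(fasta_paths, label_map, circular = TRUE) {
  if (is.data.frame(label_map)) {
    stopifnot(all(c("id", "group") %in% colnames(label_map)))
    label_map <- setNames(as.character(label_map$group), label_map$id)
  }
  stopifnot(is.character(label_map), !is.null(names(label_map)))
  seqs <- character(0)
  for (p in fasta_paths) {
    if (!file.exists(p)) stop("input error: FASTA file not found: ", p)
    ss <- Biostrings::readBStringSet(p)
    if (length(ss) == 0) stop("input error: empty FASTA file: ", p)
    ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
    v <- toupper(as.character(ss))
    names(v) <- ids
    seqs <- c(seqs, v)
  }
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0)) stop("input error: zero-length sequence record")
  if (anyDuplicated(names(seqs)))
    stop("input error: duplicate record id in panel: ",
         names(seqs)[duplicated(names(seqs))][1])
  missing <- setdiff(names(seqs), names(label_map))
  if (length(missing) > 0)
    stop("configuration error: no group label for record(s): ",
         paste(missing, collapse = ", "))
  frac_bad <- vapply(seqs, function(s) {
    1 - sum(charToRaw(s) %in% charToRaw("ACGT")) / nchar(s)
  }, numeric(1))
  if (any(frac_bad > 0.05))
    stop("input error: record(s) with >5% non-ACGT characters: ",
         paste(names(seqs)[frac_bad > 0.05], collapse = ", "))
  info <- data.frame(
    id = names(seqs),
    group = unname(label_map[names(seqs)]),
    circular = rep_len(circular, length(seqs)),
    length = unname(nchar(seqs)),
    stringsAsFactors = FALSE
  )
  structure(list(info = info, seq = seqs), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", nrow(x$info), " genomes, groups: ",
      paste(sprintf("%s (%d)", names(table(x$info$group)), table(x$info$group)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a two-column id-to-group label map
#'
#' The file is tab-separated with columns `id` and `group`; a header line
#' `id<TAB>group` is optional.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping id to group.
#' @export
read_label_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2))
    stop("configuration error: label map must have exactly two tab-separated columns")
  m <- do.call(rbind, parts)
  if (identical(tolower(m[1, ]), c("id", "group"))) m <- m[-1, , drop = FALSE]
  setNames(m[, 2], m[, 1])
}

#' Accession panel of Siberian larch chloroplast genomes
#'
#' The published complete chloroplast genomes used to define diagnostic sites
#' between the two Siberian larch species groups: 19 GenBank accessions of
#' L. gmelinii / L. cajanderi (treated as one group, following the one-species
#' classification of the eastern larches) and the L. sibirica RefSeq genome.
#' `MK468637.1` is the coordinate anchor. The sequences themselves are not
#' shipped; fetch them with `analysis/00_download_references.R` or any GenBank
#' client, then feed the FASTA files to [build_panel()].
#'
#' @return data frame with columns `accession`, `group`, `anchor`.
#' @export
larix_accessions <- function() {
  acc <- c(sprintf("MK4686%02d.1", 30:48), "NC_036811.1")
  data.frame(
    accession = acc,
    group = c(rep("gmelinii", 19), "sibirica"),
    anchor = acc == "MK468637.1",
    stringsAsFactors = FALSE
  )
}

# unique k-mer start positions shared between two sequences, subsampled to a
# roughly even stride so chaining stays cheap on full organelle genomes
shared_unique_kmers <- function(a, b, k, max_anchors = 4000L) {
  ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
  kb <- substring(b, 1:(nchar(b) - k + 1), k:nchar(b))
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  pa <- which(ua)
  hit <- match(ka[pa], kb)
  keep <- !is.na(hit) & ub[pmax(hit, 1L)]
  pa <- pa[keep]
  pb <- hit[keep]
  if (length(pa) > max_anchors) {
    stride <- ceiling(length(pa) / max_anchors)
    sel <- unique(c(seq(1L, length(pa), by = stride), length(pa)))
    pa <- pa[sel]; pb <- pb[sel]
  }
  list(pa = pa, pb = pb)
}

# longest increasing subsequence (strict, on pb) of anchor matches ordered by
# pa; patience sorting with binary search
lis_chain <- function(pa, pb) {
  n <- length(pa)
  if (n == 0) return(integer(0))
  tails <- integer(0)   # values of pb ending each pile
  tidx <- integer(0)    # index of that match
  prev <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(pb[i] - 1L, tails) + 1L
    prev[i] <- if (pos > 1L) tidx[pos - 1L] else 0L
    tails[pos] <- pb[i]
    tidx[pos] <- i
    if (pos < length(tails)) { tails <- tails[1:pos]; tidx <- tidx[1:pos] }
  }
  chain <- integer(0)
  cur <- tidx[length(tidx)]
  while (cur != 0L) { chain <- c(cur, chain); cur <- prev[cur] }
  chain
}

# pairwise anchored alignment of one genome against the anchor sequence;
# returns the two gapped strings
align_pair_anchored <- function(a, g, k, band_extra, min_anchors, id) {
  sk <- shared_unique_kmers(a, g, k)
  if (length(sk$pa) == 0)
    stop("alignment failure: no shared unique ", k, "-mers for genome ", id)
  chain <- lis_chain(sk$pa, sk$pb)
  pa <- sk$pa[chain]; pb <- sk$pb[chain]
  # enforce non-overlapping exact blocks of width k
  keep <- logical(length(pa))
  last_a <- -1e9; last_b <- -1e9
  for (i in seq_along(pa)) {
    if (pa[i] >= last_a + k && pb[i] >= last_b + k) {
      keep[i] <- TRUE; last_a <- pa[i]; last_b <- pb[i]
    }
  }
  pa <- pa[keep]; pb <- pb[keep]
  if (length(pa) < min_anchors)
    stop("alignment failure: fewer than ", min_anchors,
         " chained anchors for genome ", id)
  # segments between blocks (plus leading/trailing)
  seg_a_start <- c(1L, pa + k); seg_a_end <- c(pa - 1L, nchar(a))
  seg_b_start <- c(1L, pb + k); seg_b_end <- c(pb - 1L, nchar(g))
  seg_a <- substring(a, seg_a_start, seg_a_end)
  seg_b <- substring(g, seg_b_start, seg_b_end)
  seg_a[seg_a_start > seg_a_end] <- ""
  seg_b[seg_b_start > seg_b_end] <- ""
  aln_a <- seg_a; aln_b <- seg_b
  need_dp <- which(seg_a != seg_b)
  if (length(need_dp) > 0) {
    dp <- cpp_align_segment_pairs(seg_a[need_dp], seg_b[need_dp], band_extra)
    aln_a[need_dp] <- dp$a_aln
    aln_b[need_dp] <- dp$b_aln
  }
  blocks <- substring(a, pa, pa + k - 1L)
  n_seg <- length(aln_a)
  out_a <- character(2L * n_seg - 1L)
  out_b <- character(2L * n_seg - 1L)
  out_a[seq(1L, 2L * n_seg - 1L, by = 2L)] <- aln_a
  out_b[seq(1L, 2L * n_seg - 1L, by = 2L)] <- aln_b
  if (n_seg > 1) {
    out_a[seq(2L, 2L * n_seg - 2L, by = 2L)] <- blocks
    out_b[seq(2L, 2L * n_seg - 2L, by = 2L)] <- blocks
  }
  list(a = paste(out_a, collapse = ""), b = paste(out_b, collapse = ""))
}

# rotate a circular genome so its coordinates start at the anchor's origin
rotate_to_anchor <- function(a, g, k) {
  La <- nchar(a)
  kg <- substring(g, 1:(nchar(g) - k + 1), k:nchar(g))
  ug <- !(duplicated(kg) | duplicated(kg, fromLast = TRUE))
  # first unique anchor k-mer that occurs uniquely in g
  limit <- min(La - k + 1L, 5000L)
  ka <- substring(a, 1:limit, k:(limit + k - 1L))
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  for (qa in which(ua)) {
    hit <- which(kg == ka[qa])
    if (length(hit) == 1 && ug[hit]) {
      shift <- hit - qa
      if (shift == 0) return(g)
      return(substr_circular(g, shift + 1L, nchar(g)))
    }
  }
  g # no unique shared origin k-mer; leave unrotated and let chaining decide
}

#' Align a reference panel to an anchor genome
#'
#' Every non-anchor genome is (for circular molecules) rotated to the
#' anchor's origin, then anchored by chaining unique shared k-mer matches
#' with a longest-increasing-subsequence pass; gaps between anchors are
#' closed by banded global alignment with unit edit costs. The result is a
#' column matrix in anchor coordinates; columns inserted relative to the
#' anchor carry `NA` in `anchor_map`.
#'
#' @param panel a `reference_panel` from [build_panel()].
#' @param anchor_id id of the genome defining the coordinate system.
#' @param k anchoring k-mer length (default 21, unique in organelle genomes).
#' @param band_extra additive term of the banded-closure band width
#'   (band = 2 x length difference + `band_extra`).
#' @param min_anchors minimum number of chained anchors per genome before the
#'   alignment is declared failed.
#' @return An object of class `panel_alignment`: list with `anchor_id`,
#'   `ids`, `groups`, `rows` (named character vector of equal-length gapped
#'   sequences) and `anchor_map` (integer vector, 1-based anchor position per
#'   column, `NA` for insertion columns).
#' @export
align_to_anchor <- function(panel, anchor_id, k = 21, band_extra = 32,
                            min_anchors = 10) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!anchor_id %in% panel$info$id)
    stop("configuration error: anchor id not in panel: ", anchor_id)
  a <- panel$seq[[anchor_id]]
  La <- nchar(a)
  others <- setdiff(panel$info$id, anchor_id)
  # per genome: chars at each anchor position, plus insertions keyed by the
  # anchor position they precede (1 .. La + 1)
  at_anchor <- list()
  insertions <- list()
  for (id in others) {
    g <- panel$seq[[id]]
    if (identical(g, a)) {
      at_anchor[[id]] <- NULL # marker: identical row
      insertions[[id]] <- list()
      next
    }
    if (panel$info$circular[panel$info$id == id]) g <- rotate_to_anchor(a, g, k)
    pw <- align_pair_anchored(a, g, k, band_extra, min_anchors, id)
    av <- strsplit(pw$a, "")[[1]]
    gv <- strsplit(pw$b, "")[[1]]
    is_anchor <- av != "-"
    apos <- cumsum(is_anchor) # anchor position of / before each column
    chars <- character(La)
    chars[apos[is_anchor]] <- gv[is_anchor]
    at_anchor[[id]] <- chars
    ins_idx <- which(!is_anchor)
    ins <- list()
    if (length(ins_idx) > 0) {
      before <- apos[ins_idx] + 1L # insertion precedes this anchor position
      ins <- lapply(split(gv[ins_idx], before), paste, collapse = "")
    }
    insertions[[id]] <- ins
  }
  # insertion length needed before each anchor position (index p = before p)
  ins_len <- integer(La + 1L)
  for (id in others) {
    for (p in names(insertions[[id]])) {
      pi <- as.integer(p)
      ins_len[pi] <- max(ins_len[pi], nchar(insertions[[id]][[p]]))
    }
  }
  total_cols <- La + sum(ins_len)
  # column index of anchor position p
  col_of <- cumsum(ins_len[1:La] + 1L)
  anchor_map <- rep(NA_integer_, total_cols)
  anchor_map[col_of] <- seq_len(La)
  build_row <- function(chars, ins) {
    if (sum(ins_len) == 0) return(paste(chars, collapse = ""))
    v <- rep("-", total_cols)
    v[col_of] <- chars
    for (p in names(ins)) {
      pi <- as.integer(p)
      s <- ins[[p]]
      start_col <- (if (pi <= La) col_of[pi] else total_cols + 1L) - ins_len[pi]
      v[start_col:(start_col + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    }
    paste(v, collapse = "")
  }
  anchor_chars <- strsplit(a, "")[[1]]
  rows <- c(setNames(build_row(anchor_chars, list()), anchor_id))
  for (id in others) {
    if (is.null(at_anchor[[id]])) {
      rows[id] <- rows[[anchor_id]]
    } else {
      rows[id] <- build_row(at_anchor[[id]], insertions[[id]])
    }
  }
  rows <- rows[panel$info$id]
  structure(list(
    anchor_id = anchor_id,
    ids = panel$info$id,
    groups = setNames(panel$info$group, panel$info$id),
    rows = rows,
    anchor_map = anchor_map
  ), class = "panel_alignment")
}

#' @export
print.panel_alignment <- function(x, ...) {
  cat("<panel_alignment> anchor ", x$anchor_id, ", ", length(x$rows),
      " rows x ", nchar(x$rows[[1]]), " columns (",
      sum(is.na(x$anchor_map)), " insertion columns)\n", sep = "")
  invisible(x)
}

#' Call fixed single-nucleotide differences between two genome groups
#'
#' A column of the panel alignment yields a diagnostic site iff it maps to an
#' anchor position (not an insertion), no row carries a gap or `N`, all
#' group-A rows share one base, all group-B rows share one base, and the two
#' bases differ. Indel columns never yield sites, so the table is usable on
#' reads down to the minimum molecule length.
#'
#' @param aln a `panel_alignment` from [align_to_anchor()].
#' @param group_A,group_B the two group labels to contrast.
#' @return data frame with columns `anchor_pos` (1-based), `allele_A`,
#'   `allele_B`, `is_transition`, sorted by `anchor_pos`; the group labels are
#'   kept in `attr(, "groups")`.
#' @export
call_diagnostic_sites <- function(aln, group_A, group_B) {
  stopifnot(inherits(aln, "panel_alignment"))
  rows_A <- names(aln$groups)[aln$groups == group_A]
  rows_B <- names(aln$groups)[aln$groups == group_B]
  if (length(rows_A) == 0 || length(rows_B) == 0)
    stop("configuration error: empty group in panel: ",
         if (length(rows_A) == 0) group_A else group_B)
  m <- lapply(aln$rows, charToRaw)
  gapN <- Reduce(`|`, lapply(m, function(r) r == charToRaw("-") | r == charToRaw("N")))
  fixed_base <- function(ids) {
    first <- m[[ids[1]]]
    same <- rep(TRUE, length(first))
    for (id in ids[-1]) same <- same & (m[[id]] == first)
    list(base = first, fixed = same)
  }
  fa <- fixed_base(rows_A)
  fb <- fixed_base(rows_B)
  ok <- !is.na(aln$anchor_map) & !gapN & fa$fixed & fb$fixed & (fa$base != fb$base)
  idx <- which(ok)
  aA <- rawToChar(fa$base[idx], multiple = TRUE)
  aB <- rawToChar(fb$base[idx], multiple = TRUE)
  out <- data.frame(
    anchor_pos = aln$anchor_map[idx],
    allele_A = aA,
    allele_B = aB,
    is_transition = paste(pmin(aA, aB), pmax(aA, aB)) %in% c("C T", "A G"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$anchor_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- c(A = group_A, B = group_B)
  out
}

#' Write a diagnostic site table as TSV
#'
#' Columns: `anchor_pos_1based`, `allele_<groupA>`, `allele_<groupB>`,
#' `is_transition`, sorted ascending.
#'
#' @param sites table from [call_diagnostic_sites()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_diagnostic_sites <- function(sites, path) {
  gr <- attr(sites, "groups")
  if (is.null(gr)) gr <- c(A = "A", B = "B")
  df <- data.frame(
    anchor_pos_1based = sites$anchor_pos,
    a = sites$allele_A, b = sites$allele_B,
    is_transition = sites$is_transition
  )
  colnames(df)[2:3] <- paste0("allele_", gr[c("A", "B")])
  write_tsv(df, path)
}

#' Write a panel alignment as aligned multi-FASTA
#'
#' @param aln a `panel_alignment`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_panel_alignment <- function(aln, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", names(aln$rows)), unname(aln$rows))),
             con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
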