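# Wraparound (phased) mapping of reads against a tandem satellite motif and
# per-position nucleotide-frequency profiling.

#' Map reads to a tandem repeat motif in wraparound phase
#'
#' Each read is aligned semi-globally against the motif concatenated
#' `ceiling(len / P) + 1` times, so reads spanning copy junctions map with a
#' phase in `[0, P)`. Both strands are tried; the best edit distance wins
#' (plus strand on ties). Reads above the divergence ceiling are no-hits.
#'
#' @param reads data frame with `read_id` and `seq`, or a named character
#'   vector.
#' @param motif motif consensus sequence (single string of length `P`).
#' @param min_len minimum read length in bp.
#' @param max_div maximum edits per aligned base; above it the read is a
#'   no-hit. Default 0.15 admits array divergence plus terminal damage.
#' @return data frame: `read_id`, `mapped`, `phase` (0-based, in `[0, P)`),
#'   `strand`, `start` (1-based on the concatenated motif), `edits`, `nm`,
#'   `cigar`, `seq_aln`.
#' @export
map_to_motif <- function(reads, motif, min_len = 30L, max_div = 0.15) {
  if (is.character(reads)) {
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%06d", seq_along(reads))
    reads <- data.frame(read_id = ids, seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  P <- nchar(motif)
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id, mapped = FALSE,
                    phase = NA_integer_, strand = NA_character_,
                    start = NA_integer_, edits = NA_integer_,
                    nm = NA_integer_, cigar = NA_character_,
                    seq_aln = NA_character_, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    len <- nchar(s)
    if (len < min_len) next
    ref <- strrep(motif, ceiling(len / P) + 1L)
    best <- NULL
    for (st in c("+", "-")) {
      q <- if (st == "+") s else revcomp(s)
      a <- cpp_semiglobal(q, ref)
      if (is.null(best) || a$edits < best$edits) {
        best <- a; best$strand <- st; best$seq_aln <- q
      }
    }
    if (best$edits / len > max_div) next
    out$mapped[i] <- TRUE
    out$phase[i] <- (best$start - 1L) %% P
    out$strand[i] <- best$strand
    out$start[i] <- best$start
    out$edits[i] <- best$edits
    out$nm[i] <- best$nm
    out$cigar[i] <- best$cigar
    out$seq_aln[i] <- best$seq_aln
  }
  out
}

#' Build a per-position nucleotide-frequency profile of a repeat motif
#'
#' Every aligned base of every phased alignment is tallied at its motif
#' position (alignment position modulo the period), strand-resolved.
#'
#' @param phased data frame from [map_to_motif()].
#' @param motif motif consensus (defines the period `P`).
#' @param sample_id sample name.
#' @return object of class `repeat_profile`: list with `sample`, `P`,
#'   `counts` (`P x 4` integer matrix over A,C,G,T), `coverage` (per-position
#'   totals) and `freqs` (row-normalised where coverage > 0, `NA` elsewhere).
#' @export
build_repeat_profile <- function(phased, motif, sample_id = "sample1") {
  P <- nchar(motif)
  hits <- phased[phased$mapped, , drop = FALSE]
  mpos_all <- integer(0)
  base_all <- character(0)
  for (i in seq_len(nrow(hits))) {
    pr <- aligned_pairs(hits$start[i], hits$cigar[i], nchar(hits$seq_aln[i]))
    mpos_all <- c(mpos_all, ((pr$rpos - 1L) %% P) + 1L)
    base_all <- c(base_all,
                  strsplit(hits$seq_aln[i], "")[[1]][pr$qpos])
  }
  counts <- table(factor(mpos_all, levels = seq_len(P)),
                  factor(base_all, levels = DNA_BASES))
  counts <- matrix(as.integer(counts), nrow = P, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  coverage <- rowSums(counts)
  freqs <- counts / ifelse(coverage > 0, coverage, NA)
  structure(list(sample = sample_id, P = P, counts = counts,
                 coverage = coverage, freqs = freqs),
            class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("<repeat_profile> sample ", x$sample, ", period ", x$P, " bp, ",
      sum(x$coverage), " bases over ", sum(x$coverage > 0),
      " covered positions\n", sep = "")
  invisible(x)
}

#' Compare repeat profiles across samples
#'
#' Pairwise distance between two profiles is the mean, over positions
#' covered in both, of the total-variation distance between their
#' base-frequency vectors. Also reports, per position, the maximum spread of
#' any base frequency across samples covering it.
#'
#' @param profiles list of `repeat_profile` objects (same period).
#' @return list with `pairs` (data frame `sample1`, `sample2`, `mean_tv`,
#'   `max_tv`, `n_positions`), `mean_tv`, `max_tv`, and `position_spread`
#'   (data frame `pos`, `spread`, `n_samples`).
#' @export
compare_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  P <- profiles[[1]]$P
  stopifnot(all(vapply(profiles, function(p) p$P, numeric(1)) == P))
  ids <- vapply(profiles, function(p) p$sample, character(1))
  pairs <- list()
  for (i in seq_along(profiles)) {
    for (j in seq_along(profiles)) {
      if (j <= i) next
      a <- profiles[[i]]; b <- profiles[[j]]
      both <- a$coverage > 0 & b$coverage > 0
      tv <- 0.5 * rowSums(abs(a$freqs - b$freqs))
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample1 = ids[i], sample2 = ids[j],
        mean_tv = mean(tv[both]), max_tv = if (any(both)) max(tv[both]) else NA,
        n_positions = sum(both), stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, pairs)
  spread <- vapply(seq_len(P), function(p) {
    f <- t(vapply(profiles, function(pr) pr$freqs[p, ], numeric(4)))
    f <- f[!is.na(f[, 1]), , drop = FALSE]
    if (nrow(f) < 2) return(NA_real_)
    max(apply(f, 2, function(col) diff(range(col))))
  }, numeric(1))
  n_samp <- vapply(seq_len(P), function(p) {
    sum(vapply(profiles, function(pr) pr$coverage[p] > 0, logical(1)))
  }, numeric(1))
  list(pairs = pairs,
       mean_tv = mean(pairs$mean_tv),
       max_tv = max(pairs$max_tv, na.rm = TRUE),
       position_spread = data.frame(pos = seq_len(P), spread = spread,
                                    n_samples = as.integer(n_samp)))
}

#' Write a repeat profile as TSV
#'
#' Columns: `pos_1based`, `A`, `C`, `G`, `T`, `coverage`, `freq_A`,
#' `freq_C`, `freq_G`, `freq_T`.
#'
#' @param profile a `repeat_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_repeat_profile <- function(profile, path) {
  fm <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  df <- data.frame(
    pos_1based = seq_len(profile$P),
    A = profile$counts[, "A"], C = profile$counts[, "C"],
    G = profile$counts[, "G"], T = profile$counts[, "T"],
    coverage = profile$coverage,
    freq_A = fm(profile$freqs[, "A"]), freq_C = fm(profile$freqs[, "C"]),
    freq_G = fm(profile$freqs[, "G"]), freq_T = fm(profile$freqs[, "T"]),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
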