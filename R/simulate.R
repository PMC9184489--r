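#' Default adapter used for simulated read-through
#'
#' A fixed, documented constant (the standard Illumina R1/R2 adapter stem) so
#' that adapter read-through of short inserts is deterministically detectable
#' by the pair merger.
#' @export
SIM_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Simulation configuration
#'
#' Bundles every knob of the synthetic sedaDNA generator. The defaults encode
#' the data-generating conditions this package validates against: 2 x 250 bp
#' paired-end reads, short lognormal fragment lengths typical of sedimentary
#' ancient DNA, strong terminal deamination decaying into the read, and a
#' predominantly off-target library (around 1% on-target reads, as seen in
#' chloroplast capture from lake sediments).
#'
#' @param seed master integer seed; every stage derives its own labelled
#'   child stream from it.
#' @param n_fragments number of target-genome fragments to draw.
#' @param mixture named numeric vector of species-group proportions (must sum
#'   to 1).
#' @param frag_meanlog,frag_sdlog lognormal fragment-length parameters (bp on
#'   the natural scale; default median 70 bp).
#' @param frag_min,frag_max truncation bounds of fragment length in bp.
#' @param d0 5'-terminal C-to-T deamination amplitude.
#' @param lambda per-base exponential decay of deamination into the read.
#' @param e position-independent background rate of the damage channels.
#' @param seq_error per-base sequencing error rate outside the damage
#'   channels.
#' @param read_len paired-end read length in bp.
#' @param duplicate_rate probability that a library molecule is re-emitted as
#'   a PCR duplicate.
#' @param background_frac fraction of fragments drawn from a non-target
#'   source.
#' @param repeat_spec list with `P` (motif length, bp), `copies`, and
#'   `divergence` (per-base substitution rate of array copies from the
#'   consensus).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_fragments = 10000L,
                              mixture = c(A = 0.5, B = 0.5),
                              frag_meanlog = log(70), frag_sdlog = 0.35,
                              frag_min = 20L, frag_max = 500L,
                              d0 = 0.3, lambda = 0.3, e = 0.01,
                              seq_error = 0.001,
                              read_len = 250L,
                              duplicate_rate = 0.2,
                              background_frac = 0.99,
                              repeat_spec = list(P = 173L, copies = 200L,
                                                 divergence = 0.05)) {
  stopifnot(abs(sum(mixture) - 1) < 1e-9,
            all(c(d0, e, seq_error, duplicate_rate, background_frac) >= 0),
            all(c(d0, e, seq_error, duplicate_rate, background_frac) <= 1),
            lambda >= 0, frag_min >= 1, frag_max >= frag_min, read_len >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a reference panel with implanted diagnostic sites
#'
#' Builds a random base genome and two (or more) groups of genomes that are
#' fixed-different at exactly `n_sites` positions, with additional
#' within-group polymorphisms at distinct positions. The returned truth table
#' has the same shape as [call_diagnostic_sites()] output, which makes the
#' site caller directly checkable against construction.
#'
#' @param n_per_group named integer vector: genomes per group (names are the
#'   group labels; the first group supplies the anchor genome).
#' @param genome_len genome length in bp.
#' @param n_sites number of implanted fixed inter-group differences.
#' @param within_group_snps number of within-group polymorphic positions
#'   (each private to one group and segregating inside it).
#' @param seed integer seed.
#' @param transition_frac fraction of implanted site allele pairs that are
#'   transitions (C/T or A/G); organelle SNPs are transition-biased.
#' @return list with `panel` (a `reference_panel`), `sites` (truth table with
#'   `anchor_pos`, `allele_A`, `allele_B`, `is_transition`) and `anchor_id`.
#' @export
generate_panel <- function(n_per_group = c(A = 5L, B = 5L),
                           genome_len = 120000L, n_sites = 157L,
                           within_group_snps = 20L, seed = 1L,
                           transition_frac = 0.6) {
  stopifnot(length(n_per_group) >= 2, !is.null(names(n_per_group)),
            all(n_per_group >= 1))
  if (n_sites > genome_len / 10)
    stop("input error: n_sites exceeds genome_len/10")
  gA <- names(n_per_group)[1]
  gB <- names(n_per_group)[2]
  with_seed(child_seed(seed, "generate_panel"), {
    base <- strsplit(random_dna(1, genome_len), "")[[1]]
    pos <- sample.int(genome_len, n_sites + within_group_snps)
    site_pos <- pos[seq_len(n_sites)] # unsorted; sorted only in the truth table
    poly_pos <- pos[-seq_len(n_sites)]
    transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
    allele_A <- sample(DNA_BASES, n_sites, replace = TRUE)
    is_ts <- runif(n_sites) < transition_frac
    allele_B <- character(n_sites)
    allele_B[is_ts] <- transition_partner[allele_A[is_ts]]
    tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
    if (any(!is_ts)) {
      allele_B[!is_ts] <- vapply(allele_A[!is_ts], function(b) {
        sample(tv_choices[[b]], 1)
      }, character(1))
    }
    ids <- unlist(lapply(names(n_per_group), function(g) {
      sprintf("%s_g%02d", g, seq_len(n_per_group[[g]]))
    }))
    groups <- rep(names(n_per_group), n_per_group)
    seqs <- list()
    for (i in seq_along(ids)) {
      v <- base
      if (groups[i] == gA) v[site_pos] <- allele_A
      if (groups[i] == gB) v[site_pos] <- allele_B
      seqs[[ids[i]]] <- v
    }
    # within-group polymorphisms: random group, alternate base in a random
    # nonempty proper subset of that group's genomes
    for (p in poly_pos) {
      g <- sample(names(n_per_group), 1)
      members <- ids[groups == g]
      if (length(members) < 2) next
      carriers <- sample(members, sample.int(length(members) - 1L, 1))
      cur <- seqs[[members[1]]][p]
      alt <- sample(setdiff(DNA_BASES, cur), 1)
      for (id in carriers) seqs[[id]][p] <- alt
    }
    seq_str <- vapply(seqs, paste, character(1), collapse = "")
    info <- data.frame(id = ids, group = groups, circular = FALSE,
                       length = genome_len, stringsAsFactors = FALSE)
    panel <- structure(list(info = info, seq = seq_str),
                       class = "reference_panel")
    ord <- order(site_pos)
    sites <- data.frame(
      anchor_pos = site_pos[ord],
      allele_A = allele_A[ord],
      allele_B = allele_B[ord],
      stringsAsFactors = FALSE
    )
    sites$is_transition <- paste(pmin(sites$allele_A, sites$allele_B),
                                 pmax(sites$allele_A, sites$allele_B)) %in%
      c("C T", "A G")
    attr(sites, "groups") <- c(A = gA, B = gB)
    list(panel = panel, sites = sites, anchor_id = ids[1])
  })
}

# truncated lognormal fragment lengths by resampling
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(rlnorm(max(n - length(out), 1) * 2L, meanlog, sdlog))
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(out[seq_len(n)])
}

#' Sample fragments from a genome
#'
#' Uniform start positions and strands; fragment lengths are lognormal,
#' truncated to the configured bounds and to the genome length. Truth
#' coordinates are recorded for every fragment.
#'
#' @param seq genome sequence (single character string).
#' @param n number of fragments.
#' @param meanlog,sdlog,frag_min,frag_max fragment-length distribution.
#' @param seed integer seed.
#' @param source_id id recorded in the `source_id` column.
#' @return data frame: `source_id`, `start` (1-based on the source), `len`,
#'   `strand`, `seq` (fragment in molecule orientation).
#' @export
sample_fragments <- function(seq, n, meanlog = log(70), sdlog = 0.35,
                             frag_min = 20L, frag_max = 500L, seed = 1L,
                             source_id = "genome") {
  stopifnot(n >= 0)
  if (n == 0) {
    return(data.frame(source_id = character(0), start = integer(0),
                      len = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  L <- nchar(seq)
  with_seed(child_seed(seed, paste0("fragments:", source_id)), {
    len <- pmin(rlnorm_trunc(n, meanlog, sdlog, frag_min, frag_max), L)
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag <- substring(seq, start, start + len - 1L)
    frag[strand == "-"] <- revcomp(frag[strand == "-"])
    data.frame(source_id = source_id, start = start, len = len,
               strand = strand, seq = frag, stringsAsFactors = FALSE)
  })
}

#' Apply terminal deamination damage and sequencing error to fragments
#'
#' Each `C` at 0-based distance `i` from the molecule's 5' end becomes `T`
#' with probability `e + d0 * exp(-lambda * i)`; symmetrically each `G` at
#' distance `j` from the 3' end becomes `A` with probability
#' `e + d0 * exp(-lambda * j)`. All remaining positions suffer an independent
#' uniform sequencing error at rate `seq_error`. Damage counts per fragment
#' are recorded for truth tables.
#'
#' @param fragments data frame with a `seq` column (molecule orientation).
#' @param d0,lambda,e damage model parameters.
#' @param seq_error per-base sequencing error rate.
#' @param seed integer seed.
#' @return the input data frame with `seq` replaced by the damaged sequence
#'   and columns `n_damage_5p`, `n_damage_3p` added.
#' @export
apply_damage <- function(fragments, d0 = 0.3, lambda = 0.3, e = 0.01,
                         seq_error = 0.001, seed = 1L) {
  stopifnot(all(c(d0, e, seq_error) >= 0), all(c(d0, e, seq_error) <= 1),
            lambda >= 0)
  n <- nrow(fragments)
  if (n == 0) {
    fragments$n_damage_5p <- integer(0)
    fragments$n_damage_3p <- integer(0)
    return(fragments)
  }
  with_seed(child_seed(seed, "damage"), {
    lens <- nchar(fragments$seq)
    chars <- strsplit(paste(fragments$seq, collapse = ""), "")[[1]]
    pos5 <- sequence(lens) - 1L
    pos3 <- rep(lens, lens) - sequence(lens)
    fid <- rep(seq_len(n), lens)
    isC <- chars == "C"
    isG <- chars == "G"
    u <- runif(length(chars))
    ct <- isC & u < e + d0 * exp(-lambda * pos5)
    ga <- isG & u < e + d0 * exp(-lambda * pos3)
    err <- !isC & !isG & u < seq_error
    chars[ct] <- "T"
    chars[ga] <- "A"
    if (any(err)) {
      idx <- which(err)
      pick <- ceiling(runif(length(idx)) * 3)
      alt <- vapply(seq_along(idx), function(t) {
        setdiff(DNA_BASES, chars[idx[t]])[pick[t]]
      }, character(1))
      chars[idx] <- alt
    }
    big <- paste(chars, collapse = "")
    ends <- cumsum(lens)
    fragments$seq <- substring(big, ends - lens + 1L, ends)
    cnt5 <- rowsum(as.integer(ct), fid)
    cnt3 <- rowsum(as.integer(ga), fid)
    fragments$n_damage_5p <- as.integer(cnt5[, 1])
    fragments$n_damage_3p <- as.integer(cnt3[, 1])
    fragments
  })
}

#' Turn fragments into paired-end reads
#'
#' Mate 1 is the first `read_len` bases of the fragment, padded by the fixed
#' adapter on read-through; mate 2 is the same from the reverse complement.
#'
#' @param fragments data frame with `seq` column.
#' @param read_len read length in bp.
#' @param adapter adapter sequence used for read-through padding.
#' @return data frame: `read_id`, `mate1`, `mate2`.
#' @export
to_paired_reads <- function(fragments, read_len = 250L, adapter = SIM_ADAPTER) {
  n <- nrow(fragments)
  ids <- if (!is.null(fragments$read_id)) fragments$read_id else
    sprintf("frag%06d", seq_len(n))
  if (n == 0) {
    return(data.frame(read_id = character(0), mate1 = character(0),
                      mate2 = character(0), stringsAsFactors = FALSE))
  }
  pad <- strrep(adapter, ceiling(read_len / nchar(adapter)) + 1L)
  m1 <- substr(paste0(fragments$seq, pad), 1L, read_len)
  m2 <- substr(paste0(revcomp(fragments$seq), pad), 1L, read_len)
  data.frame(read_id = ids, mate1 = m1, mate2 = m2, stringsAsFactors = FALSE)
}

#' Generate a tandem satellite-repeat array
#'
#' A random consensus motif of length `P` is repeated `copies` times; each
#' copy is independently mutated by substitutions at the given per-base rate.
#'
#' @param motif_len motif length `P` in bp (reference case 173).
#' @param copies number of tandem copies.
#' @param divergence per-base substitution rate per copy.
#' @param seed integer seed.
#' @return list with `consensus` and `array` (length `P * copies`).
#' @export
generate_repeat_array <- function(motif_len = 173L, copies = 200L,
                                  divergence = 0.05, seed = 1L) {
  stopifnot(motif_len >= 1, copies >= 1, divergence >= 0, divergence <= 1)
  with_seed(child_seed(seed, "repeat_array"), {
    consensus <- random_dna(1, motif_len)
    if (divergence == 0) {
      return(list(consensus = consensus, array = strrep(consensus, copies)))
    }
    cons_chars <- strsplit(consensus, "")[[1]]
    copies_chr <- vapply(seq_len(copies), function(i) {
      v <- cons_chars
      hit <- which(runif(motif_len) < divergence)
      if (length(hit) > 0) {
        v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1))
      }
      paste(v, collapse = "")
    }, character(1))
    list(consensus = consensus, array = paste(copies_chr, collapse = ""))
  })
}

#' Generate non-target background fragments
#'
#' Fragments drawn either from a supplied genome sequence or from a fresh
#' random genome, labelled `background` so downstream precision/recall can be
#' computed against truth.
#'
#' @param source a genome sequence string, or `"random"` for a fresh random
#'   genome of length `random_len`.
#' @param n number of fragments.
#' @param meanlog,sdlog,frag_min,frag_max fragment-length distribution.
#' @param seed integer seed.
#' @param random_len length of the random genome when `source = "random"`.
#' @return fragment data frame as in [sample_fragments()], with `source_id`
#'   set to `"background"`.
#' @export
generate_background <- function(source = "random", n, meanlog = log(70),
                                sdlog = 0.35, frag_min = 20L, frag_max = 500L,
                                seed = 1L, random_len = 100000L) {
  seq <- if (identical(source, "random")) {
    with_seed(child_seed(seed, "background_genome"), random_dna(1, random_len))
  } else source
  sample_fragments(seq, n, meanlog, sdlog, frag_min, frag_max,
                   seed = child_seed(seed, "background_frags"),
                   source_id = "background")
}

#' Simulate a complete truth-labelled read set
#'
#' Draws target fragments from a species mixture over a reference panel and
#' background fragments from a non-target genome, applies deamination damage
#' and sequencing error, re-emits PCR duplicates, and renders paired-end
#' reads. Fully deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @param panel a `reference_panel` whose groups cover
#'   `names(config$mixture)`.
#' @param sample_id id recorded for the sample.
#' @return list with `reads` (read_id/mate1/mate2), `truth` (one row per
#'   emitted read pair: `read_id`, `group`, `source_id`, `frag_start_1based`,
#'   `frag_len`, `strand`, `n_damage_5p`, `n_damage_3p`, `is_duplicate`) and
#'   `fragments` (damaged fragment sequences, molecule orientation).
#' @export
simulate_readset <- function(config, panel, sample_id = "sample1") {
  stopifnot(inherits(config, "simulation_config"),
            inherits(panel, "reference_panel"))
  groups <- names(config$mixture)
  if (!all(groups %in% panel$info$group))
    stop("configuration error: mixture group(s) absent from panel: ",
         paste(setdiff(groups, panel$info$group), collapse = ", "))
  n_bg <- with_seed(child_seed(config$seed, "n_background"),
                    rbinom(1, config$n_fragments, config$background_frac))
  n_target <- config$n_fragments - n_bg
  alloc <- with_seed(child_seed(config$seed, "mixture_alloc"),
                     as.integer(rmultinom(1, n_target, config$mixture)))
  frags <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    if (alloc[gi] == 0) next
    members <- panel$info$id[panel$info$group == g]
    per_genome <- with_seed(
      child_seed(config$seed, paste0("genome_alloc:", g)),
      as.integer(rmultinom(1, alloc[gi], rep(1, length(members))))
    )
    for (mi in seq_along(members)) {
      if (per_genome[mi] == 0) next
      f <- sample_fragments(panel$seq[[members[mi]]], per_genome[mi],
                            config$frag_meanlog, config$frag_sdlog,
                            config$frag_min, config$frag_max,
                            seed = child_seed(config$seed,
                                              paste0("frag:", members[mi])),
                            source_id = members[mi])
      f$group <- g
      frags[[length(frags) + 1L]] <- f
    }
  }
  if (n_bg > 0) {
    bg <- generate_background("random", n_bg, config$frag_meanlog,
                              config$frag_sdlog, config$frag_min,
                              config$frag_max,
                              seed = child_seed(config$seed, "background"))
    bg$group <- "background"
    frags[[length(frags) + 1L]] <- bg
  }
  frags <- do.call(rbind, frags)
  if (is.null(frags) || nrow(frags) == 0) {
    frags <- data.frame(source_id = character(0), start = integer(0),
                        len = integer(0), strand = character(0),
                        seq = character(0), group = character(0),
                        stringsAsFactors = FALSE)
  }
  frags <- apply_damage(frags, config$d0, config$lambda, config$e,
                        config$seq_error,
                        seed = child_seed(config$seed, "apply_damage"))
  n <- nrow(frags)
  frags$read_id <- sprintf("%s_frag%06d", sample_id, seq_len(max(n, 0L)))
  frags$is_duplicate <- FALSE
  if (n > 0 && config$duplicate_rate > 0) {
    dup <- with_seed(child_seed(config$seed, "duplicates"),
                     which(runif(n) < config$duplicate_rate))
    if (length(dup) > 0) {
      d <- frags[dup, , drop = FALSE]
      d$read_id <- paste0(d$read_id, "_dup1")
      d$is_duplicate <- TRUE
      frags <- rbind(frags, d)
    }
  }
  reads <- to_paired_reads(frags, config$read_len)
  truth <- data.frame(
    read_id = frags$read_id,
    group = frags$group,
    source_id = frags$source_id,
    frag_start_1based = frags$start,
    frag_len = frags$len,
    strand = frags$strand,
    n_damage_5p = frags$n_damage_5p,
    n_damage_3p = frags$n_damage_3p,
    is_duplicate = frags$is_duplicate,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  rownames(frags) <- NULL
  list(reads = reads, truth = truth, fragments = frags)
}

#' Write paired FASTQ files (gzip)
#'
#' @param reads data frame from [to_paired_reads()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz` with flat base qualities.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (m in 1:2) {
    seqs <- reads[[paste0("mate", m)]]
    con <- gzfile(paths[m], open = "wb")
    lines <- as.vector(rbind(paste0("@", reads$read_id, "/", m), seqs,
                             "+", strrep("I", nchar(seqs))))
    writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read table
#'
#' @param r1,r2 paths to the two mate files (optionally gzipped).
#' @return data frame `read_id`, `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readBStringSet(r1, format = "fastq")
  s2 <- Biostrings::readBStringSet(r2, format = "fastq")
  ids <- sub("/[12]$", "", vapply(strsplit(names(s1), "\\s+"), `[[`,
                                  character(1), 1L))
  out <- data.frame(read_id = ids, mate1 = unname(as.character(s1)),
                    mate2 = unname(as.character(s2)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
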