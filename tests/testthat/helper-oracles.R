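# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain per-column scans and plain
# dynamic programming.

# brute-force diagnostic-site caller: loop over alignment columns applying
# the three criteria literally
oracle_call_sites <- function(aln, group_A, group_B) {
  ids_A <- names(aln$groups)[aln$groups == group_A]
  ids_B <- names(aln$groups)[aln$groups == group_B]
  ncol <- nchar(aln$rows[[1]])
  out <- list()
  for (j in seq_len(ncol)) {
    if (is.na(aln$anchor_map[j])) next
    col <- vapply(aln$rows, function(r) substr(r, j, j), character(1))
    if (any(col %in% c("-", "N"))) next
    ca <- col[ids_A]; cb <- col[ids_B]
    if (length(unique(ca)) != 1 || length(unique(cb)) != 1) next
    if (ca[1] == cb[1]) next
    out[[length(out) + 1L]] <- data.frame(
      anchor_pos = aln$anchor_map[j], allele_A = unname(ca[1]),
      allele_B = unname(cb[1]),
      is_transition = paste(sort(c(ca[1], cb[1])), collapse = "") %in%
        c("CT", "AG"),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(anchor_pos = integer(0), allele_A = character(0),
                      allele_B = character(0), is_transition = logical(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$anchor_pos), , drop = FALSE]
}

# full-DP semi-global edit distance (read global, reference end gaps free)
oracle_semiglobal_edits <- function(q, r) {
  m <- nchar(q); n <- nchar(r)
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  prev <- rep(0, n + 1)
  for (i in 1:m) {
    cur <- numeric(n + 1)
    cur[1] <- i
    for (j in 1:n) {
      cur[j + 1] <- min(prev[j] + (qc[i] != rc[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  min(prev)
}

# phase-anchored alignment cost: read aligned from reference position 0 of a
# tandem array starting at rotation r, right end free
oracle_phase_cost <- function(q, tandem) {
  m <- nchar(q); n <- nchar(tandem)
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(tandem, "")[[1]]
  INF <- 1e9
  prev <- c(0, rep(INF, n))
  for (i in 1:m) {
    cur <- rep(INF, n + 1)
    cur[1] <- i
    for (j in 1:n) {
      cur[j + 1] <- min(prev[j] + (qc[i] != rc[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  min(prev)
}

# best-of-all-rotations oracle for wraparound motif mapping: cost and argmin
# phase set over both strands
oracle_rotation_map <- function(read, motif) {
  P <- nchar(motif)
  doubled <- paste0(motif, motif)
  copies <- ceiling(nchar(read) / P) + 1L
  costs <- matrix(NA_real_, nrow = P, ncol = 2,
                  dimnames = list(NULL, c("+", "-")))
  for (r in 0:(P - 1)) {
    rot <- paste0(substr(doubled, r + 1, r + P))
    tandem <- strrep(rot, copies)
    costs[r + 1, "+"] <- oracle_phase_cost(read, tandem)
    costs[r + 1, "-"] <- oracle_phase_cost(sedadiag::revcomp(read), tandem)
  }
  best <- min(costs)
  list(edits = best,
       phases = which(apply(costs, 1, min) == best) - 1L)
}

# exhaustive k-mer -> LCA assignment by scanning every genome (and its
# reverse complement) for every candidate k-mer
oracle_kmer_assignment <- function(genomes, parent, leaf_of, k) {
  paths <- list()
  for (node in names(parent)) {
    p <- node; cur <- node
    while (!is.na(parent[[cur]])) { cur <- parent[[cur]]; p <- c(cur, p) }
    paths[[node]] <- p
  }
  all_km <- character(0)
  for (s in genomes) {
    all_km <- c(all_km, substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  }
  all_km <- unique(all_km[grepl("^[ACGT]+$", all_km)])
  rc <- sedadiag::revcomp(all_km)
  all_km <- unique(ifelse(all_km <= rc, all_km, rc))
  targets <- paste(genomes, sedadiag::revcomp(genomes), sep = "#")
  out <- character(length(all_km))
  names(out) <- all_km
  for (i in seq_along(all_km)) {
    km <- all_km[i]
    hit <- names(genomes)[grepl(km, targets, fixed = TRUE) |
                            grepl(sedadiag::revcomp(km), targets, fixed = TRUE)]
    leaves <- unique(unname(leaf_of[hit]))
    out[i] <- if (length(leaves) == 1) leaves else {
      common <- Reduce(intersect, paths[leaves])
      common[length(common)]
    }
  }
  out
}

random_genome <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# small handmade panel-alignment object for column-scan tests
toy_alignment <- function(rows, groups, anchor_map = NULL) {
  if (is.null(anchor_map)) anchor_map <- seq_len(nchar(rows[[1]]))
  structure(list(anchor_id = names(rows)[1], ids = names(rows),
                 groups = groups, rows = rows, anchor_map = anchor_map),
            class = "panel_alignment")
}

make_panel <- function(seqs, groups, circular = FALSE) {
  structure(list(
    info = data.frame(id = names(seqs), group = unname(groups[names(seqs)]),
                      circular = circular, length = nchar(seqs),
                      stringsAsFactors = FALSE),
    seq = seqs
  ), class = "reference_panel")
}
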