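# Simplified k-mer LCA read classifier with confidence-threshold semantics.
# Deliberately not a clone of the production classifiers (no minimizers, no
# spaced seeds); the
# confidence denominator is the number of k-mers queried from the read
# (hit or miss). What matters downstream is the threshold semantics: a read
# is kept only if the k-mer support along the root-to-label path reaches the
# configured fraction of its k-mers.

# root-to-node paths for every node of a small rooted taxonomy; `parent` is a
# named character vector, the root maps to NA
taxonomy_paths <- function(parent) {
  stopifnot(is.character(parent), !is.null(names(parent)))
  roots <- names(parent)[is.na(parent)]
  if (length(roots) != 1)
    stop("configuration error: taxonomy must have exactly one root")
  paths <- list()
  for (node in names(parent)) {
    p <- node
    cur <- node
    steps <- 0
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      if (!cur %in% names(parent))
        stop("configuration error: parent '", cur, "' not a taxonomy node")
      p <- c(cur, p)
      steps <- steps + 1
      if (steps > length(parent)) stop("configuration error: taxonomy cycle")
    }
    paths[[node]] <- p
  }
  paths
}

tax_lca <- function(nodes, paths) {
  common <- Reduce(intersect, paths[nodes])
  common[length(common)]
}

tax_descendants <- function(node, parent) {
  out <- node
  repeat {
    kids <- names(parent)[!is.na(parent) & parent %in% out & !names(parent) %in% out]
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  out
}

canonical_kmers <- function(kmers) {
  rc <- cpp_revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Build a k-mer LCA index over labelled genomes
#'
#' Every canonical k-mer (lexicographic minimum of the k-mer and its reverse
#' complement) is assigned to the lowest common ancestor of all source
#' genomes containing it, in a small user-supplied rooted taxonomy. K-mers
#' containing non-ACGT characters are skipped.
#'
#' @param genomes named character vector of genome sequences.
#' @param parent named character vector: taxonomy node to parent node; the
#'   root maps to `NA`.
#' @param leaf_of named character vector mapping genome id to its taxonomy
#'   leaf; defaults to genome ids being leaves themselves.
#' @param k k-mer length; odd, between 15 and 31.
#' @return object of class `kmer_index`: list with `k`, `env` (k-mer to node
#'   hash), `parent`, `paths`, `leaf_of`.
#' @export
build_kmer_index <- function(genomes, parent,
                             leaf_of = setNames(names(genomes), names(genomes)),
                             k = 21) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  if (k %% 2 != 1 || k < 15 || k > 31)
    stop("configuration error: k must be odd and in [15, 31]")
  paths <- taxonomy_paths(parent)
  missing <- setdiff(names(genomes), names(leaf_of))
  if (length(missing) > 0)
    stop("configuration error: genome(s) without taxonomy leaf: ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unname(leaf_of[names(genomes)]), names(parent))
  if (length(bad) > 0)
    stop("configuration error: leaf node(s) not in taxonomy: ",
         paste(bad, collapse = ", "))
  km_all <- character(0)
  leaf_all <- character(0)
  for (id in names(genomes)) {
    s <- toupper(genomes[[id]])
    if (nchar(s) < k) next
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    km <- unique(km[grepl("^[ACGT]+$", km)])
    km <- unique(canonical_kmers(km))
    km_all <- c(km_all, km)
    leaf_all <- c(leaf_all, rep(leaf_of[[id]], length(km)))
  }
  assignment <- tapply(leaf_all, km_all, function(leaves) {
    leaves <- unique(leaves)
    if (length(leaves) == 1) leaves else tax_lca(leaves, paths)
  })
  env <- list2env(as.list(assignment), hash = TRUE,
                  size = max(length(assignment), 1L))
  structure(list(k = k, env = env, parent = parent, paths = paths,
                 leaf_of = leaf_of),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", length(x$env), " k-mers, ",
      length(x$parent), " taxonomy nodes\n", sep = "")
  invisible(x)
}

#' Classify reads against a k-mer LCA index
#'
#' For each read, all its k-mers are queried (in canonical form). The
#' candidate label is the taxonomy node maximising the summed k-mer support
#' along its root-to-node path; ties are broken toward the root (the LCA of
#' the tied nodes). Confidence is that path support divided by the number of
#' k-mers queried, and the label is kept only when confidence reaches the
#' threshold.
#'
#' @param reads character vector of sequences, or a data frame with columns
#'   `read_id` and `seq`.
#' @param index a `kmer_index` from [build_kmer_index()].
#' @param threshold minimum confidence in `[0, 1]` (default 0.8, a very
#'   conservative setting).
#' @return data frame: `read_id`, `label` (taxonomy node or
#'   `"unclassified"`), `confidence`, `n_support`, `n_queried`.
#' @export
classify_reads <- function(reads, index, threshold = 0.8) {
  stopifnot(inherits(index, "kmer_index"), threshold >= 0, threshold <= 1)
  if (is.character(reads)) {
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%06d", seq_along(reads))
    reads <- data.frame(read_id = ids, seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  k <- index$k
  nodes <- names(index$parent)
  n <- nrow(reads)
  label <- character(n); conf <- numeric(n)
  n_support <- integer(n); n_queried <- integer(n)
  for (i in seq_len(n)) {
    s <- toupper(reads$seq[i])
    if (is.na(s) || nchar(s) < k) {
      label[i] <- "unclassified"; conf[i] <- 0
      n_support[i] <- 0L; n_queried[i] <- 0L
      next
    }
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    n_queried[i] <- length(km)
    ok <- grepl("^[ACGT]+$", km)
    hits <- character(0)
    if (any(ok)) {
      canon <- canonical_kmers(km[ok])
      got <- mget(canon, envir = index$env, ifnotfound = NA_character_)
      hits <- unlist(got, use.names = FALSE)
      hits <- hits[!is.na(hits)]
    }
    if (length(hits) == 0) {
      label[i] <- "unclassified"; conf[i] <- 0
      n_support[i] <- 0L
      next
    }
    tab <- table(hits)
    path_support <- vapply(nodes, function(nd) {
      sum(tab[intersect(index$paths[[nd]], names(tab))])
    }, numeric(1))
    best <- max(path_support)
    cand <- nodes[path_support == best]
    lab <- if (length(cand) == 1) cand else tax_lca(cand, index$paths)
    n_support[i] <- as.integer(best)
    conf[i] <- best / n_queried[i]
    label[i] <- if (conf[i] >= threshold) lab else "unclassified"
  }
  data.frame(read_id = reads$read_id, label = label, confidence = conf,
             n_support = n_support, n_queried = n_queried,
             stringsAsFactors = FALSE)
}

#' Filter a read set to a target clade
#'
#' Keeps the reads whose classification label is the target node or one of
#' its descendants at the given confidence threshold.
#'
#' @param reads data frame with `read_id` and `seq` columns (merged
#'   fragments), or a named character vector.
#' @param index a `kmer_index`.
#' @param threshold confidence threshold.
#' @param target_node taxonomy node defining the clade to keep.
#' @return list with `kept` (subset of `reads`) and `calls` (the full
#'   classification table).
#' @export
filter_readset <- function(reads, index, threshold = 0.8, target_node) {
  stopifnot(target_node %in% names(index$parent))
  if (is.character(reads)) {
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%06d", seq_along(reads))
    reads <- data.frame(read_id = ids, seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  calls <- classify_reads(reads, index, threshold)
  clade <- tax_descendants(target_node, index$parent)
  kept <- reads[calls$label %in% clade, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, calls = calls)
}

#' Write a classification table as TSV
#'
#' Columns: `read_id`, `label`, `confidence`, `n_support`, `n_queried`.
#' @param calls table from [classify_reads()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tax_calls <- function(calls, path) {
  calls$confidence <- format(calls$confidence, digits = 6, trim = TRUE)
  write_tsv(calls, path)
}
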