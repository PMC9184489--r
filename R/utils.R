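#' @useDynLib sedadiag, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom rlnorm rmultinom median quantile cor setNames
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character strings. Characters
#' outside `ACGTacgt` become `N`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# Deterministic child seed for a labelled stage, keeping the result a valid
# 32-bit R seed. Stages drawing random numbers each use their own stream so
# they can be regenerated independently.
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  s <- ((seed %% 2147483647) * 48271) %% 2147483647 # stays exact in doubles
  as.integer((s + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Half-up rounding used for all emitted percentages (two decimals by default).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# All tables leave the package as plain TSV: UTF-8, LF, no quoting.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(colnames(df), collapse = "\t"),
    do.call(paste, c(lapply(df, as.character), sep = "\t"))
  )
  if (nrow(df) == 0) lines <- lines[1]
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA, check.names = FALSE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# substring of a circular sequence starting at `start` (1-based), length `len`
substr_circular <- function(seq, start, len) {
  L <- nchar(seq)
  start <- ((start - 1) %% L) + 1
  if (start + len - 1 <= L) return(substr(seq, start, start + len - 1))
  paste0(substr(seq, start, L), substr(seq, 1, len - (L - start + 1)))
}
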