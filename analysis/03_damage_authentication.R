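#!/usr/bin/env Rscript
# Ancient-DNA authentication: terminal C->T / G->A profiles per sample, the
# exponential model fit f(i) = e + d0*exp(-lambda*i), and the verdicts.
#
# Reads results/data/, writes results/damage/.

suppressMessages(library(sedadiag))
ind <- "results/data"
out <- "results/damage"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- build_panel(file.path(ind, "panel.fa"),
                     read_label_map(file.path(ind, "labels.tsv")),
                     circular = FALSE)
anchor_id <- readLines(file.path(ind, "anchor_id.txt"))
anchor <- panel$seq[[anchor_id]]
parent <- c(root = NA_character_, larix = "root",
            gmelinii = "larix", sibirica = "larix")
index <- build_kmer_index(panel$seq, parent,
                          leaf_of = setNames(panel$info$group, panel$info$id),
                          k = 21)

fq1 <- list.files(ind, pattern = "_R1\\.fastq\\.gz$", full.names = TRUE)
fq1 <- fq1[!grepl("_repeat_R1", fq1)]
snames <- sub("_R1\\.fastq\\.gz$", "", basename(fq1))
rows <- list()
for (i in seq_along(snames)) {
  s <- snames[i]
  reads <- read_fastq_pairs(fq1[i], sub("_R1", "_R2", fq1[i]))
  mg <- merge_pairs(reads)
  fl <- filter_readset(mg$merged, index, 0.8, "larix")
  al <- deduplicate(map_reads(fl$kept, anchor, anchor_id = anchor_id))
  if (nrow(al) == 0) {
    rows[[s]] <- data.frame(sample = s, n = 0, d0 = NA, lambda = NA, e = NA,
                            d0_lo = NA, d0_hi = NA,
                            verdict = "insufficient data")
    next
  }
  prof <- profile_damage(al, anchor)
  par <- fit_damage(prof)
  auth <- authenticate_damage(par, prof, seed = 20260921L + i)
  write_damage_profile(prof, file.path(out, paste0(s, "_profile.tsv")))
  write_damage_params(par, file.path(out, paste0(s, "_params.json")))
  rows[[s]] <- data.frame(sample = s, n = nrow(al), d0 = par$d0,
                          lambda = par$lambda, e = par$e,
                          d0_lo = auth$d0_ci[1], d0_hi = auth$d0_ci[2],
                          verdict = auth$verdict)
  cat(sprintf("%-14s n=%5d  d0=%.3f [%.3f, %.3f]  lambda=%.2f  -> %s\n",
              s, nrow(al), par$d0, auth$d0_ci[1], auth$d0_ci[2], par$lambda,
              auth$verdict))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "damage_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("damage summaries written to", out, "\n")
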