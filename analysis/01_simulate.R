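#!/usr/bin/env Rscript
# Simulates a sediment-core scenario with known truth: a reference panel of
# two larch-like chloroplast groups fixed-different at 157 positions, and
# five "samples" whose species mixtures and damage levels follow a
# plausible core history (old, heavily damaged, gmelinii-dominated layers;
# a mid-record sibirica influx; a recent sibirica-rich layer; one negative
# control that is almost entirely background).
#
# Outputs under results/data/: panel FASTA + label map, diagnostic-site
# truth table, per-sample paired FASTQ + truth tables, repeat-array motif
# and per-sample repeat FASTQ.

suppressMessages(library(sedadiag))
seed <- 20260921L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gen <- generate_panel(c(gmelinii = 5, sibirica = 5), genome_len = 120000,
                      n_sites = 157, within_group_snps = 30, seed = seed)
writeLines(as.vector(rbind(paste0(">", names(gen$panel$seq)),
                           unname(gen$panel$seq))),
           file.path(out, "panel.fa"))
writeLines(c("id\tgroup",
             paste(gen$panel$info$id, gen$panel$info$group, sep = "\t")),
           file.path(out, "labels.tsv"))
write_diagnostic_sites(gen$sites, file.path(out, "sites_truth.tsv"))
writeLines(gen$anchor_id, file.path(out, "anchor_id.txt"))
cat("panel:", nrow(gen$panel$info), "genomes;",
    nrow(gen$sites), "implanted diagnostic sites\n")

samples <- list(
  core_51ka = list(n_fragments = 3000, mixture = c(gmelinii = 0.9, sibirica = 0.1),
                   background_frac = 0.85, d0 = 0.35),
  core_33ka = list(n_fragments = 6000, mixture = c(gmelinii = 0.3, sibirica = 0.7),
                   background_frac = 0.75, d0 = 0.30),
  core_21ka = list(n_fragments = 3500, mixture = c(gmelinii = 0.95, sibirica = 0.05),
                   background_frac = 0.85, d0 = 0.25),
  core_10ka = list(n_fragments = 6000, mixture = c(gmelinii = 0.4, sibirica = 0.6),
                   background_frac = 0.70, d0 = 0.15),
  blank_control = list(n_fragments = 600, mixture = c(gmelinii = 0.5, sibirica = 0.5),
                       background_frac = 0.98, d0 = 0.2)
)
arr <- generate_repeat_array(173, 200, 0.05, seed = seed + 1L)
writeLines(c(">EulaSat1_like_synthetic", arr$consensus),
           file.path(out, "repeat_motif.fa"))
writeLines(c(">repeat_array_synthetic", arr$array),
           file.path(out, "repeat_array.fa"))

for (sname in names(samples)) {
  cfg <- do.call(simulation_config,
                 c(samples[[sname]],
                   list(seed = seed + match(sname, names(samples)))))
  sim <- simulate_readset(cfg, gen$panel, sample_id = sname)
  write_fastq_pairs(sim$reads, file.path(out, sname))
  truth <- sim$truth
  truth_path <- file.path(out, paste0(sname, "_truth.tsv"))
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  # repeat-enrichment branch: fragments straight from the satellite array
  n_rep <- round(0.25 * cfg$n_fragments)
  rfr <- sample_fragments(arr$array, n_rep, seed = seed + 100L +
                            match(sname, names(samples)),
                          source_id = "repeat_array")
  rfr <- apply_damage(rfr, cfg$d0, cfg$lambda, cfg$e, cfg$seq_error,
                      seed = seed + 200L + match(sname, names(samples)))
  rfr$read_id <- sprintf("%s_rep%06d", sname, seq_len(nrow(rfr)))
  write_fastq_pairs(to_paired_reads(rfr), file.path(out, paste0(sname, "_repeat")))
  cat(sprintf("%-14s %5d chloroplast-branch pairs, %4d repeat pairs (d0 = %.2f)\n",
              sname, nrow(sim$reads), n_rep, cfg$d0))
}
cat("simulated inputs written to", out, "\n")
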