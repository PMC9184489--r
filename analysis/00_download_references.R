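#!/usr/bin/env Rscript
# Fetches the 20 published Siberian larch chloroplast genomes from NCBI
# (network required; ~2.5 MB once) and recomputes the diagnostic-site panel
# between the L. gmelinii/L. cajanderi group and L. sibirica on real data.
# Everything downstream of the download is the same code path the synthetic
# analyses use.
#
# Output: analysis/genbank/<accession>.fa, results/larix_diagnostic_sites.tsv

suppressMessages(library(sedadiag))

dir.create("analysis/genbank", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

acc <- larix_accessions()
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=fasta&retmode=text&id=")
for (a in acc$accession) {
  dest <- file.path("analysis/genbank", paste0(a, ".fa"))
  if (file.exists(dest) && file.size(dest) > 1000) next
  message("fetching ", a)
  ok <- tryCatch(utils::download.file(paste0(base, a), dest, quiet = TRUE),
                 error = function(e) 1L)
  if (!identical(ok, 0L) || file.size(dest) < 1000) {
    stop("download of ", a, " failed; this step needs network access")
  }
  Sys.sleep(0.4) # stay under the NCBI eutils request rate
}

fastas <- file.path("analysis/genbank", paste0(acc$accession, ".fa"))
panel <- build_panel(fastas, setNames(acc$group, acc$accession))
print(panel)
aln <- align_to_anchor(panel, "MK468637.1")
sites <- call_diagnostic_sites(aln, "gmelinii", "sibirica")
cat("fixed differences between the species groups:", nrow(sites), "\n")
cat("transitions:", sum(sites$is_transition),
    " transversions:", sum(!sites$is_transition), "\n")
write_diagnostic_sites(sites, "results/larix_diagnostic_sites.tsv")
cat("wrote results/larix_diagnostic_sites.tsv\n")
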