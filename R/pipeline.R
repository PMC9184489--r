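# End-to-end orchestration over synthetic samples: simulate -> classify ->
# map -> call sites -> aggregate, with damage and repeat profiling as
# parallel branches, per-stage count logging and a checksummed manifest.

#' Run the full analysis chain on simulated samples
#'
#' Generates a reference panel with known diagnostic sites, simulates one
#' read set per sample from its species mixture, then runs the package's
#' chain: paired-end merging, k-mer confidence classification to the target
#' genus, semi-global mapping to the anchor genome, deduplication, per-site
#' species assignment (with optional damage masking), damage profiling and
#' authentication, and satellite-repeat profiling. Everything is
#' deterministic under `seed`; a manifest with per-stage counts and file
#' checksums is written to the run directory.
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed; all stages derive labelled child streams.
#' @param panel_spec arguments to [generate_panel()] (less `seed`).
#' @param samples named list; each element is a list of overrides to
#'   [simulation_config()] (less `seed`) for that sample.
#' @param controls character vector of sample names treated as negative
#'   controls and screened against the others.
#' @param tax_k k-mer length of the classifier index.
#' @param tax_threshold classifier confidence threshold.
#' @param opts an [assign_options()].
#' @param damage_w damage-profile window in bp.
#' @param repeat_reads number of repeat-array fragments simulated per sample
#'   (0 disables the repeat branch).
#' @return invisibly, a list with `run_dir`, `manifest`, and per-sample
#'   result objects (`assignment`, `damage`, `repeat_profile`).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         panel_spec = list(n_per_group = c(A = 5L, B = 5L),
                                           genome_len = 20000L,
                                           n_sites = 100L,
                                           within_group_snps = 20L),
                         samples = list(sample1 = list()),
                         controls = character(0),
                         tax_k = 21L, tax_threshold = 0.8,
                         opts = assign_options(),
                         damage_w = 25L,
                         repeat_reads = 500L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(length(samples) >= 1, !is.null(names(samples)))
  manifest <- list(seed = seed, stages = list(), files = list())
  # --- reference panel and diagnostic sites ---------------------------------
  gen <- do.call(generate_panel,
                 c(panel_spec, list(seed = child_seed(seed, "panel"))))
  panel <- gen$panel
  groups <- attr(gen$sites, "groups")
  aln <- align_to_anchor(panel, gen$anchor_id)
  sites <- call_diagnostic_sites(aln, groups[["A"]], groups[["B"]])
  anchor <- panel$seq[[gen$anchor_id]]
  write_diagnostic_sites(sites, file.path(out_dir, "diagnostic_sites.tsv"))
  manifest$stages$panel <- list(
    n_genomes = nrow(panel$info),
    n_sites_called = nrow(sites),
    n_sites_truth = nrow(gen$sites),
    anchor_id = gen$anchor_id
  )
  # --- classifier index: root -> genus -> species leaves --------------------
  parent <- c(root = NA_character_,
              setNames("root", "target_genus"),
              setNames(rep("target_genus", length(unique(panel$info$group))),
                       unique(panel$info$group)))
  index <- build_kmer_index(panel$seq, parent,
                            leaf_of = setNames(panel$info$group,
                                               panel$info$id),
                            k = tax_k)
  results <- list()
  matrices <- list()
  for (sname in names(samples)) {
    cfg <- do.call(simulation_config,
                   c(samples[[sname]],
                     list(seed = child_seed(seed, paste0("sample:", sname)))))
    sim <- simulate_readset(cfg, panel, sample_id = sname)
    write_fastq_pairs(sim$reads, file.path(out_dir, sname))
    write_tsv(sim$truth, file.path(out_dir, paste0(sname, "_truth.tsv")))
    mg <- merge_pairs(sim$reads)
    # unmerged pairs are classified on the N-separated concatenation (the
    # separator contributes no k-mers) but only merged molecules are mapped
    unm <- mg$unmerged
    unm_seq <- if (nrow(unm) > 0) {
      paste0(unm$mate1, strrep("N", tax_k), revcomp(unm$mate2))
    } else character(0)
    cls_in <- rbind(
      mg$merged[, c("read_id", "seq")],
      data.frame(read_id = unm$read_id, seq = unm_seq,
                 stringsAsFactors = FALSE)
    )
    flt <- filter_readset(cls_in, index, tax_threshold, "target_genus")
    kept <- flt$kept[flt$kept$read_id %in% mg$merged$read_id, , drop = FALSE]
    write_tax_calls(flt$calls, file.path(out_dir, paste0(sname, "_taxcalls.tsv")))
    alns <- map_reads(kept, anchor, anchor_id = gen$anchor_id, opts = opts)
    dd <- deduplicate(alns)
    obs <- observe_sites(dd, sites, opts)
    obs_kept <- damage_filter(obs, opts)
    assign_mat <- aggregate_assignments(obs_kept, sample_id = sname)
    write_assignment_matrix(assign_mat, file.path(out_dir, sname))
    dmg <- NULL
    if (nrow(dd) > 0) {
      prof <- profile_damage(dd, anchor, w = damage_w)
      par <- fit_damage(prof)
      auth <- authenticate_damage(par, prof,
                                  seed = child_seed(seed, paste0("auth:", sname)))
      write_damage_profile(prof, file.path(out_dir, paste0(sname, "_damage.tsv")))
      write_damage_params(par, file.path(out_dir, paste0(sname, "_damage.json")))
      dmg <- list(profile = prof, params = par, auth = auth)
    }
    rp <- NULL
    if (repeat_reads > 0) {
      # one consensus array for the whole run: the arrays differ between
      # samples only through sampling and damage, emulating a conserved motif
      arr <- generate_repeat_array(cfg$repeat_spec$P, cfg$repeat_spec$copies,
                                   cfg$repeat_spec$divergence,
                                   seed = child_seed(seed, "repeat_consensus"))
      rfr <- sample_fragments(arr$array, repeat_reads,
                              cfg$frag_meanlog, cfg$frag_sdlog,
                              cfg$frag_min, cfg$frag_max,
                              seed = child_seed(seed, paste0("repeat:", sname)),
                              source_id = "repeat_array")
      rfr <- apply_damage(rfr, cfg$d0, cfg$lambda, cfg$e, cfg$seq_error,
                          seed = child_seed(seed, paste0("repeat_dmg:", sname)))
      ph <- map_to_motif(setNames(rfr$seq, sprintf("%s_rep%05d", sname,
                                                   seq_len(nrow(rfr)))),
                         arr$consensus, min_len = opts$min_len)
      rp <- build_repeat_profile(ph, arr$consensus, sample_id = sname)
      write_repeat_profile(rp, file.path(out_dir, paste0(sname, "_repeat.tsv")))
    }
    manifest$stages[[sname]] <- list(
      reads_in = nrow(sim$reads),
      merged = unname(mg$counts["merged"]),
      unmerged = unname(mg$counts["unmerged"]),
      discarded_empty = unname(mg$counts["discarded"]),
      genus_classified = nrow(flt$kept),
      classified_merged = nrow(kept),
      mapped = unname(attr(alns, "counts")["mapped"]),
      too_short = unname(attr(alns, "counts")["too_short"]),
      deduplicated = nrow(dd),
      duplicates_removed = attr(dd, "n_duplicates"),
      site_observations = nrow(obs),
      masked_observations = attr(obs_kept, "n_masked"),
      informative_reads = sum(assign_mat$totals[, c("reads_A", "reads_B",
                                                    "reads_unassigned")]),
      reads_A = assign_mat$totals$reads_A,
      reads_B = assign_mat$totals$reads_B,
      reads_unassigned = assign_mat$totals$reads_unassigned,
      damage_verdict = if (!is.null(dmg)) dmg$auth$verdict else "insufficient data",
      damage_d0 = if (!is.null(dmg)) dmg$params$d0 else NA,
      repeat_mapped = if (!is.null(rp)) sum(ph$mapped) else 0L
    )
    results[[sname]] <- list(assignment = assign_mat, damage = dmg,
                             repeat_profile = rp)
    matrices[[sname]] <- assign_mat
  }
  # --- negative-control screening -------------------------------------------
  if (length(controls) > 0) {
    stopifnot(all(controls %in% names(samples)))
    for (sname in setdiff(names(samples), controls)) {
      for (ctl in controls) {
        scr <- screen_controls(matrices[[sname]], matrices[[ctl]], "report")
        manifest$stages[[paste0("screen_", sname, "_vs_", ctl)]] <-
          as.list(scr$delta)
      }
    }
  }
  # --- repeat constancy across samples --------------------------------------
  rps <- Filter(Negate(is.null), lapply(results, `[[`, "repeat_profile"))
  if (length(rps) >= 2) {
    cmp <- compare_profiles(rps)
    write_tsv(cmp$pairs, file.path(out_dir, "repeat_constancy.tsv"))
    manifest$stages$repeat_constancy <- list(mean_tv = cmp$mean_tv,
                                             max_tv = cmp$max_tv)
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(setNames(unname(tools::md5sum(files)),
                                     basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(run_dir = out_dir, manifest = manifest, results = results,
                 sites = sites, truth_sites = gen$sites, panel = panel,
                 anchor_id = gen$anchor_id))
}

#' Summarise a pipeline run directory
#'
#' One row per sample: input, merged, genus-classified, mapped and
#' deduplicated read counts, informative reads, per-species totals, damage
#' verdict and repeat-mapped count, read back from the run manifest.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return data frame, one row per sample.
#' @export
pipeline_report <- function(run_dir) {
  mpath <- file.path(run_dir, "manifest.json")
  if (!file.exists(mpath))
    stop("dependency error: no manifest.json in ", run_dir,
         " (run_pipeline must run first)")
  manifest <- jsonlite::read_json(mpath)
  st <- manifest$stages
  snames <- setdiff(names(st), c("panel", "repeat_constancy"))
  snames <- snames[!grepl("^screen_", snames)]
  rows <- lapply(snames, function(s) {
    x <- st[[s]]
    data.frame(
      sample = s,
      reads_in = x$reads_in, merged = x$merged,
      genus_classified = x$genus_classified, mapped = x$mapped,
      deduplicated = x$deduplicated,
      informative_reads = x$informative_reads,
      reads_A = x$reads_A, reads_B = x$reads_B,
      reads_unassigned = x$reads_unassigned,
      damage_verdict = x$damage_verdict,
      repeat_mapped = x$repeat_mapped,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), reads_in = integer(0),
                      merged = integer(0), genus_classified = integer(0),
                      mapped = integer(0), deduplicated = integer(0),
                      informative_reads = integer(0), reads_A = integer(0),
                      reads_B = integer(0), reads_unassigned = integer(0),
                      damage_verdict = character(0),
                      repeat_mapped = integer(0), stringsAsFactors = FALSE)
  }
  out
}
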