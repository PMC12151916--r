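# End-to-end orchestration: simulate -> mine -> call -> filter -> scan ->
# enrich -> cluster, with per-stage logging, discard tallies and a
# machine-readable summary.

#' Build a pipeline configuration
#'
#' Collects the simulation settings and every stage parameter with its
#' default: telomeric classification at 7 tandem units, 100-bp anchor
#' expansion, recurrence in >= 2 runs, mapq >= 30; DMRs with >= 7 probes,
#' width > 50 bp, p < 0.05; 2-kb gene flanks for motif association;
#' subtelomere span; cluster count `k`.
#'
#' @param sim a [simulation_config()]; its seed drives everything.
#' @param min_units,pad_bp,min_runs,min_mapq Hi-C mining parameters.
#' @param min_probes,min_width_bp,p_cutoff,delta_cutoff,max_probe_gap_bp
#'   DMR-calling parameters.
#' @param flank_bp gene flank for motif association (bp).
#' @param max_mismatch motif scan Hamming tolerance.
#' @param span_bp subtelomere span used on the simulated genome (bp);
#'   chosen as the same fraction of the simulated chromosome as a 10-Mb
#'   window is of a human arm.
#' @param k number of chromosome-end clusters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            min_units = 7L, pad_bp = 100L,
                            min_runs = 2L, min_mapq = 30L,
                            min_probes = 7L, min_width_bp = 50L,
                            p_cutoff = 0.05, delta_cutoff = 0.05,
                            max_probe_gap_bp = 1000L,
                            flank_bp = 2000L, max_mismatch = 0L,
                            span_bp = 2e5, k = 2L) {
  structure(list(sim = sim, min_units = min_units, pad_bp = pad_bp,
                 min_runs = min_runs, min_mapq = min_mapq,
                 min_probes = min_probes, min_width_bp = min_width_bp,
                 p_cutoff = p_cutoff, delta_cutoff = delta_cutoff,
                 max_probe_gap_bp = max_probe_gap_bp,
                 flank_bp = flank_bp, max_mismatch = max_mismatch,
                 span_bp = span_bp, k = as.integer(k)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes every stage in order (simulate, Hi-C mining, DMR calling and
#' directional filtering, DEG thresholding, subtelomeric enrichment,
#' motif scanning and association, chromosome-end clustering), writes all
#' intermediate artifacts under `out_dir`, and returns a machine-readable
#' summary including recall/precision of the planted structure.  A stage
#' error writes a `FAILED_<stage>` marker file (partial outputs are
#' retained) and rethrows with the stage named.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary list (also written to `summary.json`
#'   and, humanly readable, `pipeline.log`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0("FAILED_", name)))
      writeLines(log_lines, file.path(out_dir, "pipeline.log"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$sim$seed)

  # -- simulate -------------------------------------------------------
  sim_dir <- file.path(out_dir, "sim")
  sim <- stage("simulate", {
    genome <- generate_genome(config$sim, out_dir = sim_dir)
    hic <- generate_hic_runs(genome, config$sim,
                             out_dir = file.path(sim_dir, "hic"))
    meth <- generate_methylation_series(genome, config$sim,
                                        out_dir = sim_dir)
    deg <- generate_deg_table(genome, config$sim, out_dir = sim_dir)
    list(genome = genome, hic = hic, meth = meth, deg = deg)
  })
  say("simulate: %d chromosomes, %d Hi-C runs, %d probes, %d genes",
      length(sim$genome$chrom_names), length(sim$hic$pairs_files),
      nrow(sim$meth$manifest), nrow(sim$genome$genes))

  # -- Hi-C mining ----------------------------------------------------
  mined <- stage("hic_mine", {
    contacts <- list(); tallies <- list()
    for (i in seq_along(sim$hic$pairs_files)) {
      res <- extract_telomeric_contacts(
        sim$hic$pairs_files[i], sim$hic$seq_file,
        telomere_arrays = sim$genome$telomere_arrays,
        its = sim$genome$its,
        run_id = sprintf("run%02d", i),
        min_units = config$min_units, min_mapq = config$min_mapq)
      contacts[[i]] <- res$contacts
      tallies[[i]] <- res$log
    }
    all_contacts <- do.call(rbind, contacts)
    inter <- aggregate_recurrent(all_contacts, sim$genome$chrom_lengths,
                                 pad_bp = config$pad_bp,
                                 min_runs = config$min_runs)
    inter <- annotate_nearest_end(inter, sim$genome$chrom_lengths)
    write_bed(inter, file.path(out_dir, "interactions.bed"))
    audit <- as.data.frame(do.call(rbind, tallies))
    audit$run <- sprintf("run%02d", seq_along(tallies))
    .write_tsv(audit, file.path(out_dir, "hic_audit.tsv"))
    list(contacts = all_contacts, interactions = inter, audit = audit)
  })
  hic_score <- score_recovery(mined$interactions, sim$hic$truth)
  summary$hic <- c(hic_score,
                   list(telo_telo_pairs = sum(mined$audit$telo_telo)))
  say("hic_mine: %d interactions (recall %.2f, precision %.2f)",
      nrow(mined$interactions), hic_score$recall, hic_score$precision)

  # -- DMR calling + directional filter -------------------------------
  dmr <- stage("dmr", {
    conds <- sim$meth$conditions
    comparisons <- list()
    for (j in seq_len(min(3L, length(conds) - 1L))) {
      lab <- paste0(sub("kb$", "", conds[j]), "v",
                    sub("kb$", "", conds[j + 1L]))
      comparisons[[lab]] <- call_dmrs(
        sim$meth$beta, sim$meth$manifest, conds[j], conds[j + 1L],
        min_probes = config$min_probes,
        min_width_bp = config$min_width_bp,
        p_cutoff = config$p_cutoff, delta_cutoff = config$delta_cutoff,
        max_probe_gap_bp = config$max_probe_gap_bp)
      .write_tsv(comparisons[[lab]],
                 file.path(out_dir, paste0("dmrs_", lab, ".tsv")))
    }
    directional <- filter_directional(comparisons)
    .write_tsv(directional, file.path(out_dir, "dmrs_directional.tsv"))
    list(comparisons = comparisons, directional = directional)
  })
  truth_mono <- sim$meth$truth[sim$meth$truth$kind == "monotone", ]
  truth_flip <- sim$meth$truth[sim$meth$truth$kind == "decoy_signflip", ]
  dmr_score <- score_recovery(dmr$directional, truth_mono)
  flip_kept <- if (nrow(dmr$directional) && nrow(truth_flip)) {
    score_recovery(dmr$directional, truth_flip)$n_truth_recovered
  } else 0L
  summary$dmr <- c(dmr_score, list(n_signflip_decoys_kept = flip_kept))
  say("dmr: %d directional DMRs (recall %.2f, precision %.2f, %d decoys kept)",
      nrow(dmr$directional), dmr_score$recall, dmr_score$precision,
      flip_kept)

  # -- DEG filter + subtelomeric enrichment ---------------------------
  enrich <- stage("enrich", {
    degs <- deg_filter(sim$deg$table)
    windows <- make_subtelomere_windows(sim$genome$chrom_lengths,
                                        span_bp = config$span_bp)
    genes <- sim$genome$genes
    gene_in <- count_in_windows(genes, windows)
    deg_in <- count_in_windows(genes[genes$name %in% degs, ], windows)
    deg_enr <- enrichment_test(deg_in$total, length(degs),
                               gene_in$total, nrow(genes),
                               test = "hypergeometric")
    dmr_enr <- NULL
    dmr_frac <- NA_real_
    if (nrow(dmr$directional)) {
      dmr_in <- count_in_windows(dmr$directional, windows)
      dmr_frac <- dmr_in$total / nrow(dmr$directional)
      # universe for region enrichment: window coverage of the genome
      cov_in <- sum(windows$end - windows$start)
      cov_tot <- sum(sim$genome$chrom_lengths)
      dmr_enr <- enrichment_test(dmr_in$total, nrow(dmr$directional),
                                 cov_in, cov_tot, test = "chisq")
    }
    list(degs = degs, windows = windows, deg_enrichment = deg_enr,
         dmr_enrichment = dmr_enr, dmr_subtel_fraction = dmr_frac)
  })
  summary$enrichment <- list(
    n_deg = length(enrich$degs),
    deg_expected_proportion = enrich$deg_enrichment$expected_proportion,
    deg_observed_proportion = enrich$deg_enrichment$observed_proportion,
    deg_p = enrich$deg_enrichment$p_value,
    dmr_subtel_fraction = enrich$dmr_subtel_fraction,
    dmr_p = if (is.null(enrich$dmr_enrichment)) NA_real_ else
      enrich$dmr_enrichment$p_value)
  say("enrich: %d DEGs (p = %.3g); %.1f%% of directional DMRs subtelomeric",
      length(enrich$degs), enrich$deg_enrichment$p_value,
      100 * enrich$dmr_subtel_fraction)

  # -- motif scan + association ---------------------------------------
  motif <- stage("motif", {
    hits <- scan_motif(sim$genome,
                       intervals = mined$interactions,
                       max_mismatch = config$max_mismatch)
    write_bed(hits, file.path(out_dir, "we_hits_interactions.bed"))
    genome_hits <- scan_motif(sim$genome,
                              max_mismatch = config$max_mismatch)
    assoc <- associate_hits(genome_hits, sim$genome$genes,
                            dmrs = dmr$directional,
                            flank_bp = config$flank_bp)
    .write_tsv(assoc$genes, file.path(out_dir, "we_gene_assoc.tsv"))
    prox <- proximity_enrichment(enrich$degs, assoc$genes)
    list(interaction_hits = hits, genome_hits = genome_hits,
         assoc = assoc, prox = prox)
  })
  summary$motif <- list(
    n_hits_at_interactions = nrow(motif$interaction_hits),
    n_interactions_with_hit =
      length(unique(motif$interaction_hits$source_region)),
    n_genome_hits = nrow(motif$genome_hits),
    deg_proximity_p = motif$prox$p_value)
  say("motif: %d hits at %d interaction windows; %d genome-wide",
      nrow(motif$interaction_hits),
      summary$motif$n_interactions_with_hit, nrow(motif$genome_hits))

  # -- chromosome-end clustering --------------------------------------
  clust <- stage("cluster", {
    set.seed(config$sim$seed + 404L)
    timing <- setNames(runif(nrow(enrich$windows), -2, 2),
                       enrich$windows$end_id)
    raw <- tally_end_features(enrich$windows, motif$genome_hits,
                              sim$genome$genes, enrich$degs,
                              its = sim$genome$its, timing = timing)
    tab <- suppressWarnings(build_end_table(raw))
    cl <- cluster_ends(tab, k = config$k)
    .write_tsv(data.frame(end_id = names(cl$labels),
                          cluster = cl$labels),
               file.path(out_dir, "end_clusters.tsv"))
    writeLines(cl$newick, file.path(out_dir, "end_dendrogram.nwk"))
    list(table = tab, clusters = cl)
  })
  summary$cluster <- list(
    n_ends = nrow(clust$table$table),
    k = config$k,
    sizes = as.integer(table(clust$clusters$labels)))
  say("cluster: %d ends into %d clusters (sizes %s)",
      nrow(clust$table$table), config$k,
      paste(summary$cluster$sizes, collapse = "/"))

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(summary = summary, sim = sim, mined = mined, dmr = dmr,
                 enrich = enrich, motif = motif, cluster = clust))
}
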