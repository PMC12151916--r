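# Simulated EPIC-style methylation series across telomere-length
# conditions, plus simulated differential-expression tables.  Planted
# monotone DMRs shift mean beta in a constant direction along telomere
# shortening; decoys violate exactly one downstream filter each.

#' Generate a synthetic methylation series
#'
#' Emits a probe manifest and a beta matrix over the telomere-length
#' conditions (default 12/10/8/6/4 kb, four replicates each).  Background
#' probes have condition-independent means; planted regions add a
#' cumulative per-step delta along the shortening series (sign-flipping
#' decoys alternate the sign).  Betas are drawn from a Beta distribution
#' parameterized by (mean, concentration); means are clamped to
#' `[0.02, 0.98]` so the shape parameters stay valid.
#'
#' @param genome a `genome_model`.
#' @param config a [simulation_config()]; see its `methylation` entry.
#' @param out_dir optional directory for `probe_manifest.tsv`,
#'   `beta_matrix.tsv` and `dmr_truth.tsv`.
#' @return List with `manifest` (probe_id, chrom, pos), `beta` (numeric
#'   matrix, probes x condition-replicates, dimnames set), `truth` (one row
#'   per planted region: `dmr_id`, `kind`, `direction`, `chrom`, `start`,
#'   `end`, `n_probes`, `width_bp`, `subtelomeric`), and `conditions`.
#' @export
generate_methylation_series <- function(genome, config, out_dir = NULL) {
  set.seed(config$seed + 202L)
  mc <- config$methylation
  conditions <- mc$conditions
  n_reps <- mc$n_replicates
  if (n_reps < 2L) stop("need >= 2 replicates per condition", call. = FALSE)
  conc <- mc$beta_concentration
  telo_len <- 6L * genome$telomere_array_units
  span <- mc$subtel_span_bp
  planted <- mc$planted_dmrs

  manifest <- list()
  region_rows <- list()
  # plant regions chromosome by chromosome, subtelomeric or central
  placed_by_chrom <- setNames(
    rep(list(data.frame(start = integer(0), end = integer(0))),
        length(genome$chrom_names)), genome$chrom_names)
  for (i in seq_len(nrow(planted))) {
    chrom <- genome$chrom_names[(i - 1L) %% length(genome$chrom_names) + 1L]
    L <- genome$chrom_lengths[[chrom]]
    w <- planted$width_bp[i]
    if (planted$subtelomeric[i]) {
      side <- sample(c("p", "q"), 1L)
      rng <- if (side == "p") c(telo_len + 100L, span) else
        c(L - span, L - telo_len - 100L)
    } else {
      rng <- c(span + 100L, L - span - 100L)
    }
    pos <- .place_intervals(w + 1L, rng[1], rng[2],
                            occupied = placed_by_chrom[[chrom]])
    placed_by_chrom[[chrom]] <- rbind(placed_by_chrom[[chrom]],
                                      data.frame(start = pos$start - 2000L,
                                                 end = pos$end + 2000L))
    probe_pos <- pos$start + round(seq(0, w, length.out = planted$n_probes[i]))
    probe_pos <- unique(as.integer(probe_pos))
    region_rows[[i]] <- data.frame(
      dmr_id = sprintf("planted%02d", i), kind = planted$kind[i],
      direction = planted$direction[i], chrom = chrom,
      start = min(probe_pos), end = max(probe_pos) + 1L,
      n_probes = length(probe_pos),
      width_bp = max(probe_pos) - min(probe_pos),
      subtelomeric = planted$subtelomeric[i])
    manifest[[length(manifest) + 1L]] <- data.frame(
      chrom = chrom, pos = probe_pos, region = i,
      delta_per_step = planted$delta_per_step[i] *
        ifelse(planted$direction[i] == "hyper", 1, -1),
      kind = planted$kind[i])
  }
  truth <- do.call(rbind, region_rows)

  # background probes, kept >= 2 kb away from planted regions
  for (chrom in genome$chrom_names) {
    L <- genome$chrom_lengths[[chrom]]
    pos <- sort(sample((telo_len + 1L):(L - telo_len - 1L),
                       mc$n_background_probes_per_chrom))
    occ <- placed_by_chrom[[chrom]]
    if (nrow(occ)) {
      keep <- !vapply(pos, function(p)
        any(p >= occ$start & p < occ$end), TRUE)
      pos <- pos[keep]
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, region = 0L, delta_per_step = 0,
      kind = "background")
  }
  man <- do.call(rbind, manifest)
  man <- man[order(match(man$chrom, genome$chrom_names), man$pos), ]
  man$probe_id <- sprintf("cg%06d", seq_len(nrow(man)))
  rownames(man) <- NULL

  n_steps <- length(conditions) - 1L
  # per-step signed deltas; sign-flipping decoys alternate, and drift
  # plateaus after the third step (the shortest, crisis-stage condition
  # is excluded from the directional analysis)
  step_sign <- function(kind) {
    s <- if (kind == "decoy_signflip") rep_len(c(1, -1), n_steps) else
      rep(1, n_steps)
    if (n_steps > 3L) s[4:n_steps] <- 0
    s
  }
  baseline <- runif(nrow(man), mc$baseline_beta_range[1],
                    mc$baseline_beta_range[2])
  # planted probes: draw the baseline so the whole trajectory stays inside
  # (0.05, 0.95) and per-step deltas are never flattened by clamping
  for (i in which(man$region > 0L)) {
    cum <- c(0, cumsum(man$delta_per_step[i] * step_sign(man$kind[i])))
    lo <- 0.02 - min(cum)
    hi <- 0.98 - max(cum)
    if (lo >= hi) {
      stop("planted delta_per_step implies beta values outside [0, 1]",
           call. = FALSE)
    }
    baseline[i] <- runif(1, lo, hi)
  }
  means <- matrix(baseline, nrow = nrow(man), ncol = length(conditions))
  for (j in 2:length(conditions)) {
    step <- vapply(seq_len(nrow(man)), function(i) {
      if (man$region[i] == 0L) 0 else
        man$delta_per_step[i] * step_sign(man$kind[i])[j - 1L]
    }, 0)
    means[, j] <- means[, j - 1L] + step
  }
  means <- pmin(pmax(means, 0.02), 0.98)

  beta <- matrix(NA_real_, nrow = nrow(man),
                 ncol = length(conditions) * n_reps)
  colnames(beta) <- as.vector(t(outer(conditions, seq_len(n_reps),
                                      function(c, r) paste0(c, "_", r))))
  rownames(beta) <- man$probe_id
  for (j in seq_along(conditions)) {
    for (r in seq_len(n_reps)) {
      beta[, (j - 1L) * n_reps + r] <-
        rbeta(nrow(man), means[, j] * conc, (1 - means[, j]) * conc)
    }
  }

  manifest_out <- man[, c("probe_id", "chrom", "pos")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(manifest_out, file.path(out_dir, "probe_manifest.tsv"))
    bdf <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
    .write_tsv(bdf, file.path(out_dir, "beta_matrix.tsv"))
    .write_tsv(truth, file.path(out_dir, "dmr_truth.tsv"))
  }
  list(manifest = manifest_out, beta = beta, truth = truth,
       conditions = conditions)
}

#' Generate a synthetic differential-expression table
#'
#' Planted DEGs satisfy both reporting thresholds (FDR < 0.05 and
#' |log2FC| > 2); every other gene fails at least one.  By default DEGs
#' are sampled uniformly over genes, so their subtelomeric proportion
#' matches the background (the non-enrichment regime); `deg$subtel_prop`
#' forces a given subtelomeric fraction instead.
#'
#' @param genome a `genome_model`.
#' @param config a [simulation_config()]; see its `deg` entry.
#' @param out_dir optional directory for `deg_table.tsv`, `deg_truth.tsv`.
#' @return List with `table` (gene, log2FC, FDR) and `truth` (planted DEG
#'   identifiers).
#' @export
generate_deg_table <- function(genome, config, out_dir = NULL) {
  set.seed(config$seed + 303L)
  dc <- config$deg
  genes <- genome$genes
  if (dc$n_deg > nrow(genes)) {
    stop("requested DEG count (", dc$n_deg, ") exceeds gene count (",
         nrow(genes), ")", call. = FALSE)
  }
  if (is.na(dc$subtel_prop)) {
    deg_idx <- sample.int(nrow(genes), dc$n_deg)
  } else {
    wins <- make_subtelomere_windows(genome$chrom_lengths,
                                     span_bp = dc$span_bp)
    gr_g <- .as_granges(genes)
    gr_w <- .as_granges(wins)
    in_sub <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_g, gr_w, ignore.strand = TRUE)))
    n_sub <- min(round(dc$n_deg * dc$subtel_prop), length(in_sub))
    deg_idx <- c(sample(in_sub, n_sub),
                 sample(setdiff(seq_len(nrow(genes)), in_sub),
                        dc$n_deg - n_sub))
  }
  is_deg <- seq_len(nrow(genes)) %in% deg_idx
  lfc <- ifelse(is_deg,
                sample(c(-1, 1), nrow(genes), replace = TRUE) *
                  runif(nrow(genes), 2.5, 6),
                runif(nrow(genes), 0, 1.8) *
                  sample(c(-1, 1), nrow(genes), replace = TRUE))
  fdr <- ifelse(is_deg, runif(nrow(genes), 1e-6, 0.02),
                runif(nrow(genes), 0, 1))
  # non-DEGs with a sub-threshold |log2FC| may keep any FDR; the rest must
  # fail the FDR cut
  fail_fdr <- !is_deg & abs(lfc) > 2
  fdr[fail_fdr] <- runif(sum(fail_fdr), 0.06, 1)
  tab <- data.frame(gene = genes$name, log2FC = lfc, FDR = fdr)
  truth <- genes$name[deg_idx]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(tab, file.path(out_dir, "deg_table.tsv"))
    .write_tsv(data.frame(gene = truth), file.path(out_dir, "deg_truth.tsv"))
  }
  list(table = tab, truth = truth)
}
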