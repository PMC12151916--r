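# Seeded synthetic genomes: chromosomes with terminal (TTAGGG)n arrays,
# interstitial telomeric sequences above/below the 7-unit classification
# threshold, planted 35-bp WE consensus copies, and gene intervals.  The
# generator is the test substrate for every downstream stage; with a fixed
# seed all outputs are byte-identical across runs.

#' Build a simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults describe
#' the study conditions the pipeline assumes: 16 Hi-C runs, five
#' telomere-length conditions (12/10/8/6/4 kb) with four replicates each,
#' terminal arrays of 500 TTAGGG units, 75-bp reads, and a planted DMR set
#' containing monotone subtelomere-enriched regions plus decoys (too few
#' probes, too narrow, sign-flipping) that downstream filters must reject.
#'
#' @param seed integer seed; fully determines all generated outputs.
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of every chromosome (bp).
#' @param telomere_units TTAGGG units in each terminal array.
#' @param n_its_below_threshold interstitial telomeric arrays with 2-6 units
#'   per chromosome (classified non-telomeric downstream).
#' @param n_its_at_or_above_threshold interstitial arrays with 7-12 units
#'   (telomere look-alikes; anchors inside them are discarded).
#' @param its_mismatch_per_unit mismatches mutated into each unit of the
#'   below-threshold ITS arrays, to exercise tolerant counting.
#' @param n_we_sites planted copies of [WE_CONSENSUS] per chromosome,
#'   random strand.
#' @param n_genes gene intervals per chromosome (width uniform in
#'   `gene_width_bp`).
#' @param gene_width_bp length-2 range of gene widths.
#' @param n_hic_runs number of simulated Hi-C runs.
#' @param contacts_per_run baseline number of noise contacts per run.
#' @param noise_contact_rate multiplier on `contacts_per_run`; 0 gives
#'   noiseless runs containing only planted contacts.
#' @param n_planted_contact_sites WE sites used as recurrent telomere
#'   contact anchors.
#' @param planted_recurrence number of runs (out of `n_hic_runs`) in which
#'   each planted contact appears.
#' @param read_length_bp mate length; must allow >= 7 tandem units (42 bp).
#' @param methylation list of methylation-series knobs: `conditions`,
#'   `n_replicates`, `n_background_probes_per_chrom`, `beta_concentration`,
#'   `baseline_beta_range`, `delta_per_step`, `subtel_span_bp`, and
#'   `planted_dmrs` (a data frame as returned by [default_planted_dmrs()]).
#' @param deg list of differential-expression knobs: `n_deg`,
#'   `subtel_prop` (`NA` = sample DEGs uniformly, i.e. background
#'   proportion), `span_bp` (subtelomere span used for that sampling).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 4L,
                              chrom_length_bp = 2e6,
                              telomere_units = 500L,
                              n_its_below_threshold = 6L,
                              n_its_at_or_above_threshold = 4L,
                              its_mismatch_per_unit = 0L,
                              n_we_sites = 10L,
                              n_genes = 80L,
                              gene_width_bp = c(2000L, 10000L),
                              n_hic_runs = 16L,
                              contacts_per_run = 500L,
                              noise_contact_rate = 1,
                              n_planted_contact_sites = 5L,
                              planted_recurrence = 16L,
                              read_length_bp = 75L,
                              methylation = list(),
                              deg = list()) {
  meth_defaults <- list(
    conditions = c("12kb", "10kb", "8kb", "6kb", "4kb"),
    n_replicates = 4L,
    n_background_probes_per_chrom = 150L,
    beta_concentration = 50,
    baseline_beta_range = c(0.2, 0.8),
    delta_per_step = 0.15,
    subtel_span_bp = 2e5,
    planted_dmrs = NULL
  )
  deg_defaults <- list(n_deg = 10L, subtel_prop = NA_real_, span_bp = 2e5)
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    telomere_units = as.integer(telomere_units),
    n_its_below_threshold = as.integer(n_its_below_threshold),
    n_its_at_or_above_threshold = as.integer(n_its_at_or_above_threshold),
    its_mismatch_per_unit = as.integer(its_mismatch_per_unit),
    n_we_sites = as.integer(n_we_sites),
    n_genes = as.integer(n_genes),
    gene_width_bp = as.integer(gene_width_bp),
    n_hic_runs = as.integer(n_hic_runs),
    contacts_per_run = as.integer(contacts_per_run),
    noise_contact_rate = noise_contact_rate,
    n_planted_contact_sites = as.integer(n_planted_contact_sites),
    planted_recurrence = as.integer(planted_recurrence),
    read_length_bp = as.integer(read_length_bp),
    methylation = modifyList(meth_defaults, methylation),
    deg = modifyList(deg_defaults, deg)
  )
  if (is.null(cfg$methylation$planted_dmrs)) {
    cfg$methylation$planted_dmrs <- default_planted_dmrs()
  }
  .validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

#' @noRd
.validate_config <- function(cfg) {
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length_bp > 0L,
            cfg$telomere_units >= 7L, cfg$n_hic_runs >= 1L)
  if (cfg$planted_recurrence > cfg$n_hic_runs) {
    stop("planted_recurrence (", cfg$planted_recurrence,
         ") exceeds n_hic_runs (", cfg$n_hic_runs, ")", call. = FALSE)
  }
  if (cfg$read_length_bp < 7L * 6L) {
    stop("read_length_bp must be >= 42 so a telomeric read can carry ",
         "7 tandem units", call. = FALSE)
  }
  if (cfg$n_planted_contact_sites > cfg$n_we_sites) {
    stop("n_planted_contact_sites exceeds n_we_sites", call. = FALSE)
  }
  pd <- cfg$methylation$planted_dmrs
  if (!is.null(pd) && nrow(pd) && any(pd$n_probes < 1L)) {
    stop("planted DMR probe counts must be >= 1", call. = FALSE)
  }
  br <- cfg$methylation$baseline_beta_range
  if (br[1] <= 0 || br[2] >= 1 || br[1] >= br[2]) {
    stop("baseline_beta_range must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Default planted DMR set
#'
#' Eight monotone DMRs (10 probes over 450 bp, per-step delta 0.15; five
#' hypermethylating and three hypomethylating upon shortening, three of the
#' eight subtelomeric) plus decoys: two sign-flipping regions, one region
#' with only six probes, and one 8-probe region squeezed into 40 bp.  The
#' decoys must be rejected by the probe-count, width and directional
#' filters respectively.
#'
#' @param delta_per_step absolute per-comparison beta shift of planted
#'   regions.
#' @return Data frame with one row per planted region: `kind`, `direction`,
#'   `n_probes`, `width_bp`, `delta_per_step`, `subtelomeric`.
#' @export
default_planted_dmrs <- function(delta_per_step = 0.15) {
  rbind(
    data.frame(kind = "monotone",
               direction = rep(c("hyper", "hypo"), c(5L, 3L)),
               n_probes = 10L, width_bp = 450L,
               delta_per_step = delta_per_step,
               subtelomeric = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                TRUE, FALSE, FALSE)),
    data.frame(kind = "decoy_signflip", direction = "hyper",
               n_probes = 10L, width_bp = 450L,
               delta_per_step = delta_per_step,
               subtelomeric = c(FALSE, FALSE)),
    data.frame(kind = "decoy_few_probes", direction = "hyper",
               n_probes = 6L, width_bp = 300L, delta_per_step = 0.3,
               subtelomeric = FALSE),
    data.frame(kind = "decoy_narrow", direction = "hyper",
               n_probes = 8L, width_bp = 40L, delta_per_step = 0.3,
               subtelomeric = FALSE)
  )
}

#' @noRd
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate `mm` random positions within each unit-length block of `seq`.
#' @noRd
.mutate_units <- function(seq, unit_len, mm) {
  if (mm <= 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_units <- length(chars) %/% unit_len
  for (u in seq_len(n_units)) {
    pos <- (u - 1L) * unit_len + sample.int(unit_len, mm)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome
#'
#' Builds `n_chroms` chromosomes whose first `6 * telomere_units` bp are a
#' pure (TTAGGG)n array and whose last are the reverse-complement
#' (CCCTAA)n array, then plants non-overlapping interior features: ITS
#' arrays below and at/above the 7-unit threshold, single-copy WE consensus
#' sites (random strand), and gene intervals.  Feature packing that cannot
#' be realized raises an explicit placement error rather than silently
#' truncating.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, writes `genome.fa` plus
#'   BED6 files `telomere_arrays.bed`, `its.bed` (score = unit count),
#'   `we_sites.bed`, `genes.bed`.
#' @return A `genome_model` list: `chrom_names`, `chrom_lengths` (named),
#'   `telomere_array_units`, interval data frames `telomere_arrays`, `its`
#'   (with `units`), `we_sites` (with `strand`), `genes` (with `name`), and
#'   `sequences` (a [Biostrings::DNAStringSet]).  All intervals 0-based
#'   half-open.
#' @export
generate_genome <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  unit <- TELOMERE_UNIT
  runit <- .revcomp(unit)
  L <- config$chrom_length_bp
  telo_len <- 6L * config$telomere_units
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))

  if (2L * telo_len >= L) {
    stop("placement error: chromosomes too short for two terminal arrays",
         call. = FALSE)
  }

  its_units_lo <- its_units_hi <- integer(0)
  seqs <- character(config$n_chroms)
  telo <- its <- we <- genes <- list()

  for (ci in seq_len(config$n_chroms)) {
    chrom <- chrom_names[ci]
    base <- .random_dna(L)
    # terminal arrays: G-rich strand repeats at the start, C-rich at the end
    left  <- strrep(unit, config$telomere_units)
    right <- strrep(runit, config$telomere_units)

    u_lo <- sample(2:6, config$n_its_below_threshold, replace = TRUE)
    u_hi <- sample(7:12, config$n_its_at_or_above_threshold, replace = TRUE)
    its_w <- 6L * c(u_lo, u_hi)
    we_w  <- rep(nchar(WE_CONSENSUS), config$n_we_sites)
    gene_w <- sample(config$gene_width_bp[1]:config$gene_width_bp[2],
                     config$n_genes, replace = TRUE)

    interior_lo <- telo_len + 1000L
    interior_hi <- L - telo_len - 1000L
    placed <- .place_intervals(c(its_w, we_w, gene_w),
                               interior_lo, interior_hi)
    n_its <- length(its_w)
    its_df  <- placed[seq_len(n_its), , drop = FALSE]
    we_df   <- placed[n_its + seq_along(we_w), , drop = FALSE]
    gene_df <- placed[n_its + length(we_w) + seq_along(gene_w), ,
                      drop = FALSE]

    its_strand <- sample(c("+", "-"), n_its, replace = TRUE)
    we_strand  <- sample(c("+", "-"), config$n_we_sites, replace = TRUE)
    its_units  <- c(u_lo, u_hi)

    # splice features into the chromosome sequence
    chars <- base
    substr(chars, 1L, telo_len) <- left
    substr(chars, L - telo_len + 1L, L) <- right
    for (k in seq_len(n_its)) {
      u <- if (its_strand[k] == "+") unit else runit
      arr <- strrep(u, its_units[k])
      if (k <= length(u_lo)) {
        arr <- .mutate_units(arr, 6L, config$its_mismatch_per_unit)
      }
      substr(chars, its_df$start[k] + 1L, its_df$end[k]) <- arr
    }
    for (k in seq_len(config$n_we_sites)) {
      s <- if (we_strand[k] == "+") WE_CONSENSUS else .revcomp(WE_CONSENSUS)
      substr(chars, we_df$start[k] + 1L, we_df$end[k]) <- s
    }
    seqs[ci] <- chars

    telo[[ci]] <- data.frame(
      chrom = chrom, start = c(0L, L - telo_len), end = c(telo_len, L),
      name = paste0(chrom, c("_p_telomere", "_q_telomere")),
      score = config$telomere_units, strand = c("+", "-"))
    its[[ci]] <- data.frame(
      chrom = chrom, start = its_df$start, end = its_df$end,
      name = sprintf("%s_ITS%d", chrom, seq_len(n_its)),
      units = its_units, strand = its_strand)
    we[[ci]] <- data.frame(
      chrom = chrom, start = we_df$start, end = we_df$end,
      name = sprintf("%s_WE%d", chrom, seq_len(config$n_we_sites)),
      strand = we_strand)
    genes[[ci]] <- data.frame(
      chrom = chrom, start = gene_df$start, end = gene_df$end,
      name = sprintf("%s_gene%d", chrom, seq_len(config$n_genes)),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE))
  }

  sequences <- Biostrings::DNAStringSet(setNames(seqs, chrom_names))
  model <- list(
    chrom_names = chrom_names,
    chrom_lengths = setNames(rep(L, config$n_chroms), chrom_names),
    telomere_array_units = config$telomere_units,
    telomere_arrays = do.call(rbind, telo),
    its = do.call(rbind, its),
    we_sites = do.call(rbind, we),
    genes = do.call(rbind, genes),
    sequences = sequences,
    seed = config$seed
  )
  class(model) <- "genome_model"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sequences, file.path(out_dir, "genome.fa"))
    write_bed(model$telomere_arrays,
              file.path(out_dir, "telomere_arrays.bed"))
    its_bed <- model$its
    its_bed$score <- its_bed$units
    write_bed(its_bed, file.path(out_dir, "its.bed"))
    write_bed(model$we_sites, file.path(out_dir, "we_sites.bed"))
    write_bed(model$genes, file.path(out_dir, "genes.bed"))
    model$out_dir <- out_dir
  }
  model
}

#' Extract the sequence of genome intervals, oriented by strand
#'
#' @param genome a `genome_model`.
#' @param intervals 0-based half-open data frame with `chrom`, `start`,
#'   `end` and optionally `strand` (minus-strand intervals are
#'   reverse-complemented).
#' @return Character vector of sequences.
#' @export
interval_sequence <- function(genome, intervals) {
  out <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- as.character(Biostrings::subseq(
      genome$sequences[[intervals$chrom[i]]],
      start = intervals$start[i] + 1L, end = intervals$end[i]))
    if ("strand" %in% names(intervals) && intervals$strand[i] == "-") {
      s <- .revcomp(s)
    }
    out[i] <- s
  }
  out
}
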