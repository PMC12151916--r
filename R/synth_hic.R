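# Simulated Hi-C runs: pairs-format contact records plus a sequence
# side-file.  Planted contacts pair a read drawn from a terminal telomere
# array with a read overlapping a planted WE site; noise contacts pair two
# random non-telomeric loci.  Each planted contact recurs in a fixed number
# of runs, recorded in a truth table for downstream scoring.

#' @noRd
.subseq_chr <- function(genome, chrom, start0, width) {
  as.character(Biostrings::subseq(genome$sequences[[chrom]],
                                  start = start0 + 1L,
                                  width = width))
}

#' Generate simulated Hi-C runs
#'
#' Writes one 4DN-style pairs file per run (`readID chr1 pos1 chr2 pos2
#' strand1 strand2`, positions 0-based) and a shared TSV sequence side-file
#' (`read_id seq1 seq2 mapq1 mapq2`), because telomeric mates are
#' unalignable and classification operates on raw sequence.  Each planted
#' contact site appears in exactly `planted_recurrence` runs (which runs is
#' seeded-random per site); mate order is randomized so the telomeric mate
#' is not always mate 1.  Noise contacts draw both mates from interior loci
#' outside terminal arrays.
#'
#' @param genome a `genome_model` from [generate_genome()].
#' @param config the [simulation_config()] used to build it.
#' @param out_dir directory for `run01.pairs` ... and `hic_seqs.tsv`,
#'   `hic_truth.tsv`.
#' @return List with `pairs_files`, `seq_file`, `truth` (data frame:
#'   `site`, `chrom`, `start`, `end`, `runs` comma-separated, `n_runs`).
#' @export
generate_hic_runs <- function(genome, config, out_dir) {
  set.seed(config$seed + 101L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rl <- config$read_length_bp
  n_runs <- config$n_hic_runs
  telo_len <- 6L * genome$telomere_array_units

  sites <- genome$we_sites[seq_len(config$n_planted_contact_sites), ,
                           drop = FALSE]
  site_runs <- lapply(seq_len(nrow(sites)), function(i) {
    sort(sample.int(n_runs, config$planted_recurrence))
  })

  n_noise <- round(config$contacts_per_run * config$noise_contact_rate)
  chrom_seq <- setNames(as.character(genome$sequences),
                        genome$chrom_names)
  pair_rows <- vector("list", n_runs)
  seq_rows <- vector("list", n_runs)
  read_counter <- 0L

  for (r in seq_len(n_runs)) {
    rows <- list()
    srows <- list()
    # planted telomere-anchored contacts assigned to this run
    for (i in seq_len(nrow(sites))) {
      if (!(r %in% site_runs[[i]])) next
      read_counter <- read_counter + 1L
      id <- sprintf("read%06d", read_counter)
      tchrom <- sample(genome$chrom_names, 1L)
      side <- sample(c("p", "q"), 1L)
      tpos <- if (side == "p") {
        sample.int(telo_len - rl, 1L) - 1L
      } else {
        genome$chrom_lengths[[tchrom]] - telo_len +
          sample.int(telo_len - rl, 1L) - 1L
      }
      tseq <- .subseq_chr(genome, tchrom, tpos, rl)
      # anchor read overlapping the planted site
      off <- sample.int(rl - (sites$end[i] - sites$start[i]), 1L) - 1L
      apos <- max(0L, sites$start[i] - off)
      aseq <- .subseq_chr(genome, sites$chrom[i], apos, rl)
      swap <- sample(c(TRUE, FALSE), 1L)
      if (swap) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = id, chr1 = sites$chrom[i], pos1 = apos,
          chr2 = tchrom, pos2 = tpos, strand1 = "+", strand2 = "+")
        srows[[length(srows) + 1L]] <- data.frame(
          read_id = id, seq1 = aseq, seq2 = tseq, mapq1 = 60L, mapq2 = 0L)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = id, chr1 = tchrom, pos1 = tpos,
          chr2 = sites$chrom[i], pos2 = apos, strand1 = "+", strand2 = "+")
        srows[[length(srows) + 1L]] <- data.frame(
          read_id = id, seq1 = tseq, seq2 = aseq, mapq1 = 0L, mapq2 = 60L)
      }
    }
    # noise: random interior-locus pairs (vectorized)
    if (n_noise > 0L) {
      interior_pos <- function(chroms) {
        span <- genome$chrom_lengths[chroms] - 2L * telo_len - rl
        telo_len + as.integer(floor(runif(length(chroms)) * span))
      }
      seq_at <- function(chroms, pos) {
        out <- character(length(chroms))
        for (ch in unique(chroms)) {
          i <- chroms == ch
          out[i] <- substring(chrom_seq[[ch]], pos[i] + 1L, pos[i] + rl)
        }
        out
      }
      ids <- sprintf("read%06d", read_counter + seq_len(n_noise))
      read_counter <- read_counter + n_noise
      c1 <- sample(genome$chrom_names, n_noise, replace = TRUE)
      c2 <- sample(genome$chrom_names, n_noise, replace = TRUE)
      p1 <- interior_pos(c1); p2 <- interior_pos(c2)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = ids, chr1 = c1, pos1 = p1, chr2 = c2, pos2 = p2,
        strand1 = sample(c("+", "-"), n_noise, replace = TRUE),
        strand2 = sample(c("+", "-"), n_noise, replace = TRUE))
      srows[[length(srows) + 1L]] <- data.frame(
        read_id = ids, seq1 = seq_at(c1, p1), seq2 = seq_at(c2, p2),
        mapq1 = 60L, mapq2 = 60L)
    }
    pair_rows[[r]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(0), chr1 = character(0),
                 pos1 = integer(0), chr2 = character(0), pos2 = integer(0),
                 strand1 = character(0), strand2 = character(0))
    seq_rows[[r]] <- if (length(srows)) do.call(rbind, srows) else NULL
  }

  pairs_files <- character(n_runs)
  for (r in seq_len(n_runs)) {
    f <- file.path(out_dir, sprintf("run%02d.pairs", r))
    con <- file(f, "w")
    writeLines("## pairs format v1.0", con)
    writeLines("#columns: readID chr1 pos1 chr2 pos2 strand1 strand2", con)
    df <- pair_rows[[r]]
    if (nrow(df)) {
      writeLines(do.call(paste, c(df, sep = "\t")), con)
    }
    close(con)
    pairs_files[r] <- f
  }
  seq_file <- file.path(out_dir, "hic_seqs.tsv")
  .write_tsv(do.call(rbind, seq_rows[!vapply(seq_rows, is.null, TRUE)]),
             seq_file)

  truth <- data.frame(
    site = sites$name, chrom = sites$chrom,
    start = sites$start, end = sites$end,
    runs = vapply(site_runs, function(x) paste(x, collapse = ","), ""),
    n_runs = vapply(site_runs, length, 0L))
  .write_tsv(truth, file.path(out_dir, "hic_truth.tsv"))

  list(pairs_files = pairs_files, seq_file = seq_file, truth = truth)
}

#' Read a pairs-format file
#'
#' Parses the 7-column 4DN-style dialect written by [generate_hic_runs()]
#' (header lines start with `#`).  A malformed data line raises an error
#' naming its line number.
#'
#' @param path pairs file.
#' @return Data frame `read_id`, `chr1`, `pos1`, `chr2`, `pos2`, `strand1`,
#'   `strand2` (positions 0-based).
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  data_lines <- lines[keep]
  if (!length(data_lines)) {
    return(data.frame(read_id = character(0), chr1 = character(0),
                      pos1 = integer(0), chr2 = character(0),
                      pos2 = integer(0), strand1 = character(0),
                      strand2 = character(0)))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L)) {
    bad <- which(keep)[which(nf != 7L)[1]]
    stop("malformed pairs line ", bad, " in ", path,
         " (expected 7 fields, got ", nf[nf != 7L][1], ")", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(read_id = m[, 1], chr1 = m[, 2], pos1 = as.integer(m[, 3]),
             chr2 = m[, 4], pos2 = as.integer(m[, 5]), strand1 = m[, 6],
             strand2 = m[, 7], stringsAsFactors = FALSE)
}
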