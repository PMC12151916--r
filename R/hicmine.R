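# Mining telomere-anchored interactions from Hi-C read pairs: classify
# mates by their longest tandem TTAGGG run, keep pairs joining a telomeric
# mate to a mapped non-telomeric anchor, expand anchors by +/-100 bp, and
# aggregate anchors that recur across sequencing runs.

#' Count tandem telomere-repeat units in a read
#'
#' Finds the longest run of consecutive repeat-unit copies (each copy
#' allowed up to `max_mismatch_per_unit` Hamming mismatches) in a read,
#' evaluating both the G-rich unit (TTAGGG) and its reverse complement
#' (CCCTAA) over all six phase offsets, and reporting the better
#' orientation.  `N` counts as a mismatch.
#'
#' @param seq nucleotide string over ACGTN; an empty string yields a
#'   zero-unit call.
#' @param unit repeat unit (default [TELOMERE_UNIT]).
#' @param max_mismatch_per_unit mismatches tolerated within each unit copy.
#' @return A `repeat_call` list: `max_tandem_units`, `unit_orientation`
#'   (`"forward"`/`"reverse"`), `total_units` (unit copies at the best
#'   phase, bounded by `floor(nchar(seq)/nchar(unit))`).
#' @export
count_tandem_units <- function(seq, unit = TELOMERE_UNIT,
                               max_mismatch_per_unit = 0L) {
  if (nchar(unit) < 2L) stop("unit length must be >= 2", call. = FALSE)
  if (is.na(seq) || nchar(seq) == 0L) {
    return(structure(list(max_tandem_units = 0L,
                          unit_orientation = "forward", total_units = 0L),
                     class = "repeat_call"))
  }
  .check_dna(seq, "read sequence")
  best <- list(run = 0L, total = 0L, orient = "forward")
  for (orient in c("forward", "reverse")) {
    u <- if (orient == "forward") unit else .revcomp(unit)
    res <- .scan_orientation(seq, u, max_mismatch_per_unit)
    if (res$run > best$run ||
        (res$run == best$run && res$total > best$total)) {
      best <- list(run = res$run, total = res$total, orient = orient)
    }
  }
  structure(list(max_tandem_units = best$run,
                 unit_orientation = best$orient,
                 total_units = best$total),
            class = "repeat_call")
}

# Longest run and per-phase maximum of matching unit-sized chunks for one
# orientation: chunk the read at each of the ulen phase offsets and count
# chunks within the mismatch budget.
#' @noRd
.scan_orientation <- function(seq, unit, mm) {
  n <- nchar(seq)
  ulen <- nchar(unit)
  if (n < ulen) return(list(run = 0L, total = 0L))
  unit_chars <- strsplit(unit, "")[[1]]
  best_run <- 0L
  best_total <- 0L
  for (off in 0:(ulen - 1L)) {
    n_chunks <- (n - off) %/% ulen
    if (n_chunks == 0L) next
    starts <- off + (seq_len(n_chunks) - 1L) * ulen + 1L
    chunks <- substring(seq, starts, starts + ulen - 1L)
    if (mm == 0L) {
      ok <- chunks == unit
    } else {
      ok <- vapply(chunks, function(ch) {
        sum(strsplit(ch, "")[[1]] != unit_chars) <= mm
      }, TRUE, USE.NAMES = FALSE)
    }
    r <- rle(ok)
    run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    best_run <- max(best_run, run)
    best_total <- max(best_total, sum(ok))
  }
  list(run = best_run, total = best_total)
}

#' Classify a read as telomeric or not
#'
#' A read is telomeric when its longest tandem run reaches `min_units`
#' unit copies (default 7); reads with 1-6 tandem units are ITS-like and
#' discarded from the telomeric class.
#'
#' @param call a `repeat_call` from [count_tandem_units()].
#' @param min_units classification threshold, >= 1.
#' @return `"telomeric"` or `"non_telomeric"`.
#' @export
classify_read <- function(call, min_units = 7L) {
  if (min_units < 1L) stop("min_units must be >= 1", call. = FALSE)
  if (call$max_tandem_units >= min_units) "telomeric" else "non_telomeric"
}

# Vectorized telomeric classification; exact for zero-mismatch counting
# (a regex for min_units consecutive copies in either orientation covers
# every phase), falling back to per-read counting otherwise.
#' @noRd
.classify_seqs <- function(seqs, unit, min_units, mm) {
  if (mm == 0L) {
    pat <- sprintf("(%s){%d}|(%s){%d}", unit, min_units,
                   .revcomp(unit), min_units)
    grepl(pat, seqs)
  } else {
    vapply(seqs, function(s) {
      classify_read(count_tandem_units(s, unit, mm),
                    min_units) == "telomeric"
    }, TRUE, USE.NAMES = FALSE)
  }
}

#' Extract telomere-anchored contacts from a pairs file
#'
#' A contact record is emitted iff exactly one mate classifies telomeric
#' (longest tandem run >= `min_units`) and the other maps with
#' `mapq >= min_mapq` to a locus that overlaps neither an annotated
#' terminal telomere array nor (when `drop_its_anchors`) an annotated ITS
#' interval of >= `min_units` units — internal telomere look-alikes do not
#' count as telomere anchors.  Pairs with two telomeric mates, missing
#' sequence, low anchor mapq or an excluded anchor locus are dropped and
#' tallied in the audit log.
#'
#' @param pairs_file pairs-format file ([read_pairs()] dialect).
#' @param seq_file TSV sequence side-file (`read_id`, `seq1`, `seq2`,
#'   `mapq1`, `mapq2`), or a data frame of the same shape.
#' @param telomere_arrays interval data frame of terminal arrays.
#' @param its interval data frame of ITS arrays with a `units` column
#'   (may be `NULL`).
#' @param run_id label stored with every record.
#' @param min_units telomeric classification threshold (default 7).
#' @param min_mapq minimum anchor mapping quality (default 30).
#' @param max_mismatch_per_unit mismatch tolerance per unit copy.
#' @param drop_its_anchors discard anchors inside >= `min_units`-unit ITS
#'   intervals (default TRUE).
#' @return List with `contacts` (data frame: `run_id`, `read_id`, `chrom`,
#'   `start`, `end`, `mapq`, `telo_units`, `telo_orientation`) and `log`
#'   (named discard tallies).
#' @export
extract_telomeric_contacts <- function(pairs_file, seq_file,
                                       telomere_arrays, its = NULL,
                                       run_id = NULL,
                                       min_units = 7L, min_mapq = 30L,
                                       max_mismatch_per_unit = 0L,
                                       drop_its_anchors = TRUE) {
  if (is.null(run_id)) {
    run_id <- if (is.character(pairs_file)) basename(pairs_file) else
      "run1"
  }
  pairs <- if (is.data.frame(pairs_file)) pairs_file else
    read_pairs(pairs_file)
  seqs <- if (is.data.frame(seq_file)) seq_file else .read_tsv(seq_file)
  log <- c(n_pairs = nrow(pairs), missing_seq = 0L, telo_telo = 0L,
           no_telomeric_mate = 0L, low_mapq = 0L,
           anchor_in_telomere = 0L, anchor_in_its = 0L, emitted = 0L)
  empty <- data.frame(run_id = character(0), read_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), mapq = integer(0),
                      telo_units = integer(0),
                      telo_orientation = character(0))
  if (!nrow(pairs)) return(list(contacts = empty, log = log))

  m <- match(pairs$read_id, seqs$read_id)
  missing <- is.na(m)
  log["missing_seq"] <- sum(missing)
  pairs <- pairs[!missing, , drop = FALSE]
  sq <- seqs[m[!missing], , drop = FALSE]
  if (!nrow(pairs)) return(list(contacts = empty, log = log))

  telo1 <- .classify_seqs(sq$seq1, TELOMERE_UNIT, min_units,
                          max_mismatch_per_unit)
  telo2 <- .classify_seqs(sq$seq2, TELOMERE_UNIT, min_units,
                          max_mismatch_per_unit)
  log["telo_telo"] <- sum(telo1 & telo2)
  log["no_telomeric_mate"] <- sum(!telo1 & !telo2)
  keep <- xor(telo1, telo2)
  if (!any(keep)) return(list(contacts = empty, log = log))
  pairs <- pairs[keep, , drop = FALSE]
  sq <- sq[keep, , drop = FALSE]
  t1 <- telo1[keep]

  anchor <- data.frame(
    run_id = run_id,
    read_id = pairs$read_id,
    chrom = ifelse(t1, pairs$chr2, pairs$chr1),
    start = ifelse(t1, pairs$pos2, pairs$pos1),
    mapq = ifelse(t1, sq$mapq2, sq$mapq1),
    telo_seq = ifelse(t1, sq$seq1, sq$seq2),
    anchor_seq_len = nchar(ifelse(t1, sq$seq2, sq$seq1)),
    stringsAsFactors = FALSE)
  anchor$end <- anchor$start + anchor$anchor_seq_len

  ok_mapq <- anchor$mapq >= min_mapq
  log["low_mapq"] <- sum(!ok_mapq)
  anchor <- anchor[ok_mapq, , drop = FALSE]
  if (nrow(anchor)) {
    gr <- .as_granges(anchor)
    in_telo <- rep(FALSE, nrow(anchor))
    if (!is.null(telomere_arrays) && nrow(telomere_arrays)) {
      in_telo <- IRanges::overlapsAny(gr, .as_granges(telomere_arrays),
                                      ignore.strand = TRUE)
    }
    log["anchor_in_telomere"] <- sum(in_telo)
    in_its <- rep(FALSE, nrow(anchor))
    if (drop_its_anchors && !is.null(its) && nrow(its)) {
      its_big <- its[its$units >= min_units, , drop = FALSE]
      if (nrow(its_big)) {
        in_its <- IRanges::overlapsAny(gr, .as_granges(its_big),
                                       ignore.strand = TRUE)
      }
    }
    log["anchor_in_its"] <- sum(in_its & !in_telo)
    anchor <- anchor[!in_telo & !in_its, , drop = FALSE]
  }
  log["emitted"] <- nrow(anchor)

  calls <- lapply(anchor$telo_seq, count_tandem_units,
                  unit = TELOMERE_UNIT,
                  max_mismatch_per_unit = max_mismatch_per_unit)
  contacts <- data.frame(
    run_id = anchor$run_id, read_id = anchor$read_id,
    chrom = anchor$chrom, start = anchor$start, end = anchor$end,
    mapq = anchor$mapq,
    telo_units = vapply(calls, `[[`, 0L, "max_tandem_units"),
    telo_orientation = vapply(calls, `[[`, "", "unit_orientation"),
    stringsAsFactors = FALSE)
  list(contacts = contacts, log = log)
}

#' Expand an anchor interval symmetrically
#'
#' Pads an interval by `pad_bp` on both sides (the search window for
#' motifs around an interaction anchor; default 100 bp), clipping at the
#' chromosome bounds.
#'
#' @param intervals 0-based half-open interval data frame.
#' @param pad_bp pad on each side.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return The intervals with `start`/`end` padded and clipped.
#' @export
expand_anchor <- function(intervals, pad_bp = 100L, chrom_sizes) {
  intervals$start <- pmax(0L, intervals$start - pad_bp)
  intervals$end <- pmin(unname(chrom_sizes[intervals$chrom]),
                        intervals$end + pad_bp)
  intervals
}

#' Aggregate contacts recurring across runs
#'
#' Expands every anchor by `pad_bp`, merges expanded anchors lying within
#' `merge_gap_bp` of each other, and keeps merged interactions supported
#' by at least `min_runs` distinct runs — the recurrence filter that
#' suppresses non-reproducible contacts.
#'
#' @param contacts data frame of contact records pooled across runs (as
#'   emitted by [extract_telomeric_contacts()], with a `run_id` column).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param pad_bp anchor expansion (default 100).
#' @param merge_gap_bp maximal gap between expanded anchors merged into
#'   one interaction (default 0: touching/overlapping only).
#' @param min_runs minimal number of distinct supporting runs (default 2).
#' @return Data frame sorted by position: `chrom`, `start`, `end`, `name`,
#'   `score` (= `n_runs`), `n_runs`, `runs` (comma-separated), `n_reads`.
#'   `min_runs` larger than the number of runs present yields an empty
#'   result with a warning.
#' @export
aggregate_recurrent <- function(contacts, chrom_sizes, pad_bp = 100L,
                                merge_gap_bp = 0L, min_runs = 2L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), n_runs = integer(0),
                      runs = character(0), n_reads = integer(0))
  if (is.null(contacts) || !nrow(contacts)) return(empty)
  n_runs_present <- length(unique(contacts$run_id))
  if (min_runs > n_runs_present) {
    warning("min_runs (", min_runs, ") exceeds the number of runs ",
            "provided (", n_runs_present, "); no interaction can qualify")
    return(empty)
  }
  exp <- expand_anchor(contacts, pad_bp = pad_bp,
                       chrom_sizes = chrom_sizes)
  gr <- .as_granges(exp)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap_bp + 1L,
                                  ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  runs_by <- split(exp$run_id, grp)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_runs = vapply(runs_by, function(x) length(unique(x)), 0L),
    runs = vapply(runs_by,
                  function(x) paste(sort(unique(x)), collapse = ","), ""),
    n_reads = vapply(runs_by, length, 0L),
    stringsAsFactors = FALSE)
  out <- out[out$n_runs >= min_runs, , drop = FALSE]
  out <- out[order(match(out$chrom, names(chrom_sizes)), out$start), ,
             drop = FALSE]
  if (nrow(out)) {
    out$name <- sprintf("interaction%03d", seq_len(nrow(out)))
    out$score <- out$n_runs
  } else {
    out$name <- character(0)
    out$score <- integer(0)
  }
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "score", "n_runs", "runs",
          "n_reads")]
}

#' Annotate interactions with their nearest chromosome end
#'
#' @param interactions interval data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return The input with `nearest_end` (`p`/`q`) and
#'   `distance_to_end_bp` (midpoint to the nearer chromosome extremity).
#' @export
annotate_nearest_end <- function(interactions, chrom_sizes) {
  if (!nrow(interactions)) {
    interactions$nearest_end <- character(0)
    interactions$distance_to_end_bp <- numeric(0)
    return(interactions)
  }
  mid <- (interactions$start + interactions$end) / 2
  L <- unname(chrom_sizes[interactions$chrom])
  d_p <- mid
  d_q <- L - mid
  interactions$nearest_end <- ifelse(d_p <= d_q, "p", "q")
  interactions$distance_to_end_bp <- pmin(d_p, d_q)
  interactions
}
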