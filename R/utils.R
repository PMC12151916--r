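# Shared helpers: interval containers, BED/TSV I/O, sequence utilities,
# recovery scoring.  All genomic intervals in the package are 0-based
# half-open [start, end), the BED convention; conversion to the 1-based
# closed IRanges convention happens only at the GenomicRanges boundary.

#' Convert a 0-based half-open interval data frame to a GRanges
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return A [GenomicRanges::GRanges] with the same rows.
#' @keywords internal
#' @noRd
.as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand   = strand
  )
}

#' Write intervals as BED
#'
#' Writes a BED6 file (chrom, start, end, name, score, strand) from a
#' 0-based half-open interval data frame.  Missing name/score/strand
#' columns are filled with `"."`, `0` and `"."`.
#'
#' @param df interval data frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  n <- nrow(df)
  out <- data.frame(
    chrom  = df$chrom,
    start  = df$start,
    end    = df$end,
    name   = if ("name" %in% names(df)) df$name else rep(".", n),
    score  = if ("score" %in% names(df)) df$score else rep(0L, n),
    strand = if ("strand" %in% names(df)) df$strand else rep(".", n),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval data frame
#'
#' @param path BED file (3 to 6 columns, no header).
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.  Coordinates stay 0-based
#'   half-open.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  df
}

#' @noRd
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' @noRd
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
.check_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(what, " contains non-ACGTN symbols (first offender: ",
         seq[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Sample `n` non-overlapping intervals of the given widths inside
# [lo, hi).  Rejection sampling against already-placed intervals; a
# packing that cannot be realized raises an explicit placement error.
#' @noRd
.place_intervals <- function(widths, lo, hi, occupied = NULL,
                             max_tries = 2000L) {
  starts <- integer(0)
  ends   <- integer(0)
  occ_s  <- if (is.null(occupied)) integer(0) else occupied$start
  occ_e  <- if (is.null(occupied)) integer(0) else occupied$end
  for (w in widths) {
    if (hi - lo < w) {
      stop("placement error: interval of width ", w,
           " cannot fit in [", lo, ", ", hi, ")", call. = FALSE)
    }
    placed <- FALSE
    for (i in seq_len(max_tries)) {
      s <- lo + sample.int(hi - lo - w + 1L, 1L) - 1L
      e <- s + w
      if (!any(s < c(occ_e, ends) & e > c(occ_s, starts))) {
        starts <- c(starts, s); ends <- c(ends, e)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place an interval of width ", w,
           " without overlap after ", max_tries, " tries", call. = FALSE)
    }
  }
  data.frame(start = starts, end = ends)
}

#' Score recovery of planted intervals
#'
#' Compares called intervals with a truth set by any-overlap and reports
#' recall (planted intervals recovered) and precision (calls matching a
#' planted interval).  Both sets are 0-based half-open data frames with
#' `chrom`, `start`, `end`.
#'
#' @param called data frame of called intervals.
#' @param truth data frame of planted intervals.
#' @return List with `recall`, `precision`, `n_called`, `n_truth`,
#'   `n_truth_recovered`, `n_called_matching`.  Empty `called` gives
#'   precision `NA` and recall 0 (or `NA` when `truth` is empty too).
#' @export
score_recovery <- function(called, truth) {
  n_called <- if (is.null(called)) 0L else nrow(called)
  n_truth  <- if (is.null(truth)) 0L else nrow(truth)
  if (n_truth == 0L) {
    return(list(recall = NA_real_, precision = if (n_called) 0 else NA_real_,
                n_called = n_called, n_truth = 0L,
                n_truth_recovered = 0L, n_called_matching = 0L))
  }
  if (n_called == 0L) {
    return(list(recall = 0, precision = NA_real_, n_called = 0L,
                n_truth = n_truth, n_truth_recovered = 0L,
                n_called_matching = 0L))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(called), .as_granges(truth),
                                      ignore.strand = TRUE)
  rec <- length(unique(S4Vectors::subjectHits(hits)))
  mat <- length(unique(S4Vectors::queryHits(hits)))
  list(recall = rec / n_truth, precision = mat / n_called,
       n_called = n_called, n_truth = n_truth,
       n_truth_recovered = rec, n_called_matching = mat)
}
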