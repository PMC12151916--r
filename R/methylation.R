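# DMR calling between adjacent telomere-length conditions, the
# directional-consistency filter along the shortening series, and
# bisulfite amplicon summaries.
#
# The caller is deliberately minimal and fully specified: probe-level
# delta-beta merging followed by a region-level two-sample t-test, carrying
# the reporting thresholds (>= 7 probes, > 50 bp width, p < 0.05).

#' @noRd
.condition_cols <- function(beta, condition) {
  cols <- grep(paste0("^", condition, "_"), colnames(beta))
  if (!length(cols)) {
    stop("condition '", condition, "' absent from the beta matrix",
         call. = FALSE)
  }
  cols
}

#' Call differentially methylated regions between two conditions
#'
#' Probe-level delta is mean beta of `condition_b` minus `condition_a`;
#' pass the longer-telomere condition as `condition_a` so positive deltas
#' (hypermethylation) mean gain upon shortening.  Candidate regions are
#' consecutive probes on the same chromosome (gap <= `max_probe_gap_bp`)
#' whose locally smoothed delta (centered running mean over
#' `smooth_probes` probes, computed per chromosome) reaches
#' |delta| >= `delta_cutoff` with a common sign; smoothing bridges single
#' noisy probes inside a true region, and region edges are then trimmed
#' back to probes whose raw delta passes the cutoff with the region's
#' sign, so boundaries stay sharp.  The region p-value is a two-sample
#' t-test on replicate-level region means.  Regions failing the
#' probe-count filter (`min_probes`), the width filter (width, last minus
#' first probe position, must exceed `min_width_bp`) or the p-value
#' cutoff are dropped.
#'
#' @param beta numeric matrix, probes x samples; column names
#'   `<condition>_<replicate>`.
#' @param manifest data frame `probe_id`, `chrom`, `pos`, sorted by
#'   position within each chromosome (unsorted input is an error).
#' @param condition_a,condition_b condition labels (a = longer telomeres).
#' @param min_probes minimum probes per region (default 7).
#' @param min_width_bp width each region must exceed (default 50).
#' @param p_cutoff region p-value cutoff (default 0.05).
#' @param delta_cutoff minimum probe |delta beta| (default 0.05).
#' @param max_probe_gap_bp maximum gap between consecutive probes of one
#'   region (default 1000).
#' @param smooth_probes window of the running-mean delta smoother, odd
#'   (default 3; 1 disables smoothing).
#' @param adjust apply Benjamini-Hochberg correction across candidate
#'   regions before the p cutoff (default FALSE: plain cutoff).
#' @return Data frame of DMRs (0-based half-open): `chrom`, `start`,
#'   `end`, `n_probes`, `width_bp`, `mean_delta_beta`, `direction`
#'   (`hyper`/`hypo`), `p_value`, `comparison`.
#' @export
call_dmrs <- function(beta, manifest, condition_a, condition_b,
                      min_probes = 7L, min_width_bp = 50L,
                      p_cutoff = 0.05, delta_cutoff = 0.05,
                      max_probe_gap_bp = 1000L, smooth_probes = 3L,
                      adjust = FALSE) {
  stopifnot(nrow(beta) == nrow(manifest))
  for (ch in unique(manifest$chrom)) {
    p <- manifest$pos[manifest$chrom == ch]
    if (is.unsorted(p)) {
      stop("manifest positions are not sorted on ", ch, call. = FALSE)
    }
  }
  cols_a <- .condition_cols(beta, condition_a)
  cols_b <- .condition_cols(beta, condition_b)
  comparison <- paste0(sub("kb$", "", condition_a), "v",
                       sub("kb$", "", condition_b))

  if (smooth_probes < 1L || smooth_probes %% 2L == 0L) {
    stop("smooth_probes must be a positive odd integer", call. = FALSE)
  }
  delta <- rowMeans(beta[, cols_b, drop = FALSE]) -
    rowMeans(beta[, cols_a, drop = FALSE])

  half <- (smooth_probes - 1L) %/% 2L
  regions <- list()
  for (ch in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == ch)
    pos <- manifest$pos[idx]
    d <- delta[idx]
    sm <- if (half == 0L) d else vapply(seq_along(d), function(i) {
      mean(d[max(1L, i - half):min(length(d), i + half)])
    }, 0)
    ok <- abs(sm) >= delta_cutoff
    if (!any(ok)) next
    s_sm <- sign(sm)
    # break runs at non-candidates, smoothed-sign changes, large gaps
    brk <- c(TRUE, diff(pos) > max_probe_gap_bp |
               s_sm[-1] != s_sm[-length(s_sm)])
    grp <- cumsum(brk | !ok)
    for (g in unique(grp[ok])) {
      loc <- which(grp == g & ok)
      if (!length(loc)) next
      # trim edges back to probes passing the raw-delta cutoff
      sgn <- s_sm[loc[1]]
      raw_ok <- d[loc] * sgn >= delta_cutoff
      if (!any(raw_ok)) next
      loc <- loc[min(which(raw_ok)):max(which(raw_ok))]
      regions[[length(regions) + 1L]] <- idx[loc]
    }
  }
  if (!length(regions)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      width_bp = integer(0), mean_delta_beta = numeric(0),
                      direction = character(0), p_value = numeric(0),
                      comparison = character(0)))
  }

  rows <- lapply(regions, function(sel) {
    pos <- manifest$pos[sel]
    mean_a <- colMeans(beta[sel, cols_a, drop = FALSE])
    mean_b <- colMeans(beta[sel, cols_b, drop = FALSE])
    p <- tryCatch(t.test(mean_b, mean_a)$p.value,
                  error = function(e) NA_real_)
    md <- mean(delta[sel])
    data.frame(chrom = manifest$chrom[sel[1]],
               start = min(pos), end = max(pos) + 1L,
               n_probes = length(sel),
               width_bp = max(pos) - min(pos),
               mean_delta_beta = md,
               direction = if (md >= 0) "hyper" else "hypo",
               p_value = p, comparison = comparison)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_value <- p.adjust(out$p_value, method = "BH")
  keep <- out$n_probes >= min_probes & out$width_bp > min_width_bp &
    !is.na(out$p_value) & out$p_value < p_cutoff
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
.parse_comparison <- function(label) {
  as.numeric(strsplit(label, "v", fixed = TRUE)[[1]])
}

#' Keep DMRs with a constant direction along telomere shortening
#'
#' A DMR from the first comparison (e.g. 12 vs 10 kb) is kept iff every
#' subsequent comparison (10 vs 8, 8 vs 6) contains an overlapping DMR
#' with the same direction — constant hyper- or hypomethylation across
#' the shortening series.  The kept set is always a subset of the first
#' comparison's set.
#'
#' @param dmr_sets named list of DMR data frames from [call_dmrs()], in
#'   telomere-length order; names like `"12v10"`, `"10v8"`, `"8v6"`.
#'   Labels that do not chain (each comparison starting where the previous
#'   ended, lengths decreasing) are an error.
#' @param min_overlap_bp minimal overlap between chained DMRs (default 1).
#' @return The surviving rows of the first comparison's set, with a
#'   `supported_by` column recording the chain of comparisons.
#' @export
filter_directional <- function(dmr_sets, min_overlap_bp = 1L) {
  if (length(dmr_sets) < 2L) {
    stop("need at least two comparisons", call. = FALSE)
  }
  labels <- names(dmr_sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("dmr_sets must be named by comparison (e.g. '12v10')",
         call. = FALSE)
  }
  pairs <- lapply(labels, .parse_comparison)
  for (i in seq_along(pairs)) {
    if (length(pairs[[i]]) != 2L || any(is.na(pairs[[i]])) ||
        pairs[[i]][1] <= pairs[[i]][2]) {
      stop("malformed comparison label '", labels[i], "'", call. = FALSE)
    }
    if (i > 1L && pairs[[i]][1] != pairs[[i - 1L]][2]) {
      stop("comparisons out of order: '", labels[i - 1L],
           "' is not followed by '", labels[i], "'", call. = FALSE)
    }
  }
  first <- dmr_sets[[1]]
  if (!nrow(first)) {
    first$supported_by <- character(0)
    return(first)
  }
  keep <- rep(TRUE, nrow(first))
  for (j in 2:length(dmr_sets)) {
    other <- dmr_sets[[j]]
    if (!nrow(other)) { keep[] <- FALSE; break }
    ov <- GenomicRanges::findOverlaps(
      .as_granges(first), .as_granges(other),
      minoverlap = min_overlap_bp, ignore.strand = TRUE)
    same_dir <- first$direction[S4Vectors::queryHits(ov)] ==
      other$direction[S4Vectors::subjectHits(ov)]
    supported <- unique(S4Vectors::queryHits(ov)[same_dir])
    keep <- keep & seq_len(nrow(first)) %in% supported
  }
  out <- first[keep, , drop = FALSE]
  out$supported_by <- rep(paste(labels, collapse = ","), nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a bisulfite amplicon call matrix
#'
#' TSV of one amplicon: rows are reads/clones, columns CpG positions,
#' entries `1` (methylated), `0` (unmethylated) or `X` (misaligned).
#'
#' @param path TSV file (no header by default).
#' @param header whether the file has a header row.
#' @return Character matrix of `"1"`/`"0"`/`"X"`.
#' @export
read_bisulfite <- function(path, header = FALSE) {
  m <- as.matrix(read.table(path, sep = "\t", header = header,
                            colClasses = "character"))
  bad <- !(m %in% c("1", "0", "X"))
  if (any(bad)) {
    stop("bisulfite matrix entries must be 1, 0 or X (found '",
         m[bad][1], "')", call. = FALSE)
  }
  m
}

#' Summarize a bisulfite call matrix per CpG
#'
#' Per-CpG mean methylation is the number of `1` calls over the number of
#' non-`X` calls in that column; the smoothed series is a centered moving
#' average over `smooth_window` CpGs (edges average over the neighbors
#' available).  A column consisting entirely of `X` has an undefined mean:
#' it is flagged and excluded from the smoothing series.
#'
#' @param mat character matrix of `"1"`/`"0"`/`"X"` (rows = reads,
#'   columns = CpGs), e.g. from [read_bisulfite()].
#' @param smooth_window moving-average window, odd (default 3).
#' @return Data frame per CpG: `cpg`, `n_meth`, `n_valid`, `mean_meth`,
#'   `smoothed` (`NA` for flagged columns), `flagged`.
#' @export
summarize_bisulfite <- function(mat, smooth_window = 3L) {
  if (!nrow(mat) || !ncol(mat)) stop("empty matrix", call. = FALSE)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("smooth_window must be a positive odd integer", call. = FALSE)
  }
  n_meth <- colSums(mat == "1")
  n_valid <- colSums(mat != "X")
  mean_meth <- ifelse(n_valid > 0, n_meth / n_valid, NA_real_)
  flagged <- n_valid == 0
  half <- (smooth_window - 1L) %/% 2L
  valid_idx <- which(!flagged)
  smoothed <- rep(NA_real_, ncol(mat))
  # smooth over the series of valid columns only
  for (k in seq_along(valid_idx)) {
    lo <- max(1L, k - half)
    hi <- min(length(valid_idx), k + half)
    smoothed[valid_idx[k]] <- mean(mean_meth[valid_idx[lo:hi]])
  }
  data.frame(cpg = seq_len(ncol(mat)), n_meth = n_meth,
             n_valid = n_valid, mean_meth = mean_meth,
             smoothed = smoothed, flagged = flagged)
}
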