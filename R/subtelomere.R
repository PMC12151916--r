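# Subtelomeric windows (default 10 Mb from each chromosome end) and
# enrichment tests of gene/region sets within them.

#' Build subtelomeric windows
#'
#' Two windows per chromosome, one from each end, each spanning `span_bp`
#' (default 10 Mb, the operational definition of a subtelomere).  On
#' chromosomes shorter than twice the span the two windows are truncated
#' at the midpoint so they never overlap.
#'
#' @param chrom_sizes named numeric vector (or 2-column data frame
#'   `chrom`, `size`) of chromosome lengths in bp.
#' @param span_bp window span from each end, bp.
#' @return Data frame with one row per chromosome end, in chromosome order
#'   with the p (start) side before the q (end) side: `chrom`, `end_id`
#'   (`<chrom>_p` / `<chrom>_q`), `side`, `start`, `end` (0-based
#'   half-open).
#' @export
make_subtelomere_windows <- function(chrom_sizes, span_bp = 1e7) {
  if (span_bp <= 0) stop("span_bp must be positive", call. = FALSE)
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes[[2]], chrom_sizes[[1]])
  }
  if (any(chrom_sizes <= 0)) {
    stop("all chromosome sizes must be positive", call. = FALSE)
  }
  chroms <- names(chrom_sizes)
  rows <- lapply(chroms, function(ch) {
    L <- chrom_sizes[[ch]]
    cut_p <- min(span_bp, floor(L / 2))
    cut_q <- max(L - span_bp, floor(L / 2))
    data.frame(chrom = ch,
               end_id = paste0(ch, c("_p", "_q")),
               side = c("p", "q"),
               start = c(0, cut_q),
               end = c(cut_p, L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count features inside subtelomeric windows
#'
#' Each feature is counted at most once overall.  A feature overlapping
#' the windows of both ends (possible on short chromosomes) is assigned to
#' the end whose telomere is nearer to the feature midpoint; an exact tie
#' goes to the p side.  Features on chromosomes absent from the windows
#' are skipped with a warning and reported in `n_skipped`.
#'
#' @param features 0-based half-open interval data frame (`chrom`,
#'   `start`, `end`).
#' @param windows output of [make_subtelomere_windows()].
#' @param rule `"any"` (default): any overlap with a window counts;
#'   `"within"`: the feature must be fully contained.
#' @return List with `per_end` (windows plus a `count` column), `total`
#'   (features counted), `n_features`, `n_skipped`.
#' @export
count_in_windows <- function(features, windows, rule = c("any", "within")) {
  rule <- match.arg(rule)
  known <- features$chrom %in% windows$chrom
  if (any(!known)) {
    warning(sum(!known), " feature(s) on chromosomes absent from the ",
            "window set were skipped")
  }
  feats <- features[known, , drop = FALSE]
  counts <- setNames(rep(0L, nrow(windows)), windows$end_id)
  if (nrow(feats)) {
    type <- if (rule == "any") "any" else "within"
    hits <- GenomicRanges::findOverlaps(.as_granges(feats),
                                        .as_granges(windows),
                                        type = type, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # resolve multi-window features to the nearest end (tie -> p side)
    chrom_len <- setNames(windows$end[windows$side == "q"],
                          windows$chrom[windows$side == "q"])
    for (f in unique(qh)) {
      cand <- sh[qh == f]
      pick <- cand[1]
      if (length(cand) > 1L) {
        mid <- (feats$start[f] + feats$end[f]) / 2
        d <- vapply(cand, function(w) {
          if (windows$side[w] == "p") mid else
            chrom_len[[windows$chrom[w]]] - mid
        }, 0)
        best <- cand[d == min(d)]
        pick <- best[order(windows$side[best])][1]
      }
      counts[pick] <- counts[pick] + 1L
    }
  }
  per_end <- windows
  per_end$count <- as.integer(counts)
  list(per_end = per_end, total = sum(counts),
       n_features = nrow(features), n_skipped = sum(!known))
}

#' Test enrichment of a feature set in subtelomeric windows
#'
#' Given a universe of `n_universe` features of which
#' `n_in_windows_universe` lie in subtelomeric windows, and a set of
#' `n_set` features of which `n_set_in_windows` do, tests whether the set
#' is over-represented in the windows.
#'
#' `test = "hypergeometric"` gives the exact upper-tail probability of
#' drawing at least `n_set_in_windows` in-window members when `n_set`
#' features are drawn without replacement from the universe.
#' `test = "chisq"` is the 1-df goodness-of-fit test of the observed
#' in/out split against the universe proportion; when an expected cell is
#' below 5 the result carries `low_count = TRUE` but is still returned.
#'
#' @param n_set_in_windows in-window members of the set.
#' @param n_set set size.
#' @param n_in_windows_universe in-window members of the universe.
#' @param n_universe universe size.
#' @param test `"hypergeometric"` or `"chisq"`.
#' @return An `enrichment_result` list: `n_universe`,
#'   `n_in_windows_universe`, `n_set`, `n_set_in_windows`,
#'   `expected_proportion`, `observed_proportion`, `test_name`,
#'   `statistic`, `p_value`, `low_count`.
#' @export
enrichment_test <- function(n_set_in_windows, n_set,
                            n_in_windows_universe, n_universe,
                            test = c("hypergeometric", "chisq")) {
  test <- match.arg(test)
  if (n_universe <= 0) stop("empty universe", call. = FALSE)
  if (n_set > n_universe) {
    stop("set larger than universe", call. = FALSE)
  }
  if (n_set_in_windows > min(n_set, n_in_windows_universe)) {
    stop("inconsistent counts: more in-window set members than possible",
         call. = FALSE)
  }
  p0 <- n_in_windows_universe / n_universe
  low_count <- FALSE
  if (test == "hypergeometric") {
    statistic <- n_set_in_windows
    p <- phyper(n_set_in_windows - 1, n_in_windows_universe,
                n_universe - n_in_windows_universe, n_set,
                lower.tail = FALSE)
    test_name <- "hypergeometric upper tail"
  } else {
    expected <- c(n_set * p0, n_set * (1 - p0))
    low_count <- any(expected < 5)
    observed <- c(n_set_in_windows, n_set - n_set_in_windows)
    if (any(expected == 0)) {
      statistic <- NA_real_
      p <- NA_real_
    } else {
      ct <- suppressWarnings(chisq.test(observed, p = c(p0, 1 - p0)))
      statistic <- unname(ct$statistic)
      p <- ct$p.value
    }
    test_name <- "chi-squared goodness of fit (1 df)"
  }
  structure(list(
    n_universe = n_universe,
    n_in_windows_universe = n_in_windows_universe,
    n_set = n_set, n_set_in_windows = n_set_in_windows,
    expected_proportion = p0,
    observed_proportion = if (n_set > 0) n_set_in_windows / n_set else
      NA_real_,
    test_name = test_name, statistic = statistic, p_value = p,
    low_count = low_count
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "%s\n  set: %d/%d in windows (%.1f%%); expected %.1f%%\n  statistic = %.4g, p = %.4g%s\n",
    x$test_name, x$n_set_in_windows, x$n_set,
    100 * x$observed_proportion, 100 * x$expected_proportion,
    x$statistic, x$p_value,
    if (isTRUE(x$low_count)) "  [low-count]" else ""))
  invisible(x)
}
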