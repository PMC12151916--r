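# Scanning for the 35-bp WE consensus: Hamming matching on both strands,
# association of hits with genes/DMRs, and 2x2 proximity enrichment.

#' Scan sequences for a consensus motif
#'
#' Reports every position whose window is within `max_mismatch` Hamming
#' mismatches of the consensus; with `both_strands` the reverse complement
#' is matched too (hits reported on the forward coordinates with strand
#' `-`).  Matching is ungapped (no indels) and ambiguity codes in the
#' consensus are rejected.  When `intervals` is given, only those windows
#' are scanned (`source_region` records which); hit coordinates are always
#' genomic.
#'
#' @param sequences a named [Biostrings::DNAStringSet], a `genome_model`,
#'   or a FASTA path.
#' @param consensus motif string over ACGT (default [WE_CONSENSUS]).
#' @param max_mismatch Hamming tolerance (default 0).
#' @param both_strands also match the reverse complement (default TRUE).
#' @param intervals optional 0-based half-open data frame (`chrom`,
#'   `start`, `end`, optional `name`) restricting the scan.
#' @return Data frame sorted by position: `chrom`, `start`, `end`,
#'   `strand`, `mismatches`, `source_region`.
#' @export
scan_motif <- function(sequences, consensus = WE_CONSENSUS,
                       max_mismatch = 0L, both_strands = TRUE,
                       intervals = NULL) {
  if (grepl("[^ACGT]", consensus)) {
    stop("consensus must be over ACGT (ambiguity codes unsupported)",
         call. = FALSE)
  }
  if (is(sequences, "genome_model") ||
      (is.list(sequences) && !is.null(sequences$sequences))) {
    sequences <- sequences$sequences
  }
  if (is.character(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  k <- nchar(consensus)
  pats <- list("+" = Biostrings::DNAString(consensus))
  if (both_strands) {
    pats[["-"]] <- Biostrings::reverseComplement(pats[["+"]])
  }
  windows <- if (is.null(intervals)) {
    data.frame(chrom = names(sequences), start = 0L,
               end = Biostrings::width(sequences),
               name = "genome")
  } else {
    w <- intervals
    if (!"name" %in% names(w)) {
      w$name <- sprintf("region%03d", seq_len(nrow(w)))
    }
    w
  }
  hits <- list()
  for (i in seq_len(nrow(windows))) {
    chrom <- windows$chrom[i]
    subj <- Biostrings::subseq(sequences[[chrom]],
                               start = windows$start[i] + 1L,
                               end = windows$end[i])
    for (strand in names(pats)) {
      m <- Biostrings::matchPattern(pats[[strand]], subj,
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (!length(m)) next
      mism <- vapply(seq_along(m), function(j) {
        Biostrings::neditAt(pats[[strand]], subj,
                            at = Biostrings::start(m)[j])
      }, 0L)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom,
        start = windows$start[i] + Biostrings::start(m) - 1L,
        end = windows$start[i] + Biostrings::start(m) - 1L + k,
        strand = strand, mismatches = mism,
        source_region = windows$name[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0),
                      source_region = character(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate motif hits with genes and DMRs
#'
#' A hit is associated with every gene whose locus, extended by
#' `flank_bp` on both sides (default 2 kb), overlaps it, and with every
#' DMR overlapping it directly.  Genes and DMRs with at least one hit are
#' flagged WE-associated.
#'
#' @param hits data frame from [scan_motif()].
#' @param genes interval data frame with `name`.
#' @param dmrs optional DMR interval data frame.
#' @param flank_bp gene flank (default 2000).
#' @return List with `genes` (per-gene `n_hits`, `we_associated`), `dmrs`
#'   (same per DMR, or `NULL`), and `pairs` (hit index / gene name rows).
#' @export
associate_hits <- function(hits, genes, dmrs = NULL, flank_bp = 2000L) {
  gene_hits <- integer(nrow(genes))
  pairs <- data.frame(hit = integer(0), gene = character(0))
  if (nrow(hits) && nrow(genes)) {
    ext <- genes
    ext$start <- pmax(0L, ext$start - flank_bp)
    ext$end <- ext$end + flank_bp
    ov <- GenomicRanges::findOverlaps(.as_granges(hits), .as_granges(ext),
                                      ignore.strand = TRUE)
    tab <- table(factor(S4Vectors::subjectHits(ov),
                        levels = seq_len(nrow(genes))))
    gene_hits <- as.integer(tab)
    pairs <- data.frame(hit = S4Vectors::queryHits(ov),
                        gene = genes$name[S4Vectors::subjectHits(ov)])
  }
  gene_out <- data.frame(gene = genes$name, n_hits = gene_hits,
                         we_associated = gene_hits > 0)
  dmr_out <- NULL
  if (!is.null(dmrs)) {
    dmr_hits <- integer(nrow(dmrs))
    if (nrow(hits) && nrow(dmrs)) {
      ov <- GenomicRanges::findOverlaps(.as_granges(hits),
                                        .as_granges(dmrs),
                                        ignore.strand = TRUE)
      tab <- table(factor(S4Vectors::subjectHits(ov),
                          levels = seq_len(nrow(dmrs))))
      dmr_hits <- as.integer(tab)
    }
    dmr_out <- cbind(dmrs, n_hits = dmr_hits,
                     we_associated = dmr_hits > 0)
  }
  list(genes = gene_out, dmrs = dmr_out, pairs = pairs)
}

#' Test motif proximity enrichment in a gene set
#'
#' 2x2 chi-squared test (1 df, no continuity correction) of membership in
#' the gene set `set_genes` against WE-association, as used for repeat
#' proximity enrichment near deregulated genes.  Degenerate margins (all
#' or no genes associated, or an empty off-set) return p = 1 with
#' `degenerate = TRUE`.
#'
#' @param set_genes character vector of gene identifiers (must be a
#'   subset of `associations$gene`).
#' @param associations per-gene association table from
#'   [associate_hits()]`$genes` (the background universe).
#' @return List: the 2x2 `table`, `odds_ratio` (`Inf` flagged),
#'   `statistic`, `p_value`, `degenerate`.
#' @export
proximity_enrichment <- function(set_genes, associations) {
  set_norm <- normalize_gene_list(set_genes)
  univ_norm <- toupper(trimws(associations$gene))
  if (!all(set_norm %in% univ_norm)) {
    stop("set_genes must be a subset of the association universe",
         call. = FALSE)
  }
  in_set <- univ_norm %in% set_norm
  assoc <- associations$we_associated
  tab <- matrix(c(sum(in_set & assoc), sum(in_set & !assoc),
                  sum(!in_set & assoc), sum(!in_set & !assoc)),
                nrow = 2, dimnames = list(
                  set = c("in_set", "background"),
                  we = c("associated", "not_associated")),
                byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, odds_ratio = NA_real_, statistic = 0,
                p_value = 1, degenerate = TRUE))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab, odds_ratio = or,
       statistic = unname(ct$statistic), p_value = ct$p.value,
       degenerate = FALSE)
}
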