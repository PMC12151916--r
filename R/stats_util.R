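# Small shared computations: population doublings, DEG thresholding,
# gene-list overlap percentages.

#' Population doublings between two cell counts
#'
#' PD = ln(final / initial) / ln 2; negative when the population shrank.
#'
#' @param initial_cells,final_cells positive cell counts.
#' @return Population doublings (numeric).
#' @export
population_doublings <- function(initial_cells, final_cells) {
  if (any(initial_cells <= 0) || any(final_cells <= 0)) {
    stop("cell counts must be positive", call. = FALSE)
  }
  log(final_cells / initial_cells) / log(2)
}

#' Normalize a gene list
#'
#' Upper-cases, strips surrounding whitespace and deduplicates gene
#' identifiers; cross-annotation ID mapping is out of scope.
#'
#' @param x character vector of gene identifiers.
#' @return Unique normalized identifiers.
#' @export
normalize_gene_list <- function(x) {
  unique(toupper(trimws(x)))
}

#' Filter a differential-expression table to DEGs
#'
#' Keeps genes with `FDR < fdr_cutoff` and `|log2FC| > abs_lfc_cutoff`
#' (both strict).
#'
#' @param table data frame with columns `gene`, `log2FC`, `FDR`.
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param abs_lfc_cutoff absolute log2 fold-change threshold (default 2).
#' @return Normalized character vector of DEG identifiers.
#' @export
deg_filter <- function(table, fdr_cutoff = 0.05, abs_lfc_cutoff = 2) {
  need <- c("gene", "log2FC", "FDR")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$FDR < 0 | table$FDR > 1, na.rm = TRUE)) {
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  }
  keep <- table$FDR < fdr_cutoff & abs(table$log2FC) > abs_lfc_cutoff
  normalize_gene_list(table$gene[keep & !is.na(keep)])
}

#' Percentage overlap between two gene lists
#'
#' 100 * |a intersect b| / |denominator list|.  Identifiers are
#' normalized with [normalize_gene_list()] first.  The denominator choice
#' is explicit because overlap percentages are asymmetric.
#'
#' @param a,b character vectors of gene identifiers.
#' @param denominator which list sizes the percentage: `"a"` (default),
#'   `"b"` or `"union"`.
#' @return List: `percent`, `n_overlap`, `n_denominator`, `denominator`.
#' @export
list_overlap_percent <- function(a, b,
                                 denominator = c("a", "b", "union")) {
  denominator <- match.arg(denominator)
  a <- normalize_gene_list(a)
  b <- normalize_gene_list(b)
  denom <- switch(denominator, a = a, b = b, union = union(a, b))
  if (!length(denom)) stop("empty denominator list", call. = FALSE)
  n_ov <- length(intersect(a, b))
  list(percent = 100 * n_ov / length(denom), n_overlap = n_ov,
       n_denominator = length(denom), denominator = denominator)
}
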