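# Per-chromosome-end feature tables and unsupervised hierarchical
# clustering of chromosome ends (Ward.D2 on Manhattan distances).

#' Build a normalized chromosome-end feature table
#'
#' Rows are chromosome ends; columns are telomere-associated features
#' (WE motif occurrences, DEG counts, ITS, replication timing, optional
#' protein signals).  A DEG ratio (DEG count / gene count, the
#' gene-density correction) is added when both columns are named.  Every
#' non-timing column is divided by its mean so its mean becomes exactly 1;
#' the replication-timing column is affinely mapped so its minimum (early
#' replication) becomes -1 and its maximum (late) becomes +1.  Columns
#' with mean 0, constant timing, or missing values cannot be normalized
#' and are dropped with a warning — values are never imputed.
#'
#' @param raw data frame of per-end features; row identifiers in
#'   `end_col`.
#' @param end_col name of the end-identifier column (default `"end_id"`).
#' @param timing_col replication-timing column name (or `NA` if absent).
#' @param deg_col,gene_count_col columns used to derive the DEG ratio;
#'   the gene-count column itself is not clustered on.  Ends with zero
#'   genes get ratio 0 and are flagged.
#' @return An `end_feature_table` list: `table` (numeric matrix, rownames
#'   = end ids), `normalization` (per-column method and scale),
#'   `zero_gene_ends`.
#' @export
build_end_table <- function(raw, end_col = "end_id",
                            timing_col = "replication_timing",
                            deg_col = "n_deg",
                            gene_count_col = "n_genes") {
  stopifnot(end_col %in% names(raw))
  ends <- raw[[end_col]]
  feats <- raw[, setdiff(names(raw), end_col), drop = FALSE]
  zero_gene_ends <- character(0)
  if (!is.na(deg_col) && deg_col %in% names(feats) &&
      !is.na(gene_count_col) && gene_count_col %in% names(feats)) {
    g <- feats[[gene_count_col]]
    ratio <- ifelse(g > 0, feats[[deg_col]] / g, 0)
    zero_gene_ends <- ends[g == 0]
    feats$deg_ratio <- ratio
    feats[[gene_count_col]] <- NULL
  }
  na_cols <- names(feats)[vapply(feats, function(x) any(is.na(x)), TRUE)]
  if (length(na_cols)) {
    warning("dropping column(s) with missing values (no imputation): ",
            paste(na_cols, collapse = ", "))
    feats <- feats[, setdiff(names(feats), na_cols), drop = FALSE]
  }
  norm <- list()
  for (cn in names(feats)) {
    x <- feats[[cn]]
    if (!is.na(timing_col) && cn == timing_col) {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        warning("constant replication-timing column dropped")
        feats[[cn]] <- NULL
        next
      }
      feats[[cn]] <- 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
      norm[[cn]] <- list(method = "range_-1_1", min = rng[1],
                         max = rng[2])
    } else {
      m <- mean(x)
      if (m == 0) {
        warning("column '", cn, "' has mean 0 and was dropped")
        feats[[cn]] <- NULL
        next
      }
      feats[[cn]] <- x / m
      norm[[cn]] <- list(method = "mean_1", mean = m)
    }
  }
  tab <- as.matrix(feats)
  rownames(tab) <- ends
  structure(list(table = tab, normalization = norm,
                 zero_gene_ends = zero_gene_ends),
            class = "end_feature_table")
}

#' Cluster chromosome ends
#'
#' Agglomerative hierarchical clustering of the normalized end-feature
#' table with pairwise Manhattan distances and the Ward.D2 linkage (the
#' Lance-Williams update applied to squared dissimilarities, with merge
#' heights reported on the unsquared scale).
#'
#' @param table an `end_feature_table` from [build_end_table()], or a
#'   numeric matrix with row names.
#' @param k number of clusters to cut into (optional).
#' @param h cut height (alternative to `k`).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @return List: `hclust` (the merge tree), `labels` (named cluster
#'   labels when `k` or `h` given), `newick` (dendrogram serialization),
#'   `dist` the distance object.
#' @export
cluster_ends <- function(table, k = NULL, h = NULL,
                         metric = "manhattan", linkage = "ward.D2") {
  m <- if (inherits(table, "end_feature_table")) table$table else table
  if (nrow(m) < 2L) stop("need at least two ends to cluster",
                         call. = FALSE)
  if (!is.null(k) && k > nrow(m)) {
    stop("k (", k, ") exceeds the number of ends (", nrow(m), ")",
         call. = FALSE)
  }
  d <- dist(m, method = metric)
  hc <- hclust(d, method = linkage)
  labels <- NULL
  if (!is.null(k) || !is.null(h)) {
    labels <- cutree(hc, k = k, h = h)
  }
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  list(hclust = hc, labels = labels, newick = newick, dist = d)
}

#' Tally per-end features from pipeline results
#'
#' Convenience builder of the raw per-end feature table from pipeline
#' intermediates: counts WE motif hits, DEGs, genes and ITS arrays inside
#' each subtelomeric window.
#'
#' @param windows subtelomere windows ([make_subtelomere_windows()]).
#' @param hits motif hits ([scan_motif()]).
#' @param genes gene intervals with `name`.
#' @param deg_genes character vector of DEG identifiers.
#' @param its ITS interval data frame (optional).
#' @param timing optional named numeric vector of per-end replication
#'   timing.
#' @return Data frame with one row per end: `end_id`, `n_we`, `n_deg`,
#'   `n_genes`, `n_its`, and `replication_timing` when supplied.
#' @export
tally_end_features <- function(windows, hits, genes, deg_genes,
                               its = NULL, timing = NULL) {
  count_feats <- function(f) {
    if (is.null(f) || !nrow(f)) return(setNames(rep(0L, nrow(windows)),
                                                windows$end_id))
    cw <- count_in_windows(f, windows, rule = "any")
    setNames(cw$per_end$count, cw$per_end$end_id)
  }
  deg <- genes[genes$name %in% deg_genes, , drop = FALSE]
  out <- data.frame(end_id = windows$end_id,
                    n_we = as.integer(count_feats(hits)),
                    n_deg = as.integer(count_feats(deg)),
                    n_genes = as.integer(count_feats(genes)),
                    n_its = as.integer(count_feats(its)))
  if (!is.null(timing)) {
    out$replication_timing <- unname(timing[out$end_id])
  }
  out
}
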