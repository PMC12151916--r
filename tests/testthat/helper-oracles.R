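# Independent brute-force oracles used to cross-check the implementation.
# Each is written against the definition, not the code path it verifies.

# Longest run of consecutive exact unit copies, via regex on both
# orientations (covers every phase offset by construction).
oracle_max_tandem_units <- function(seq, unit = "TTAGGG") {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unit)))
  best <- 0L
  for (u in c(unit, rc)) {
    m <- gregexpr(paste0("(", u, ")+"), seq)[[1]]
    if (m[1] != -1L) {
      best <- max(best, max(attr(m, "match.length")) %/% nchar(u))
    }
  }
  best
}

# All-positions Hamming scan for a consensus, both strands.
oracle_hamming_scan <- function(seq, consensus, max_mismatch = 0L,
                                both_strands = TRUE) {
  k <- nchar(consensus)
  n <- nchar(seq)
  if (n < k) return(data.frame(start = integer(0), strand = character(0),
                               mismatches = integer(0)))
  s_chars <- strsplit(seq, "")[[1]]
  pats <- list("+" = strsplit(consensus, "")[[1]])
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(consensus)))
    pats[["-"]] <- strsplit(rc, "")[[1]]
  }
  rows <- list()
  for (st in names(pats)) {
    p <- pats[[st]]
    for (i in 0:(n - k)) {
      mm <- sum(s_chars[(i + 1):(i + k)] != p)
      if (mm <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = i, strand = st, mismatches = mm)
      }
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0),
                                       strand = character(0),
                                       mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Upper-tail hypergeometric probability by direct summation over the
# exact composition probabilities P(X = x) = C(K,x) C(N-K,n-x) / C(N,n).
oracle_hypergeom_upper <- function(k, K, N, n) {
  xs <- k:min(n, K)
  xs <- xs[xs >= max(0, n - (N - K))]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Centered moving average with partial windows at the edges.
oracle_moving_average <- function(x, window) {
  half <- (window - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  }, 0)
}

# Greedy Ward.D2 agglomeration from first principles: at each step merge
# the pair of clusters minimizing the Ward criterion
# d^2(A,B) -> (|A||B|)/(|A|+|B|) applied through the Lance-Williams
# update on squared dissimilarities; heights reported unsquared.
oracle_ward_d2 <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        if (d2[a, b] < best_val) { best_val <- d2[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- sqrt(best_val)
    merges[[step]] <- sort(c(members[[a]], members[[b]]))
    # Lance-Williams (Ward) update on squared dissimilarities
    for (c_ in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[c_]
      upd <- ((na + nc) * d2[a, c_] + (nb + nc) * d2[b, c_] -
                nc * d2[a, b]) / (na + nb + nc)
      d2[a, c_] <- d2[c_, a] <- upd
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  list(heights = heights, merges = merges)
}

# Flat partition at k clusters from the oracle merge sequence.
oracle_ward_cut <- function(oracle, n, k) {
  labels <- seq_len(n)
  for (step in seq_len(n - k)) {
    m <- oracle$merges[[step]]
    labels[labels %in% labels[m]] <- min(labels[m])
  }
  as.integer(factor(labels))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small fast simulation configuration shared across tests; any
# simulation_config() argument can be overridden.
tiny_config <- function(seed = 42L, ...) {
  defaults <- list(
    seed = seed, n_chroms = 2L, chrom_length_bp = 6e5,
    telomere_units = 100L, n_its_below_threshold = 3L,
    n_its_at_or_above_threshold = 2L, n_we_sites = 6L, n_genes = 30L,
    n_hic_runs = 4L, contacts_per_run = 100L,
    n_planted_contact_sites = 3L, planted_recurrence = 4L,
    methylation = list(n_background_probes_per_chrom = 80L,
                       subtel_span_bp = 1e5),
    deg = list(n_deg = 6L, span_bp = 1e5))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
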