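# DMR calling, the directional-consistency filter, bisulfite summaries.

# deterministic beta matrix builder: `regions` rows are (start index,
# n probes, delta applied to condition b)
make_beta <- function(n_probes, n_reps = 4, base = 0.4, spacing = 50,
                      deltas = numeric(0), idx = integer(0),
                      sd = 0.01, seed = 1) {
  set.seed(seed)
  manifest <- data.frame(probe_id = sprintf("cg%04d", seq_len(n_probes)),
                         chrom = "chr1",
                         pos = seq(0, by = spacing,
                                   length.out = n_probes))
  mean_a <- rep(base, n_probes)
  mean_b <- mean_a
  mean_b[idx] <- mean_b[idx] + deltas
  beta <- cbind(
    matrix(rnorm(n_probes * n_reps, mean_a, sd), ncol = n_reps),
    matrix(rnorm(n_probes * n_reps, mean_b, sd), ncol = n_reps))
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- c(paste0("12kb_", 1:n_reps), paste0("10kb_", 1:n_reps))
  rownames(beta) <- manifest$probe_id
  list(beta = beta, manifest = manifest)
}

test_that("the caller emits planted regions and applies all three filters", {
  # 10 candidate probes spanning 450 bp at delta +0.15: one hyper DMR
  d <- make_beta(40, idx = 11:20, deltas = rep(0.15, 10))
  dmrs <- call_dmrs(d$beta, d$manifest, "12kb", "10kb")
  expect_identical(nrow(dmrs), 1L)
  expect_identical(dmrs$direction, "hyper")
  expect_identical(dmrs$n_probes, 10L)
  expect_equal(dmrs$width_bp, 450)
  expect_equal(dmrs$start, d$manifest$pos[11])
  expect_lt(dmrs$p_value, 0.05)
  expect_equal(dmrs$mean_delta_beta, 0.15, tolerance = 0.05)

  # 6 probes at delta +0.3: rejected by the probe-count filter
  d6 <- make_beta(40, idx = 11:16, deltas = rep(0.3, 6))
  expect_identical(nrow(call_dmrs(d6$beta, d6$manifest, "12kb", "10kb")),
                   0L)

  # 8 probes within 40 bp: rejected by the width filter
  d8 <- make_beta(40, idx = 11:18, deltas = rep(0.3, 8), spacing = 5)
  expect_identical(nrow(call_dmrs(d8$beta, d8$manifest, "12kb", "10kb")),
                   0L)

  # hypomethylation gives direction "hypo"
  dh <- make_beta(40, idx = 11:20, deltas = rep(-0.15, 10))
  expect_identical(call_dmrs(dh$beta, dh$manifest, "12kb",
                             "10kb")$direction, "hypo")
})

test_that("emitted DMRs are monotone in every threshold", {
  d <- make_beta(60, idx = c(11:20, 35:44),
                 deltas = c(rep(0.12, 10), rep(-0.2, 10)), seed = 4)
  base_n <- nrow(call_dmrs(d$beta, d$manifest, "12kb", "10kb"))
  looser <- nrow(call_dmrs(d$beta, d$manifest, "12kb", "10kb",
                           min_probes = 3L, min_width_bp = 10L,
                           p_cutoff = 0.2, delta_cutoff = 0.02))
  expect_gte(looser, base_n)
  tighter <- nrow(call_dmrs(d$beta, d$manifest, "12kb", "10kb",
                            min_probes = 15L))
  expect_lte(tighter, base_n)
})

test_that("caller validates conditions and manifest ordering", {
  d <- make_beta(20)
  expect_error(call_dmrs(d$beta, d$manifest, "12kb", "99kb"),
               "absent from the beta matrix")
  bad <- d$manifest
  bad$pos <- rev(bad$pos)
  expect_error(call_dmrs(d$beta, bad, "12kb", "10kb"), "not sorted")
})

test_that("directional filter keeps constant-direction chains only", {
  dmr <- function(start, end, dir, comparison)
    data.frame(chrom = "chr1", start = start, end = end, n_probes = 10L,
               width_bp = end - start, mean_delta_beta = 0.1,
               direction = dir, p_value = 0.01, comparison = comparison)
  hyper_all <- list(
    "12v10" = rbind(dmr(100, 600, "hyper", "12v10"),
                    dmr(5000, 5400, "hyper", "12v10")),
    "10v8" = rbind(dmr(150, 550, "hyper", "10v8"),
                   dmr(5100, 5300, "hypo", "10v8")),
    "8v6" = dmr(120, 580, "hyper", "8v6"))
  kept <- filter_directional(hyper_all)
  # first region is hyper in all three comparisons; second flips sign
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$start, 100)
  expect_identical(kept$supported_by, "12v10,10v8,8v6")

  # an empty later comparison empties the result
  empty_last <- hyper_all
  empty_last[["8v6"]] <- empty_last[["8v6"]][0, ]
  expect_identical(nrow(filter_directional(empty_last)), 0L)

  # comparisons must chain along the shortening series
  bad_order <- hyper_all[c("12v10", "8v6", "10v8")]
  expect_error(filter_directional(bad_order), "out of order")
  expect_error(filter_directional(hyper_all["12v10"]), "at least two")
})

test_that("planted monotone DMRs are recovered with high recall/precision", {
  # the stage-level acceptance property, at reduced seed count here
  ok <- vapply(1:10, function(s) {
    cfg <- tiny_config(seed = 1000L + s)
    g <- generate_genome(cfg)
    m <- generate_methylation_series(g, cfg)
    sets <- list(
      "12v10" = call_dmrs(m$beta, m$manifest, "12kb", "10kb"),
      "10v8" = call_dmrs(m$beta, m$manifest, "10kb", "8kb"),
      "8v6" = call_dmrs(m$beta, m$manifest, "8kb", "6kb"))
    direc <- filter_directional(sets)
    sc <- score_recovery(direc, m$truth[m$truth$kind == "monotone", ])
    flips <- score_recovery(direc,
                            m$truth[m$truth$kind == "decoy_signflip", ])
    c(sc$recall, sc$precision, flips$n_truth_recovered)
  }, c(0, 0, 0))
  expect_gte(mean(ok[1, ]), 0.9)
  expect_gte(mean(ok[2, ]), 0.9)
  # sign-flipping decoys are always removed
  expect_identical(sum(ok[3, ]), 0)
})

test_that("bisulfite summaries follow the 1/0/X convention", {
  m <- matrix(c("1", "0", "X", "1"), ncol = 1)
  s <- summarize_bisulfite(m)
  expect_equal(s$mean_meth, 2 / 3)

  all1 <- matrix("1", nrow = 5, ncol = 8)
  s1 <- summarize_bisulfite(all1)
  expect_true(all(s1$mean_meth == 1))
  expect_true(all(s1$smoothed == 1))

  # an all-X column is flagged and excluded from smoothing
  mx <- matrix("1", nrow = 4, ncol = 5)
  mx[, 3] <- "X"
  sx <- summarize_bisulfite(mx)
  expect_true(sx$flagged[3])
  expect_true(is.na(sx$smoothed[3]))
  expect_false(any(is.na(sx$smoothed[-3])))

  expect_error(summarize_bisulfite(matrix(character(0), 0, 0)), "empty")
  expect_error(summarize_bisulfite(all1, smooth_window = 2), "odd")
})

test_that("smoothed series equals an independent moving average", {
  set.seed(17)
  m <- matrix(sample(c("1", "0", "X"), 50 * 16, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)), nrow = 50)
  s <- summarize_bisulfite(m, smooth_window = 3)
  means <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    sum(col == "1") / sum(col != "X")
  }, 0)
  expect_equal(s$mean_meth, means)
  expect_equal(s$smoothed, oracle_moving_average(means, 3))

  # round-trip through the TSV representation
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(m, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_identical(unname(read_bisulfite(tmp)), unname(m))
})

test_that("directional chain false positives stay below nominal alpha", {
  # null: no planted signal anywhere; the full chain (three independent
  # comparisons each at p < 0.05 with matching sign) should pass a
  # region far less often than alpha
  set.seed(55)
  n_sim <- 200L
  n_probes <- 12L
  false_pos <- vapply(seq_len(n_sim), function(i) {
    manifest <- data.frame(probe_id = sprintf("cg%03d", 1:n_probes),
                           chrom = "chr1",
                           pos = seq(0, by = 50, length.out = n_probes))
    beta <- matrix(pmin(pmax(rnorm(n_probes * 16, 0.5, 0.05), 0), 1),
                   nrow = n_probes)
    colnames(beta) <- as.vector(outer(1:4, c("12kb", "10kb", "8kb", "6kb"),
                                      function(r, c) paste0(c, "_", r)))
    sets <- list(
      "12v10" = call_dmrs(beta, manifest, "12kb", "10kb",
                          delta_cutoff = 0.01),
      "10v8" = call_dmrs(beta, manifest, "10kb", "8kb",
                         delta_cutoff = 0.01),
      "8v6" = call_dmrs(beta, manifest, "8kb", "6kb",
                        delta_cutoff = 0.01))
    nrow(filter_directional(sets)) > 0
  }, TRUE)
  expect_lte(mean(false_pos), 0.05)
})
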