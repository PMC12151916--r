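# Tandem-repeat counting, read classification, contact extraction and
# recurrence aggregation.

test_that("tandem unit counting handles both orientations and phases", {
  f <- count_tandem_units(strrep("TTAGGG", 7))
  expect_identical(f$max_tandem_units, 7L)
  expect_identical(f$unit_orientation, "forward")

  seq <- paste0(random_dna(20), strrep("CCCTAA", 10), random_dna(15))
  r <- count_tandem_units(seq)
  expect_identical(r$max_tandem_units, 10L)
  expect_identical(r$unit_orientation, "reverse")

  # interrupted runs: the maximal consecutive run is reported, the
  # interrupted copies still count toward total_units
  seq2 <- paste0(strrep("TTAGGG", 4), "ACGTAC", strrep("TTAGGG", 3))
  r2 <- count_tandem_units(seq2)
  expect_identical(r2$max_tandem_units, 4L)
  expect_identical(r2$total_units, 7L)

  expect_identical(count_tandem_units("")$max_tandem_units, 0L)
  expect_error(count_tandem_units("TTAGGQ"), "non-ACGTN")
  expect_error(count_tandem_units("TTAGGG", unit = "A"), ">= 2")
})

test_that("unit counting agrees with a regex oracle on random reads", {
  set.seed(31)
  n_reads <- 10000L
  # bias reads toward repeat-rich content so nonzero calls are frequent
  reads <- vapply(seq_len(n_reads), function(i) {
    if (i %% 4 == 0) {
      k <- sample(1:12, 1)
      paste0(random_dna(sample(0:15, 1)),
             strrep(sample(c("TTAGGG", "CCCTAA"), 1), k),
             random_dna(sample(0:15, 1)))
    } else {
      random_dna(75L)
    }
  }, "")
  got <- vapply(reads, function(s)
    count_tandem_units(s)$max_tandem_units, 0L, USE.NAMES = FALSE)
  want <- vapply(reads, oracle_max_tandem_units, 0L, USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("mismatch-tolerant counting accepts degenerate unit copies", {
  # one mismatch per unit copy
  seq <- paste0("TTAGGA", "TTAGGG", "TAAGGG", "TTAGGG", "TTAGGG",
                "TTCGGG", "TTAGGG")
  expect_identical(count_tandem_units(seq)$max_tandem_units, 2L)
  expect_identical(
    count_tandem_units(seq, max_mismatch_per_unit = 1L)$max_tandem_units,
    7L)
})

test_that("the 7-unit boundary separates telomeric from ITS-like reads", {
  mk <- function(u) count_tandem_units(strrep("TTAGGG", u))
  expect_identical(classify_read(mk(6)), "non_telomeric")
  expect_identical(classify_read(mk(7)), "telomeric")
  expect_identical(classify_read(mk(0)), "non_telomeric")
  expect_error(classify_read(mk(7), min_units = 0L), ">= 1")
})

test_that("contact extraction recovers planted contacts and applies filters", {
  cfg <- tiny_config(seed = 21L, noise_contact_rate = 0)
  g <- generate_genome(cfg)
  h <- generate_hic_runs(g, cfg, out_dir = withr::local_tempdir())
  res <- extract_telomeric_contacts(h$pairs_files[1], h$seq_file,
                                    g$telomere_arrays, g$its,
                                    run_id = "run01")
  # noiseless: every planted contact of the run is emitted at its anchor
  expect_identical(nrow(res$contacts), cfg$n_planted_contact_sites)
  expect_identical(unname(res$log["emitted"]),
                   cfg$n_planted_contact_sites)
  sc <- score_recovery(res$contacts, h$truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_true(all(res$contacts$telo_units >= 7L))

  # a pair of two non-telomeric mates yields no record
  rl <- cfg$read_length_bp
  pairs <- data.frame(read_id = "p1", chr1 = "chr1", pos1 = 700L,
                      chr2 = "chr2", pos2 = 900L,
                      strand1 = "+", strand2 = "+")
  seqs <- data.frame(read_id = "p1", seq1 = random_dna(rl),
                     seq2 = random_dna(rl), mapq1 = 60L, mapq2 = 60L)
  r0 <- extract_telomeric_contacts(pairs, seqs, g$telomere_arrays, g$its)
  expect_identical(nrow(r0$contacts), 0L)
  expect_identical(unname(r0$log["no_telomeric_mate"]), 1L)

  # telomere-telomere pairs are dropped and tallied
  telo_seq <- strrep("TTAGGG", rl %/% 6)
  seqs2 <- data.frame(read_id = "p1", seq1 = telo_seq, seq2 = telo_seq,
                      mapq1 = 0L, mapq2 = 0L)
  r1 <- extract_telomeric_contacts(pairs, seqs2, g$telomere_arrays, g$its)
  expect_identical(unname(r1$log["telo_telo"]), 1L)
  expect_identical(nrow(r1$contacts), 0L)

  # an anchor inside a >= 7-unit ITS interval is discarded
  its_big <- g$its[g$its$units >= 7L, ][1, ]
  pairs3 <- data.frame(read_id = "p1", chr1 = "chr1", pos1 = 100L,
                       chr2 = its_big$chrom, pos2 = its_big$start,
                       strand1 = "+", strand2 = "+")
  seqs3 <- data.frame(read_id = "p1", seq1 = telo_seq,
                      seq2 = random_dna(rl), mapq1 = 0L, mapq2 = 60L)
  r2 <- extract_telomeric_contacts(pairs3, seqs3, g$telomere_arrays,
                                   g$its)
  expect_identical(nrow(r2$contacts), 0L)
  expect_identical(unname(r2$log["anchor_in_its"]), 1L)
  # with the ITS rule switched off the same pair is emitted
  r3 <- extract_telomeric_contacts(pairs3, seqs3, g$telomere_arrays,
                                   g$its, drop_its_anchors = FALSE)
  expect_identical(nrow(r3$contacts), 1L)

  # low anchor mapq is filtered
  seqs4 <- seqs3
  seqs4$mapq2 <- 5L
  pairs4 <- pairs3
  pairs4$chr2 <- "chr1"; pairs4$pos2 <- 50000L
  r4 <- extract_telomeric_contacts(pairs4, seqs4, g$telomere_arrays,
                                   g$its)
  expect_identical(unname(r4$log["low_mapq"]), 1L)
  expect_identical(nrow(r4$contacts), 0L)
})

test_that("malformed pairs lines and missing sequences are surfaced", {
  tmp <- withr::local_tempfile(fileext = ".pairs")
  writeLines(c("## pairs format v1.0", "r1\tchr1\t100\tchr2"), tmp)
  expect_error(read_pairs(tmp), "malformed pairs line 2")

  pairs <- data.frame(read_id = "nope", chr1 = "chr1", pos1 = 1L,
                      chr2 = "chr1", pos2 = 2L, strand1 = "+",
                      strand2 = "+")
  seqs <- data.frame(read_id = "other", seq1 = "ACGT", seq2 = "ACGT",
                     mapq1 = 60L, mapq2 = 60L)
  r <- extract_telomeric_contacts(pairs, seqs, NULL, NULL)
  expect_identical(unname(r$log["missing_seq"]), 1L)
  expect_identical(nrow(r$contacts), 0L)
})

test_that("anchor expansion pads symmetrically and clips at bounds", {
  sizes <- c(chr1 = 10000L)
  iv <- data.frame(chrom = "chr1", start = 1000L, end = 1150L)
  out <- expand_anchor(iv, 100L, sizes)
  expect_identical(c(out$start, out$end), c(900L, 1250L))

  near0 <- expand_anchor(data.frame(chrom = "chr1", start = 50L,
                                    end = 150L), 100L, sizes)
  expect_identical(c(near0$start, near0$end), c(0L, 250L))

  ident <- expand_anchor(iv, 0L, sizes)
  expect_identical(c(ident$start, ident$end), c(1000L, 1150L))
})

test_that("recurrence aggregation keeps planted sites and merges anchors", {
  cfg <- tiny_config(seed = 23L)
  g <- generate_genome(cfg)
  h <- generate_hic_runs(g, cfg, out_dir = withr::local_tempdir())
  contacts <- do.call(rbind, lapply(seq_along(h$pairs_files), function(i)
    extract_telomeric_contacts(h$pairs_files[i], h$seq_file,
                               g$telomere_arrays, g$its,
                               run_id = sprintf("run%02d", i))$contacts))
  inter <- aggregate_recurrent(contacts, g$chrom_lengths, min_runs = 2L)
  sc <- score_recovery(inter, h$truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_true(all(inter$n_runs >= 2L))

  # monotone in min_runs
  n_by_minruns <- vapply(1:4, function(mr)
    nrow(aggregate_recurrent(contacts, g$chrom_lengths, min_runs = mr)),
    0L)
  expect_true(all(diff(n_by_minruns) <= 0))

  # min_runs above the number of runs: empty with warning
  expect_warning(
    empty <- aggregate_recurrent(contacts, g$chrom_lengths,
                                 min_runs = 99L),
    "exceeds the number of runs")
  expect_identical(nrow(empty), 0L)

  # two anchors 50 bp apart merge under a 100 bp gap into one
  # interaction supported by the union of their runs
  two <- data.frame(run_id = c("a", "b"), read_id = c("r1", "r2"),
                    chrom = "chr1", start = c(10000L, 10125L),
                    end = c(10075L, 10200L), mapq = 60L,
                    telo_units = 10L, telo_orientation = "forward")
  m0 <- aggregate_recurrent(two, g$chrom_lengths, pad_bp = 0L,
                            merge_gap_bp = 100L, min_runs = 2L)
  expect_identical(nrow(m0), 1L)
  expect_identical(m0$runs, "a,b")
  # without the merge gap they stay apart and fail min_runs = 2
  m1 <- aggregate_recurrent(two, g$chrom_lengths, pad_bp = 0L,
                            merge_gap_bp = 0L, min_runs = 2L)
  expect_identical(nrow(m1), 0L)
})

test_that("noise contacts degrade precision gracefully, never recall", {
  cfg0 <- tiny_config(seed = 29L, noise_contact_rate = 0)
  g <- generate_genome(cfg0)
  prec <- vapply(c(0, 1, 3), function(rate) {
    cfg <- tiny_config(seed = 29L, noise_contact_rate = rate)
    h <- generate_hic_runs(g, cfg, out_dir = withr::local_tempdir())
    contacts <- do.call(rbind,
      lapply(seq_along(h$pairs_files), function(i)
        extract_telomeric_contacts(h$pairs_files[i], h$seq_file,
                                   g$telomere_arrays, g$its,
                                   run_id = sprintf("run%02d", i))$contacts))
    sc <- score_recovery(
      aggregate_recurrent(contacts, g$chrom_lengths, min_runs = 2L),
      h$truth)
    expect_equal(sc$recall, 1)
    sc$precision
  }, 0)
  expect_true(all(diff(prec) <= 0))
})
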