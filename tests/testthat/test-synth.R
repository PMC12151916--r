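# The synthetic-data generator: genome structure, determinism, Hi-C truth
# tables, methylation series construction, DEG thresholds.

test_that("generated chromosomes carry terminal arrays and planted features", {
  cfg <- tiny_config(seed = 11L)
  g <- generate_genome(cfg)
  telo_len <- 6L * cfg$telomere_units

  for (ch in g$chrom_names) {
    s <- as.character(g$sequences[[ch]])
    expect_identical(substr(s, 1, telo_len),
                     strrep("TTAGGG", cfg$telomere_units))
    expect_identical(substr(s, nchar(s) - telo_len + 1, nchar(s)),
                     strrep("CCCTAA", cfg$telomere_units))
    # exactly two terminal arrays per chromosome
    expect_identical(sum(g$telomere_arrays$chrom == ch), 2L)
  }

  # annotated intervals lie inside bounds and clear of terminal arrays
  feats <- rbind(g$its[c("chrom", "start", "end")],
                 g$we_sites[c("chrom", "start", "end")],
                 g$genes[c("chrom", "start", "end")])
  expect_true(all(feats$start >= telo_len))
  expect_true(all(feats$end <= cfg$chrom_length_bp - telo_len))

  # every WE interval reconstructs the consensus after orienting by strand
  expect_identical(interval_sequence(g, g$we_sites),
                   rep(WE_CONSENSUS, nrow(g$we_sites)))

  # ITS intervals contain the advertised number of tandem units
  its_units <- vapply(interval_sequence(g, g$its),
                      oracle_max_tandem_units, 0L, USE.NAMES = FALSE)
  expect_identical(its_units, g$its$units)
})

test_that("regenerating with one seed yields byte-identical files", {
  cfg <- tiny_config(seed = 3L, n_hic_runs = 2L, contacts_per_run = 20L,
                     planted_recurrence = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    g <- generate_genome(cfg, out_dir = d)
    generate_hic_runs(g, cfg, out_dir = file.path(d, "hic"))
    generate_methylation_series(g, cfg, out_dir = d)
    generate_deg_table(g, cfg, out_dir = d)
  }
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
})

test_that("infeasible feature packing raises a placement error", {
  expect_error(
    generate_genome(tiny_config(seed = 1L, chrom_length_bp = 1300L,
                                telomere_units = 100L)),
    "placement error")
  expect_error(telomir:::.place_intervals(c(50L, 50L), 0L, 80L),
               "placement error")
})

test_that("Hi-C truth table matches the requested recurrence design", {
  cfg <- tiny_config(seed = 5L)
  g <- generate_genome(cfg)
  h <- generate_hic_runs(g, cfg, out_dir = withr::local_tempdir())
  # full recurrence: every planted site lists all runs
  expect_true(all(h$truth$n_runs == cfg$n_hic_runs))
  expect_true(all(h$truth$runs ==
                    paste(seq_len(cfg$n_hic_runs), collapse = ",")))

  # recurrence 1, no noise: pairs files hold only the planted contacts,
  # and mining at min_runs = 2 recovers nothing
  cfg1 <- tiny_config(seed = 6L, planted_recurrence = 1L,
                      noise_contact_rate = 0)
  g1 <- generate_genome(cfg1)
  h1 <- generate_hic_runs(g1, cfg1, out_dir = withr::local_tempdir())
  per_run <- vapply(h1$pairs_files, function(f) nrow(read_pairs(f)), 0L)
  expect_identical(sum(per_run), cfg1$n_planted_contact_sites)
  contacts <- do.call(rbind, lapply(seq_along(h1$pairs_files), function(i)
    extract_telomeric_contacts(h1$pairs_files[i], h1$seq_file,
                               g1$telomere_arrays, g1$its,
                               run_id = sprintf("run%02d", i))$contacts))
  expect_identical(
    nrow(suppressWarnings(
      aggregate_recurrent(contacts, g1$chrom_lengths, min_runs = 2L))),
    0L)
})

test_that("read length too short for the telomeric class is rejected", {
  expect_error(tiny_config(read_length_bp = 30L), "42")
})

test_that("planted methylation series shift condition means monotonically", {
  cfg <- tiny_config(seed = 9L)
  g <- generate_genome(cfg)
  m <- generate_methylation_series(g, cfg)
  expect_true(all(m$beta >= 0 & m$beta <= 1))

  cond_mean <- function(region, cond) {
    gr_t <- m$truth[m$truth$dmr_id == region, ]
    sel <- m$manifest$chrom == gr_t$chrom &
      m$manifest$pos >= gr_t$start & m$manifest$pos < gr_t$end
    mean(m$beta[sel, grep(paste0("^", cond, "_"), colnames(m$beta))])
  }
  mono <- m$truth[m$truth$kind == "monotone", ]
  for (i in seq_len(nrow(mono))) {
    mm <- vapply(c("12kb", "10kb", "8kb", "6kb"), cond_mean,
                 0, region = mono$dmr_id[i])
    if (mono$direction[i] == "hyper") {
      expect_true(all(diff(mm) > 0))
    } else {
      expect_true(all(diff(mm) < 0))
    }
  }
  # decoys exist with their designed violations
  expect_identical(sum(m$truth$kind == "decoy_few_probes" &
                         m$truth$n_probes < 7), 1L)
  expect_identical(sum(m$truth$kind == "decoy_narrow" &
                         m$truth$width_bp <= 50), 1L)
})

test_that("planted DEGs pass the thresholds and non-DEGs fail them", {
  cfg <- tiny_config(seed = 13L)
  g <- generate_genome(cfg)
  d <- generate_deg_table(g, cfg)
  planted <- d$table[d$table$gene %in% d$truth, ]
  others <- d$table[!d$table$gene %in% d$truth, ]
  expect_true(all(planted$FDR < 0.05 & abs(planted$log2FC) > 2))
  expect_true(all(others$FDR >= 0.05 | abs(others$log2FC) <= 2))
  expect_error(
    generate_deg_table(g, tiny_config(seed = 13L,
                                      deg = list(n_deg = 10000L))),
    "exceeds gene count")

  # zero planted DEGs propagate to an empty filtered set
  d0 <- generate_deg_table(g, tiny_config(seed = 13L,
                                          deg = list(n_deg = 0L)))
  expect_length(deg_filter(d0$table), 0L)
})
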