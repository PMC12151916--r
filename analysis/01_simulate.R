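#!/usr/bin/env Rscript
# Stage 1 — simulate the study substrate.
#
# Builds the seeded synthetic genome (terminal TTAGGG arrays, ITS arrays
# on both sides of the 7-unit threshold, planted WE consensus copies,
# genes), 16 Hi-C runs with recurrent telomere-anchored contacts plus
# noise, the methylation beta series across the five telomere-length
# conditions, and the differential-expression table.  Everything lands
# under results/analysis/sim/ together with the truth tables used by the
# later stages to score themselves.

library(telomir)

seed <- 1L
out <- "results/analysis/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
genome <- generate_genome(cfg, out_dir = out)
hic <- generate_hic_runs(genome, cfg, out_dir = file.path(out, "hic"))
meth <- generate_methylation_series(genome, cfg, out_dir = out)
deg <- generate_deg_table(genome, cfg, out_dir = out)

message(sprintf("genome: %d chromosomes x %d bp, %d WE sites, %d genes",
                length(genome$chrom_names), cfg$chrom_length_bp,
                nrow(genome$we_sites), nrow(genome$genes)))
message(sprintf("hic: %d runs, %d planted contact sites (recurrence %d)",
                cfg$n_hic_runs, nrow(hic$truth), cfg$planted_recurrence))
message(sprintf("methylation: %d probes x %d samples, %d planted regions",
                nrow(meth$manifest), ncol(meth$beta), nrow(meth$truth)))
message(sprintf("expression: %d genes, %d planted DEGs",
                nrow(deg$table), length(deg$truth)))
message("wrote ", out)
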