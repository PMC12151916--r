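#!/usr/bin/env Rscript
# Stage 5 — subtelomeric and motif-proximity enrichment.
#
# Thresholds the expression table (FDR < 0.05, |log2FC| > 2), builds
# subtelomeric windows (here 200 kb of a 2 Mb chromosome, the same
# fraction as 10 Mb of a human arm), and tests: DEG enrichment in
# subtelomeres (exact hypergeometric), directional-DMR enrichment
# (chi-squared against window coverage), and WE-proximity enrichment of
# DEGs (2x2 chi-squared).  Run stages 01-04 first.

library(telomir)

sim <- "results/analysis/sim"
out <- "results/analysis"
span <- 2e5

deg_table <- read.table(file.path(sim, "deg_table.tsv"), header = TRUE)
genes <- read_bed(file.path(sim, "genes.bed"))
dmrs <- read.table(file.path(out, "dmrs_directional.tsv"), header = TRUE)
assoc <- read.table(file.path(out, "we_gene_assoc.tsv"), header = TRUE)
telo <- read_bed(file.path(sim, "telomere_arrays.bed"))
chrom_sizes <- setNames(
  tapply(telo$end, telo$chrom, max)[unique(telo$chrom)],
  unique(telo$chrom))

degs <- deg_filter(deg_table)
windows <- make_subtelomere_windows(chrom_sizes, span_bp = span)

gene_in <- count_in_windows(genes, windows)
deg_in <- count_in_windows(genes[toupper(genes$name) %in% degs, ],
                           windows)
deg_enr <- enrichment_test(deg_in$total, length(degs), gene_in$total,
                           nrow(genes), test = "hypergeometric")
message(sprintf("DEGs: %d/%d in subtelomeres (expected %.1f%%): hypergeometric p = %.3g",
                deg_in$total, length(degs),
                100 * deg_enr$expected_proportion, deg_enr$p_value))

dmr_in <- count_in_windows(dmrs, windows)
dmr_enr <- enrichment_test(dmr_in$total, nrow(dmrs),
                           sum(windows$end - windows$start),
                           sum(chrom_sizes), test = "chisq")
message(sprintf("DMRs: %d/%d in subtelomeres (%.1f%%; expected %.1f%%): chi-squared p = %.3g%s",
                dmr_in$total, nrow(dmrs),
                100 * dmr_enr$observed_proportion,
                100 * dmr_enr$expected_proportion, dmr_enr$p_value,
                if (dmr_enr$low_count) " [low-count]" else ""))

prox <- proximity_enrichment(degs, assoc)
message(sprintf("WE proximity of DEGs: odds ratio %.2f, chi-squared p = %.3g",
                prox$odds_ratio, prox$p_value))

res <- data.frame(
  test = c("deg_subtelomere_hypergeometric", "dmr_subtelomere_chisq",
           "deg_we_proximity_chisq"),
  observed = c(deg_enr$observed_proportion, dmr_enr$observed_proportion,
               prox$odds_ratio),
  expected = c(deg_enr$expected_proportion, dmr_enr$expected_proportion,
               1),
  p_value = c(deg_enr$p_value, dmr_enr$p_value, prox$p_value))
write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", file.path(out, "enrichment.tsv"))
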