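#!/usr/bin/env Rscript
# Stage 4 — scan for the WE consensus and associate hits.
#
# Scans the mined interaction windows and the whole genome for the 35-bp
# WE consensus (both strands, exact Hamming match), then associates
# genome-wide hits with genes (locus +/- 2 kb) and with the directional
# DMRs.  Run stages 01-03 first.

library(telomir)

sim <- "results/analysis/sim"
out <- "results/analysis"
fasta <- file.path(sim, "genome.fa")

interactions <- read_bed(file.path(out, "interactions.bed"))
genes <- read_bed(file.path(sim, "genes.bed"))
dmrs <- read.table(file.path(out, "dmrs_directional.tsv"), header = TRUE)

hits_at_interactions <- scan_motif(fasta, intervals = interactions)
write_bed(hits_at_interactions,
          file.path(out, "we_hits_interactions.bed"))

genome_hits <- scan_motif(fasta)
write_bed(genome_hits, file.path(out, "we_hits_genome.bed"))

assoc <- associate_hits(genome_hits, genes, dmrs = dmrs,
                        flank_bp = 2000L)
write.table(assoc$genes, file.path(out, "we_gene_assoc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(assoc$dmrs, file.path(out, "we_dmr_assoc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d/%d interaction windows carry the WE consensus",
                length(unique(hits_at_interactions$source_region)),
                nrow(interactions)))
message(sprintf("%d genome-wide hits; %d genes and %d DMRs WE-associated",
                nrow(genome_hits), sum(assoc$genes$we_associated),
                sum(assoc$dmrs$we_associated)))
message("wrote ", file.path(out, "we_gene_assoc.tsv"))
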