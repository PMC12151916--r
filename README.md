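# telomir

Telomeres do more than cap chromosomes: telomere length modulates the
expression and methylation of loci up to ~10 Mb away through chromatin
loops — the telomere position effect over long distances (TPE-OLD).
`telomir` is an R toolkit for the computational side of TPE-OLD
discovery, aimed at genomicists who want to mine telomere-anchored
chromatin contacts, track telomere-length-dependent methylation, and
characterize the sequence context of responsive loci. Every stage runs on
a built-in seeded simulator, so the whole pipeline is testable without
downloads.

## What it computes

**Hi-C telomere-contact mining.** A read mate is *telomeric* when its
longest run of consecutive telomere repeat units reaches 7 copies of
TTAGGG (or CCCTAA; both orientations, all six phase offsets, optional
per-unit Hamming tolerance). Reads with 1–6 tandem units are interstitial
telomeric sequence (ITS)-like and discarded, as are anchors falling in
annotated ITS arrays of ≥ 7 units. A contact is kept when exactly one
mate is telomeric and the other maps with mapq ≥ 30 outside terminal
arrays; anchors are expanded ±100 bp and only anchors recurring in ≥ 2
of the sequencing runs are emitted as interactions.

**Telomere-length-dependent methylation.** DMRs between adjacent
telomere-length conditions (12 / 10 / 8 / 6 / 4 kb) are called from probe
deltas (Δβ = shorter − longer, so "hyper" = gain upon shortening) merged
into regions and tested with a region-level t-test, then filtered at the
reporting thresholds: ≥ 7 probes, width > 50 bp, p < 0.05. The
*directional filter* keeps only regions with constant hyper- or
hypomethylation across 12v10, 10v8 and 8v6. Bisulfite amplicon matrices
(1 = methylated, 0 = unmethylated, X = misaligned) are summarized as
per-CpG means with a smoothed series.

**Subtelomeric enrichment.** Subtelomeres are operationalized as 10-Mb
windows from each chromosome end (92 ends in a diploid human karyotype).
Enrichment of a gene/region set in the windows is tested with the exact
hypergeometric upper tail, P(X ≥ k) with X ~ Hypergeom(N, K, n), or a
1-df chi-squared test of the in/out split.

**WE motif scanning.** The 35-bp "Wide Effect" consensus
`CCTCCCAAAGTGCTGGGATTACAGGCGTGAGCCAC` is matched by ungapped Hamming
scan on both strands, associated with genes (locus ± 2 kb) and DMRs, and
tested for proximity enrichment with a 2×2 chi-squared test.

**Chromosome-end clustering.** Per-end features (WE occurrences, DEG
count, gene-density-corrected DEG ratio, ITS, replication timing,
optional protein signals) are normalized to mean 1 (timing mapped to
[−1, 1]) and clustered by Ward.D2 on Manhattan distances.

Shared utilities include population doublings,
PD = ln(final / initial) / ln 2, strict DEG thresholding (FDR < 0.05,
|log2FC| > 2) and asymmetric gene-list overlap percentages.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads the previous stage's plain-text outputs under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R      # genome, Hi-C runs, beta series, DE table
Rscript analysis/02_mine_contacts.R
Rscript analysis/03_call_dmrs.R
Rscript analysis/04_scan_motif.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_cluster_ends.R
```

With the default seed the run prints, among others:

```
5 recurrent interactions; recall 1.00 / precision 1.00 vs the planted truth
directional filter kept 8 regions; recall 1.00 / precision 1.00, 0 sign-flipping decoys kept
5/5 interaction windows carry the WE consensus
DMRs: 3/8 in subtelomeres (37.5%; expected 20.0%): chi-squared p = 0.216 [low-count]
clustered 8 chromosome ends into 2 groups (sizes 6/2)
```

i.e. all five planted recurrent telomere contacts are recovered with no
false positives, the eight planted monotone DMRs survive the directional
filter while every decoy is rejected, the planted WE copies are found at
every mined interaction window, and the planted subtelomeric excess of
DMRs is visible (37.5% observed vs 20% expected; not significant at this
desk scale, as expected for n = 8).

The same stages are available programmatically:

```r
library(telomir)
cfg <- pipeline_config(sim = simulation_config(seed = 1))
res <- run_pipeline(cfg, "out")
res$summary$hic$recall       # 1
res$summary$dmr$precision    # 1
```

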