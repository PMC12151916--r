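---
title: "Methods: mining telomere-anchored interactions and telomere-length-dependent methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining telomere-anchored interactions and telomere-length-dependent methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomir)
```

`telomir` implements the computational workflow behind telomere position
effects over long distances (TPE-OLD): telomere-length-dependent
chromatin loops that modulate genes and methylation up to ~10 Mb from
chromosome ends. This vignette explains each model and procedure, its
assumptions, the parameters that matter, and the choices made where the
design was genuinely open. Every number shown is computed by the chunk
that prints it.

## The synthetic substrate

All stages are exercised on data from a seeded simulator
(`simulation_config()`, `generate_genome()`, `generate_hic_runs()`,
`generate_methylation_series()`, `generate_deg_table()`). The defaults
encode the study conditions the pipeline assumes:

* **Genome**: 4 chromosomes × 2 Mb. Real subtelomere analysis uses 10-Mb
  windows on ~100–250 Mb chromosomes; the simulated genome keeps the same
  *proportion* (200-kb windows on 2-Mb chromosomes, i.e. 10% of an arm)
  so enrichment behaves comparably at desk scale.
* **Terminal arrays**: 500 exact TTAGGG units (3 kb) at the start of each
  chromosome, the reverse-complement array at the end — the G-rich strand
  convention. Interstitial telomeric sequences (ITS) are planted both
  below (2–6 units) and at/above (7–12 units) the classification
  threshold; below-threshold arrays optionally carry per-unit mismatches
  to exercise tolerant counting.
* **Hi-C**: 16 runs, 75-bp mates. Planted contacts pair a read drawn from
  a terminal array with a read overlapping a planted WE site; each
  planted site recurs in a configurable number of runs (default all 16).
  Noise contacts pair random non-telomeric interior loci. Pairs files use
  a 7-column 4DN-style dialect plus a sequence side-file, because
  telomeric mates are unalignable and classification needs raw sequence.
* **Methylation**: five conditions (12/10/8/6/4 kb telomere length), four
  replicates. Betas are Beta-distributed with mean *m* and concentration
  50 (shape parameters `m * 50` and `(1 - m) * 50`), a simple
  overdispersion model chosen because array noise is bounded in [0, 1];
  no batch structure is simulated. Planted monotone DMRs shift the mean
  by ±0.15 per step along 12→10→8→6; their baselines are drawn so the
  whole trajectory stays inside (0.02, 0.98) and the drift plateaus at
  the 4-kb (crisis) condition, which the directional analysis excludes.
  Decoys violate exactly one filter each: six probes only, 8 probes in
  40 bp, and sign-flipping deltas.
* **Expression**: planted DEGs satisfy FDR < 0.05 and |log2FC| > 2
  strictly; all other genes fail at least one threshold. By default DEGs
  are drawn uniformly over genes, the non-enrichment regime.

What the simulator does *not* model: Hi-C distance decay and
restriction-fragment chemistry, array batch effects, probe-type bias,
CpG-density covariates of gene placement. Passing tests therefore
demonstrate correctness of the *computations* under a clean generative
model, not robustness to every artifact of real libraries.

## Hi-C mining

A read is classified by its longest run of consecutive repeat-unit
copies (`count_tandem_units()`): both orientations (TTAGGG / CCCTAA) and
all six phase offsets are evaluated, each copy allowed
`max_mismatch_per_unit` Hamming mismatches (default 0 — the consensus is
short and exact matching is the conservative default; tolerance is a
flag). The classification threshold is **7 tandem units**: reads with
1–6 units are ITS-like and never telomeric.

```{r}
classify_read(count_tandem_units(strrep("TTAGGG", 6)))
classify_read(count_tandem_units(strrep("TTAGGG", 7)))
```

`extract_telomeric_contacts()` keeps pairs with exactly one telomeric
mate whose other mate maps at mapq ≥ 30 (the paper-facing pipelines we
mirror do not state a mapping filter; 30 is the conventional
uniqueness cut, exposed as a flag) to a locus outside terminal arrays.
The ITS discard is implemented as two separately switchable rules: reads
with < 7 units are not telomeric, and anchors inside annotated ≥ 7-unit
ITS arrays are excluded so interactions are anchored to true chromosome
ends. Telomere–telomere pairs, missing sequences, low-mapq and excluded
anchors are tallied in an audit log because only survivors appear in the
output.

Anchors are expanded ±100 bp (`expand_anchor()`, the motif search
window), merged (`merge_gap_bp = 0` after expansion — the expansion
itself creates 200 bp of slack), and kept when supported by
`min_runs = 2` distinct runs. Recurrence is the noise filter: planted
contacts recur by construction, noise anchors almost never land within
200 bp of each other across runs. Emitted interaction counts are
non-increasing in `min_runs` and non-decreasing in the pad, both
property-tested.

## DMR calling and the directional filter

The caller (`call_dmrs()`) is deliberately minimal and fully specified —
the scientific content is the threshold set and the directional filter,
not the machinery of a packaged caller. Probe delta is
Δβ = mean(shorter) − mean(longer), so **hyper = gain upon shortening**.
Candidate regions are runs of probes (gap ≤ 1 kb) whose *smoothed* delta
(centered 3-probe running mean) reaches |Δβ| ≥ 0.05 with a common sign;
edges are trimmed back to probes passing the cutoff on the raw delta.
The smoothing is the one genuinely open design point: thresholding raw
per-probe deltas splits a true 10-probe region whenever a single noisy
probe dips below the cutoff (probability ≈ 0.2 per comparison at
Δβ = 0.15, concentration 50, 4 replicates), capping chain recovery near
0.86; smoothing bridges such dips exactly as bumphunter-style callers
do, while edge-trimming keeps boundaries sharp. `smooth_probes = 1`
restores the strict per-probe rule.

Region significance is a two-sample t-test on replicate-level region
means; emitted regions must have **≥ 7 probes**, **width > 50 bp**
(last minus first probe position) and **p < 0.05** (a plain cutoff; BH
correction is available but off by default, matching the reporting
convention the thresholds come from).

`filter_directional()` keeps a region from the first comparison only if
every later comparison (12v10 → 10v8 → 8v6, validated to chain in
telomere-length order) contains an overlapping region (≥ 1 bp, the
permissive default) with the same direction. The shortest condition
(4 kb) is excluded as a crisis time point.

```{r}
cfg <- simulation_config(seed = 1, n_chroms = 2, chrom_length_bp = 6e5,
                         telomere_units = 100, n_we_sites = 6,
                         n_genes = 30, n_hic_runs = 1,
                         planted_recurrence = 1,
                         n_planted_contact_sites = 3)
g <- generate_genome(cfg)
m <- generate_methylation_series(g, cfg)
sets <- list("12v10" = call_dmrs(m$beta, m$manifest, "12kb", "10kb"),
             "10v8"  = call_dmrs(m$beta, m$manifest, "10kb", "8kb"),
             "8v6"   = call_dmrs(m$beta, m$manifest, "8kb", "6kb"))
direc <- filter_directional(sets)
score_recovery(direc, m$truth[m$truth$kind == "monotone", ])[c("recall", "precision")]
```

Bisulfite amplicon matrices use the 1/0/X convention (methylated /
unmethylated / misaligned). Per-CpG mean = #1 / #non-X; the smoothed
series is a centered moving average (window 3, partial at edges) — the
published smoothing method is unspecified, so a moving average is used
as a transparent stand-in. All-X columns are flagged and excluded, never
imputed.

## Subtelomeric enrichment

Subtelomeres are 10-Mb windows from each end (`span_bp = 1e7`); a
46-chromosome diploid karyotype yields 92 ends. Chromosomes shorter
than twice the span clip at the midpoint, so windows never overlap.
Features count once, assigned to the nearer end on double overlaps
(exact tie → p side; arbitrary but deterministic). The default
membership rule is any-overlap of the full locus — the TSS-based
alternative is not used because the operational definition works on
regions, not transcription starts.

The "expected" proportion is the universe's in-window fraction. The
exact test is the hypergeometric upper tail — the standard exact test
for "observed versus expected members of a region class"; what the
figure-legend name "geometric test" denotes is not fully specified, so
the chi-squared alternative is exposed under the same interface and both
hold their nominal size:

```{r}
set.seed(1)
draws <- rhyper(2000, 200, 800, 100)
mean(vapply(draws, function(k)
  enrichment_test(k, 100, 200, 1000, "hypergeometric")$p_value, 0) < 0.05)
```

Expected chi-squared cells below 5 flag the result `low_count` but still
return it — small desk-scale sets are common and silent refusal would
hide the number the user asked for.

## WE motif scanning

The 35-bp Wide Effect consensus is matched by ungapped Hamming scan
(`scan_motif()`), both strands, default 0 mismatches; IUPAC ambiguity
codes are rejected rather than expanded. Hits associate with genes via
locus ± 2 kb and with DMRs by direct overlap; 2×2 chi-squared (no
continuity correction, so a balanced table gives statistic 0, p = 1)
tests proximity enrichment, with degenerate margins returning p = 1
flagged rather than erroring.

```{r}
nchar(WE_CONSENSUS)
hits <- scan_motif(g, intervals = g$we_sites)
table(hits$strand)
```

## Chromosome-end clustering

`build_end_table()` normalizes every non-timing feature column to mean
exactly 1 and maps replication timing affinely to [−1, 1] (earliest →
−1, latest → +1). The DEG ratio (DEG count / gene count) corrects for
gene density; zero-gene ends get ratio 0 and are flagged. Missing
values are never imputed — a column with any NA is dropped.

`cluster_ends()` applies Ward.D2 to Manhattan distances. Ward linkage on
a non-Euclidean metric is formally unconventional; the implementation is
the standard Lance–Williams update on squared dissimilarities with merge
heights reported unsquared (i.e. `stats::hclust(method = "ward.D2")`),
applied verbatim because that formulation is what the clustering is
named after — a formal application, not a claim of Ward optimality. The
merge tree is verified in the test suite against a brute-force
implementation of the Ward criterion for n ≤ 8, and planted two-group
structure separated by ~10× the within-group spread is recovered in
100/100 seeded replicates.

```{r}
tab <- build_end_table(data.frame(
  end_id = c("1p", "1q", "2p", "2q"),
  n_we = c(2, 8, 1, 9), n_deg = c(0, 3, 1, 4),
  n_genes = c(10, 12, 9, 11),
  replication_timing = c(0.2, 0.9, 0.1, 0.8)))
cluster_ends(tab, k = 2)$labels
```

## Numerical and degenerate-input policy

* Coordinates are 0-based half-open everywhere internally (BED dialect
  on disk); conversion to 1-based closed happens only at the
  IRanges/GenomicRanges boundary.
* Seeds fully determine simulator output (byte-identical files,
  property-tested); derived seeds stay below 2^31.
* Empty inputs return typed empty results (empty read → zero repeat
  call; empty contact set → empty interaction table), while *inconsistent*
  inputs error loudly (malformed pairs line with its line number,
  unsorted manifests, counts exceeding their universe, infeasible
  feature packing).
* `min_runs` above the number of runs warns and returns an empty set —
  a configuration that can never match is reported, not silently
  satisfied.

## Problem sizes

The shipped tests and the acceptance script run the simulator at
reduced scale chosen once for desk reproducibility: 2–4 chromosomes of
0.6–2 Mb, 16 Hi-C runs of up to 10,000 pairs, 50-seed DMR recovery,
2000-draw null calibrations, 100-seed clustering recovery. These sizes
keep every stage's statistical behavior measurable (binomial bounds,
type-I error bands) while completing in minutes.

## Known limitations

* Telomeric classification searches raw mate sequence; aligner
  soft-clip evidence is not used.
* The DMR caller is not a reimplementation of packaged callers
  (bumphunter/ChAMP) — no probe-type normalization, no batch
  correction; it carries the stated thresholds on clean beta matrices.
* De novo motif discovery is out of scope; the scanner consumes a given
  consensus (no PWM scoring, no indels).
* Enrichment ignores gene-density and CpG-density covariates; a
  permutation framework respecting them is future work.
* Protein-signal columns for end clustering are accepted as per-end
  numbers; computing them from raw ChIP reads is out of scope.
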