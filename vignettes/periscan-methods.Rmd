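---
title: "periscan methods: finding and characterizing intronless genes at pericentromeric repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{periscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periscan)
set_log_level("WARN")
```

## The problem

Pericentromeric heterochromatin — the repeat-rich chromatin flanking, but
not inside, centromeres — is transcriptionally silent in most normal
tissues, yet becomes transcribed in cancer cells. Intronless
protein-coding genes can hide inside these repeat arrays ("GPS" genes,
genes at pericentromeric-repeat sequences). Finding them and
characterizing their products requires chaining several routine analyses:
reading signal tracks and annotations, intersecting intervals, six-frame
ORF discovery, protein annotation, transcript-to-genome alignment for
splicing and mutation analysis, family homology, and expression scoring
against miRNA context. `periscan` packages that chain as composable,
seeded, testable functions.

Every stage can be exercised without any external download: the
synthetic-data generators build a toy multi-chromosome genome with planted
ground truth (a "truth ledger"), and the test suite checks each stage by
recovering what was planted.

## Locus scan

A candidate locus is an interval in

$$\text{H3K27ac peak} \;\cap\; \text{repeat annotation} \;\cap\;
  \text{pericentromeric window},$$

where pericentromeric windows extend `flank` bp from each centromere edge
(excluding the centromere itself, clipped to the chromosome), and peaks
are maximal runs of fold-change-over-control signal at or above
`h3k27ac_threshold`, merged across gaps narrower than `merge_gap` and
dropped below `min_width`. Each candidate carries the maximum H3K27ac and
H3K27me3 signal over its span; a locus is flagged *competent* when both
marks reach their thresholds — transcription-permissive (H3K27ac) in
pericentromeric (H3K27me3) chromatin. Competence is deliberately a flag,
not a filter: the same locus can lack a mark in one cell type and carry it
in another, so filtering would discard loci that are informative across
cell types.

Published genome-browser surveys of this kind read "strong" marks by eye;
there is no community-standard numeric cutoff. The defaults
(`h3k27ac_threshold = 2`, `h3k27me3_threshold = 2` fold change,
`min_width = 200` bp, `merge_gap = 100` bp, `flank` = 2 Mb at genome
scale) are declared choices in line with narrow-mark practice, and all are
exposed in `periscan_config()`.

## ORF discovery and protein annotation

`find_orfs()` scans all six frames. Within each stop-delimited reading
segment it reports the single ORF running from the most upstream
qualifying start codon to the bounding stop — the "maximum ORF length"
convention of the common ORF finders. The default start-codon set
{ATG, CTG, GTG, TTG} covers alternative initiation; alternative starts are
translated as initiator methionine. ORFs containing N are rejected rather
than ambiguously translated, and the default minimum length is 300 nt
(stop included), which passes typical pericentromeric ORFs while
suppressing the short chance ORFs that repeat-rich sequence produces in
abundance. The defining length identity, asserted throughout the tests,
is

$$\text{nt length} = 3\,(\text{protein length} + 1),$$

e.g. a 624-nt ORF encodes a 207-residue protein and a 263-residue protein
implies a 792-nt ORF.

Protein annotation reports, per protein: length; *approximate* molecular
weight by the average-residue-mass rule $0.110\,\mathrm{kDa} \times
\text{length}$ (the convention used in quick annotations; 207 aa
$\rightarrow$ 22.77 kDa); the exact average-mass sum as an auxiliary
column; the isoelectric point; and residues enriched at ratio
$\geq$ 1.5 over a background composition (uniform by default).

The isoelectric point solves net charge $= 0$ by bisection on pH
$\in [0, 14]$, with Henderson–Hasselbalch terms for the two termini and
the ionizable side chains (D, E, C, Y, H, K, R). Net charge is strictly
decreasing in pH, so the root exists and is unique; bisection runs to an
internal interval of $10^{-3}$ pH and tests hold it within 0.01 of a
$10^{-3}$-resolution grid search. Published pI values depend strongly on
the pKa table used and the tools behind reported values rarely state
theirs, so the table here is explicit, swappable configuration
(`emboss_pka()` by default) and no exact published pI value is treated as
a reproduction target.

## Transcripts: splicing status and mutation calling

`align_transcript()` aligns a transcript to its genomic region
(global on the transcript, local on the region) with affine gaps
(nucleotide scoring match +2, mismatch −3, gap open −5, extend −2).
Genome-side gaps of at least `intron_threshold` (20 nt) are candidate
introns; a transcript with none is *intronless*. The threshold separates
splicing from small alignment indels — real introns are rarely shorter
than ~60 nt, sequencing indels rarely longer than a few nt, so 20 nt sits
comfortably between. Alignments below `identity_floor` (70%) are rejected
as unalignable rather than interpreted.

`call_mutations()` groups substitutions within the ORF span by codon
(1-based, initiator Met = codon 1) and names them in the compact
codon-level nomenclature: `F42V` (missense), `P129P (silent)`,
`G132Stop` (stop-gain). Multiple substitutions in one codon give a single
call with the full alternative codon. Indels inside the ORF are
frameshift errors by design: the nomenclature covers substitutions only,
and silently renaming a frameshift would misstate the consequence.
Heterozygous-like double peaks are out of scope — one called base per
position is assumed. Whether a call is a de novo mutation or a
polymorphism is not decided; that requires population data.

`compare_samples()` partitions catalogues into calls shared by all
samples and calls unique to one, matching on (codon index, alternative
codon). With more than two samples, calls present in some but not all
samples belong to neither set. `truncation_consequence()` flags motif
hits at or downstream of the earliest stop-gain as lost from the
truncated product.

## Family homology

`identity_matrix()` computes pairwise percent identity from global
(Needleman–Wunsch, affine) alignments — BLOSUM62 with gap open −11 /
extend −1 for proteins. Identity is matches over aligned columns.
Pairwise alignment rather than progressive multiple alignment is a
deliberate scope decision: the family analyses here (identity-from-anchor
ladders, cladogram topology) consume pairwise identities, and an MSA
engine would add machinery without changing those outputs.

`upgma_tree()` clusters on distance $100 - \text{identity}$ with average
linkage; merge heights are $d/2$, so the tree is ultrametric by
construction. Ties are broken by merging the pair whose smallest member
label sorts first — this pinned rule is why the UPGMA step is implemented
in-package (generic clustering routines do not expose a tie-break), and
an independent average-linkage implementation serves as the oracle in
tests. Trees are returned as `ape` `phylo` objects plus Newick text.

`conserved_windows()` slides 12–13-residue windows along an anchor
sequence (the first family member by default) and scores, per window, the
fraction of other members containing a same-length substring matching at
a scaled 10-of-12 identity; windows at conservation $\geq$ 0.8 merge into
maximal spans. The exact criterion behind published "conserved 12–13
amino acid stretch" statements is never stated, so these are declared
defaults. `fpfp_scan()` reports every exact, possibly overlapping,
occurrence of the Phe-Pro-Phe-Pro motif (`FPFPFP` hits at 1 and 3).

## Expression

The expression statistic is MRSP — *maximum reads at single point* — the
highest per-base depth within a gene's ORF, taken per gene per cell line.
It is order-free and monotone under added reads. Two marginal sums follow:
the *combined score* of a gene (MRSP summed over all cell lines) and the
*GPS score* of a cell line (MRSP summed over the gene family), which
satisfy the conservation identity that both totals equal the matrix grand
total — a free invariant the tests assert.

`integrate_and_sort()` adds cumulative C19MC miRNA expression (the member
list is an input, not hard-coded) and sorts lines by it;
`select_groups()` takes the top *n* = 12 lines positive for both RNA
classes and *n* double-zero lines. Top-*n*-by-C19MC is the declared
operationalization of "positive group" — no published numeric
C19MC-positivity cutoff exists — and equal group sizes keep the
two-sample test balanced.

`differential_expression()` works on $\log_2(x+1)$ values (the pseudocount
handles the all-zero negative group), computes the group-mean difference
as log2 fold change, and takes p-values from a two-sided equal-variance
Student t-test, flagging $|\mathrm{log_2FC}| > 2$ with $p < 0.05$. Raw
p-values are the default because the screen is defined that way;
Benjamini–Hochberg adjustment is available behind `fdr = "bh"`. A gene
with zero variance in both groups gets $p = 1$ at equal means and $p = 0$
otherwise.

`ddct_fold_change()` implements comparative-Ct qPCR quantification:
$\Delta Ct$ = target − normalizer per sample, $\Delta\Delta Ct$ = mean
treated − mean control, fold change $= 2^{-\Delta\Delta Ct}$, controls
reported at 1.

## The synthetic genome and its truth ledger

`simulate_all()` chains five seeded generators; every planted fact is
recorded in a ledger that downstream tests read instead of re-deriving
expectations from data. The default scale — 3 chromosomes × 300 kb,
30 kb centromeres, 50 kb repeat flanks, four planted ORFs (624, 792, 450,
900 nt), one non-pericentromeric decoy ORF, one spliced decoy gene, 100
cell lines — runs in a couple of seconds, which is what lets the test
suite sweep a 10-seed matrix of full pipeline runs.

Design choices worth knowing:

* **Repeat blocks are tandem arrays** of a 171-bp monomer
  (alpha-satellite scale), screened so every reading frame on both
  strands hits a stop codon within one monomer; planted cassettes are
  flanked by a short stop wall carrying stops in all six frames, plus an
  in-frame stop immediately upstream of the start codon. Together these
  make planted ORFs the only above-threshold ORFs inside repeat blocks
  and pin their recovered coordinates exactly — recovery tests are
  deterministic, not probabilistic.
* **Signal**: flat-top peaks (amplitude 5, i.e. 2.5× the calling
  threshold) over each planted locus in both marks, clipped to the host
  repeat block; off-peak noise is uniform on [0, threshold/2], so
  threshold separation is guaranteed by construction rather than by
  statistical tuning. The decoy ORF receives no qualifying peak.
* **Proteins** share a planted conserved 13-mer containing FPFP and an
  S/T/Y-enriched composition; the 263-residue mutation host carries fixed
  reference residues (F13, F42, K97, P129, G132, N133, R215) so the
  default mutation catalogue — four shared calls including the G132Stop
  truncation, three unique to the second sample — reproduces its intended
  names exactly. Codons are drawn uniformly from synonymous sets, which
  cannot create internal stops.
* **Expression**: GPS MRSP values are Poisson counts with gene means
  (31, 22, 6, 4) chosen so the first two genes are the top combined
  scorers; C19MC members are uniform draws whose block ranges make the 12
  planted double-positive lines strictly the highest cumulative C19MC;
  background genes carry log2 fold changes of ±5, ±4, ±3, ±1 and 0
  between the planted groups on a log-normal depth model (sd 0.3 log2
  units, rounded to counts).
* **Coverage** profiles are a baseline of $\lfloor m/2 \rfloor$ with one
  base at the planted MRSP $m$ — the minimal shape with a well-defined
  maximum at a single point.

What the toy deliberately does **not** emulate: read-level sequencing
error, fragment-length effects, chromatin-state autocorrelation, GC bias,
overdispersed (negative-binomial) expression, population polymorphism, or
genome-scale repeat diversity. Passing the recovery suite therefore
demonstrates correctness of the pipeline's logic under its stated
assumptions, not robustness to every artifact of real ChIP-seq/RNA-seq —
on real data the thresholds above are the knobs that absorb those
artifacts.

## Numerical conventions

* Intervals live in `GRanges` (1-based, closed) throughout; BED/bedGraph
  0-based half-open coordinates are converted at the file boundary only.
  Reports and ledger coordinates are 1-based inclusive.
* Affine gap cost: a gap of length $L$ costs $|open| + |extend| \times L$
  (the convention of the underlying alignment engine; the exhaustive
  oracle in the tests uses the same).
* bedGraph records must not overlap — these are fold-change signal
  tracks, and summing overlapping records would silently fabricate
  signal; overlap is a format error.
* Determinism: every generator takes an explicit seed and restores the
  caller's RNG state; ties in sorting and clustering break
  lexicographically.
* Degenerate inputs fail loudly: empty sequences, inverted BED intervals,
  negative signal, unknown configuration keys, frameshifts inside an ORF,
  and under-filled cell-line groups are all errors, not warnings.

## Limitations

* Peak calling is threshold-based on provided tracks; calling peaks from
  aligned reads (input correction, duplicate handling) is out of scope.
* Homology is pairwise; progressive MSA, database search and bootstrap
  support are out of scope.
* The mutation caller handles substitutions only; indel nomenclature and
  chromatogram parsing are out of scope.
* MRSP inherits the units of the supplied coverage; no normalization
  across libraries is attempted.

## Worked example

```{r example, eval = FALSE}
cfg <- toy_config()
sim <- simulate_all(cfg, seed = 1)

windows <- pericentromeric_windows(sim$centromeres, cfg$flank,
                                   sim$ledger$chromosomes)
peaks <- call_peaks(sim$h3k27ac, cfg$h3k27ac_threshold,
                    cfg$min_peak_width, cfg$merge_gap)
cand <- scan_candidates(windows, sim$repeats, peaks, sim$h3k27ac,
                        sim$h3k27me3, sim$centromeres, cfg)
orfs <- orfs_in_candidates(sim$genome, cand, cfg)
annotate_protein(orfs$protein[1])
```

See the README for this example with its printed output.
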