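# periscan

Discovery and characterization of intronless protein-coding genes hiding
in pericentromeric repeat sequence ("GPS" genes), for genomics groups
studying pericentromeric transcription in cancer cells.

Pericentromeric heterochromatin — the repeat arrays flanking, but outside,
centromeres — is silent in most normal tissues but can become
transcription-competent in cancer. `periscan` turns the discovery workflow
for the genes embedded there into a reusable, seeded, tested pipeline:

* **Locus scan** — candidate loci are maximal intervals of
  *H3K27ac peak ∩ repeat annotation ∩ centromere-flanking window*, with a
  joint H3K27ac/H3K27me3 *competence* flag (transcription-permissive mark
  inside repressive pericentromeric chromatin).
* **ORF discovery and protein annotation** — six-frame search with
  alternative initiation codons ({ATG, CTG, GTG, TTG}) and the
  most-upstream-start ("maximum ORF length") convention; the length
  identity `nt = 3 × (aa + 1)` (624 nt ↔ 207 aa, 792 nt ↔ 263 aa);
  approximate molecular weight by the 110 Da/residue rule
  (207 aa → 22.77 kDa); isoelectric point by Henderson–Hasselbalch
  bisection over a swappable pKa table; residue enrichment.
* **Transcript analysis** — transcript-to-genome alignment with affine
  gaps; genome-side gaps ≥ 20 nt are candidate introns (intronless =
  none); codon-level mutation calls named `F42V`, `P129P (silent)`,
  `G132Stop`; shared/unique catalogue comparison across samples; motif
  loss by truncation.
* **Family homology** — pairwise global-alignment percent-identity
  matrices (BLOSUM62 for proteins), UPGMA cladograms (distance
  `100 − identity`, ultrametric, deterministic tie-breaks) with Newick
  output, conserved 12–13-residue window scoring, exact FPFP-motif scan.
* **Expression** — MRSP (maximum reads at single point: the highest
  per-base depth within a gene's ORF) per gene per cell line; per-gene
  *combined* and per-line *GPS* scores; integration with cumulative C19MC
  miRNA expression; selection of n = 12 double-positive and n = 12
  double-negative cell-line groups; a log2FC ± 2 / Student-t p < 0.05
  differential-expression screen on `log2(x+1)` values; ΔΔCt qPCR fold
  changes (`fold = 2^(−ΔΔCt)`).
* **Synthetic data** — a seeded toy genome (3 × 300 kb chromosomes,
  centromeres, tandem-repeat flanks, planted ORFs including a decoy and a
  spliced gene, signal tracks, mutated transcripts, coverage, a
  100-cell-line expression matrix) with a JSON truth ledger, so the whole
  pipeline is testable offline.

See `vignettes/periscan-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

```r
library(periscan)
cfg <- toy_config()
sim <- simulate_all(cfg, seed = 1)

windows <- pericentromeric_windows(sim$centromeres, cfg$flank,
                                   sim$ledger$chromosomes)
peaks <- call_peaks(sim$h3k27ac, cfg$h3k27ac_threshold,
                    cfg$min_peak_width, cfg$merge_gap)
cand <- scan_candidates(windows, sim$repeats, peaks, sim$h3k27ac,
                        sim$h3k27me3, sim$centromeres, cfg)
cand
#>   chrom  start    end distance_to_centromere h3k27ac_max h3k27me3_max in_repeat competent
#> 1  chr1 128651 129700                   5300       5.780        5.004      TRUE      TRUE
#> 2  chr2 206451 207700                  41450       5.704        5.212      TRUE      TRUE
#> 3  chr3  93001  93900                  41100       5.221        5.204      TRUE      TRUE
#> 4  chr1 179651 181000                  14650       5.087        5.667      TRUE      TRUE
```

Four candidate loci, all inside repeat blocks within 50 kb of a
centromere, all carrying both marks (`competent`). ORF discovery inside
the candidates, and annotation of the 624-nt ORF's protein:

```r
orfs <- orfs_in_candidates(sim$genome, cand, cfg)
head(orfs[, c("chrom", "start", "end", "strand", "nt_length", "start_codon")], 4)
#>   chrom  start    end strand nt_length start_codon
#> 1  chr1 179870 180769      -       900         GTG
#> 2  chr2 206670 207461      -       792         ATG
#> 3  chr1 128875 129498      +       624         ATG
#> 4  chr3  93244  93693      +       450         ATG

annotate_protein(orfs$protein[orfs$nt_length == 624][1])
#>   length_aa approx_mw_kda exact_mw_kda  pI enriched_residues
#> 1       207         22.77        24.23 7.8             Y,T,S
```

The 624-nt ORF yields a 207-residue protein (624/3 − 1); the reported
approximate weight is the 110 Da/residue convention (22.77 kDa), next to
the exact average-mass sum. Mutation analysis of one transcript against
its genomic reference:

```r
## coding-strand genomic reference for the lineB GPS2 transcript
r <- subset(sim$ledger$transcript_regions, sample == "lineB" & gene == "GPS2")
region <- as.character(Biostrings::reverseComplement(  # GPS2 is minus-strand
  Biostrings::subseq(sim$genome[[r$chrom]], r$region_start, r$region_end)))
aln <- align_transcript(sim$transcripts[["lineB|GPS2"]], region, cfg)
aln
#> transcript_alignment 'lineB|GPS2': identity 99.2%, intronless (0 candidate introns)
call_mutations(aln, list(start = 61, end = 852, gene = "GPS2"))
#>   gene codon_index ref_codon alt_codon ref_aa alt_aa           name    mclass
#> 1 GPS2          13       TTC       GTC      F      V           F13V  missense
#> 2 GPS2          42       TTT       GTT      F      V           F42V  missense
#> 3 GPS2          97       AAA       AGA      K      R           K97R  missense
#> 4 GPS2         129       CCA       CCG      P      P P129P (silent)    silent
#> 5 GPS2         132       GGA       TGA      G      *       G132Stop stop-gain
#> 6 GPS2         133       AAC       AAA      N      K          N133K  missense
#> 7 GPS2         215       CGT       CGC      R      R       R215R (silent) silent
```

The transcript is intronless (no genome-side gap ≥ 20 nt) and carries
silent, missense and one truncating stop-gain call (`G132Stop`: GGA→TGA
at codon 132, which removes everything downstream — including the FPFP
motif — from the product). Group selection and the expression screen:

```r
gs <- sapply(colnames(sim$genes), function(l)
  gps_score(sim$genes, l, sim$ledger$expression$gps_genes))
tab <- integrate_and_sort(gs, sim$mirna, sim$c19mc_members)
grp <- select_groups(tab, 12)
de <- differential_expression(sim$genes, grp)
head(de[de$significant_up | de$significant_down, ], 5)
#>    gene log2fc  p_value significant_up significant_down
#> 1  GPS1   4.82 4.75e-29           TRUE            FALSE
#> 2  GPS2   4.48 2.86e-26           TRUE            FALSE
#> 3  GPS3   2.70 1.71e-11           TRUE            FALSE
#> 4  GPS4   2.49 2.16e-12           TRUE            FALSE
#> 5 BG001   5.12 2.21e-25           TRUE            FALSE
```

The GPS genes themselves come out strongly up in the
C19MC-positive/GPS-positive group, alongside the background genes planted
with large fold changes.

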