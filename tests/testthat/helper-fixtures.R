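## Shared fixtures. The default toy simulation is memoized so multiple test
## files can reuse it without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

sim_fixture <- function(seed = 1L, config = toy_config()) {
  key <- paste0("sim", seed)
  if (!exists(key, envir = .fixture_cache))
    assign(key, simulate_all(config, seed = seed), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## run the locus scan on a simulation, returning the candidate table
scan_fixture <- function(sim, config = toy_config()) {
  windows <- pericentromeric_windows(sim$centromeres, config$flank,
                                     sim$ledger$chromosomes)
  peaks <- call_peaks(sim$h3k27ac, config$h3k27ac_threshold,
                      config$min_peak_width, config$merge_gap)
  scan_candidates(windows, sim$repeats, peaks, sim$h3k27ac, sim$h3k27me3,
                  sim$centromeres, config)
}

## coding-strand genomic region and ORF span for one (sample, gene)
## transcript, straight from the ledger
transcript_reference <- function(sim, sample, gene) {
  reg <- sim$ledger$transcript_regions
  r <- reg[reg$sample == sample & reg$gene == gene, , drop = FALSE]
  stopifnot(nrow(r) == 1)
  region <- as.character(Biostrings::subseq(sim$genome[[r$chrom]],
                                            r$region_start, r$region_end))
  if (r$strand == "-")
    region <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(region)))
  orf <- sim$ledger$orfs[sim$ledger$orfs$gene == gene, , drop = FALSE]
  list(region = region,
       orf = list(start = r$orf_offset,
                  end = r$orf_offset + orf$nt_length - 1L,
                  gene = gene))
}

## per-line GPS scores of a simulation's gene matrix
gps_scores_fixture <- function(sim) {
  genes <- sim$ledger$expression$gps_genes
  vapply(colnames(sim$genes), function(l) gps_score(sim$genes, l, genes),
         numeric(1))
}

suppressMessages(set_log_level("WARN"))
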