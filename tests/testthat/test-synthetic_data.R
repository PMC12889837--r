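test_that("generation is byte-identical under a fixed seed", {
  cfg <- toy_config()
  g1 <- generate_genome(cfg, seed = 7)
  g2 <- generate_genome(cfg, seed = 7)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$ledger$orfs, g2$ledger$orfs)
  g3 <- generate_genome(cfg, seed = 8)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("planted ORFs satisfy the ORF invariants and the 624/207 arithmetic", {
  sim <- sim_fixture(1)
  orfs <- sim$ledger$orfs
  for (i in seq_len(nrow(orfs))) {
    ## translates cleanly: start codon, terminal stop, no internal stop
    prot <- translate_orf(orfs$nt[i])
    expect_identical(prot, orfs$protein[i])
    expect_identical(orfs$nt_length[i], 3L * (nchar(prot) + 1L))
    ## recoverable from the genome at exactly the ledger coordinates
    g <- as.character(Biostrings::subseq(sim$genome[[orfs$chrom[i]]],
                                         orfs$start[i], orfs$end[i]))
    if (orfs$strand[i] == "-")
      g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    expect_identical(g, orfs$nt[i])
  }
  first <- orfs[1, ]
  expect_identical(first$nt_length, 624L)
  expect_identical(nchar(first$protein), 207L)
})

test_that("planted peaks sit inside repeat blocks within the flank", {
  sim <- sim_fixture(1)
  cfg <- toy_config()
  pk <- sim$ledger$planted_peaks
  reps <- sim$ledger$repeats
  cens <- sim$ledger$centromeres
  for (i in seq_len(nrow(pk))) {
    host <- reps[reps$chrom == pk$chrom[i] & reps$start <= pk$start[i] &
                   reps$end >= pk$end[i], ]
    expect_identical(nrow(host), 1L)
    cen <- cens[cens$chrom == pk$chrom[i], ]
    dist <- max(cen$start - pk$end[i], pk$start[i] - cen$end, 0)
    expect_lte(dist, cfg$flank)
    expect_gte(pk$amplitude[i], cfg$h3k27ac_threshold)
  }
  perc <- sim$ledger$orfs$gene[sim$ledger$orfs$pericentromeric]
  expect_setequal(unique(pk$gene), perc)
})

test_that("noise-free tracks are exactly zero off peak", {
  cfg <- toy_config(signal_noise = FALSE)
  g <- generate_genome(cfg, seed = 3)
  sig <- generate_signal_tracks(g, cfg, seed = 4)
  pk <- sig$ledger$planted_peaks
  ac <- sig$h3k27ac
  on_peak <- rep(FALSE, length(ac))
  ac_df <- granges_to_df(ac)
  for (i in which(pk$mark == "h3k27ac"))
    on_peak <- on_peak | (ac_df$chrom == pk$chrom[i] &
                            ac_df$start >= pk$start[i] & ac_df$end <= pk$end[i])
  expect_true(all(ac$score[!on_peak] == 0))
  expect_true(all(ac$score[on_peak] == cfg$peak_amplitude))
})

test_that("mutation ledger carries the expected catalogue; unmutated transcripts copy the genome", {
  sim <- sim_fixture(1)
  mut <- sim$ledger$planted_mutations
  expect_true(any(grepl("^[A-Z][0-9]+Stop$", mut$name)))
  expect_true("G132Stop" %in% mut$name)
  expect_setequal(unique(mut$mclass), c("missense", "silent", "stop-gain"))
  ## shared mutations present in both samples, unique in exactly one
  shared_names <- unique(mut$name[mut$shared])
  for (nm in shared_names)
    expect_identical(sort(unique(mut$sample[mut$name == nm])),
                     sort(unique(mut$sample)))
  uniq_names <- unique(mut$name[!mut$shared])
  for (nm in uniq_names)
    expect_length(unique(mut$sample[mut$name == nm]), 1L)

  ## with no planted mutations the transcript equals the genomic sequence
  cfg <- toy_config(plant_mutations = FALSE, transcript_flank = 0L)
  g <- generate_genome(cfg, seed = 5)
  tx <- generate_transcripts(g, cfg, seed = 6)
  orfs <- g$ledger$orfs[g$ledger$orfs$pericentromeric, ]
  id <- paste(cfg$transcript_samples[1], orfs$gene[1], sep = "|")
  expect_identical(as.character(tx$transcripts[[id]]), orfs$nt[1])
})

test_that("expression matrix plants recoverable groups and DE truth", {
  sim <- sim_fixture(1)
  truth <- sim$ledger$expression
  expect_length(truth$groups$positive, 12L)
  expect_length(truth$groups$negative, 12L)
  ## group definitions hold in the generated data
  c19 <- truth$c19mc_cumulative
  gps <- colSums(sim$genes[truth$gps_genes, ])
  expect_true(all(c19[truth$groups$positive] > 0))
  expect_true(all(gps[truth$groups$positive] > 0))
  expect_true(all(c19[truth$groups$negative] == 0))
  expect_true(all(gps[truth$groups$negative] == 0))
  ## planted positives carry the highest cumulative C19MC of all lines
  others <- setdiff(names(c19), truth$groups$positive)
  expect_gt(min(c19[truth$groups$positive]), max(c19[others]))
  ## log2FC = 4 genes are DE truth; log2FC = 1 genes are not
  bt <- truth$background_truth
  expect_true(all(bt$gene[abs(bt$planted_log2fc) == 4] %in% truth$de_truth))
  expect_false(any(bt$gene[abs(bt$planted_log2fc) == 1] %in% truth$de_truth))
})

test_that("coverage tracks reproduce the MRSP truth", {
  sim <- sim_fixture(1)
  truth <- sim$ledger$expression$mrsp
  orfs <- sim$ledger$orfs[match(rownames(truth), sim$ledger$orfs$gene), ]
  some_lines <- colnames(truth)[c(1, 25, 50, 100)]
  for (ln in some_lines) {
    for (i in seq_len(nrow(orfs))) {
      profile <- coverage_profile(sim$coverage[[ln]],
                                  GenomicRanges::GRanges(orfs$chrom[i],
                                    IRanges::IRanges(orfs$start[i], orfs$end[i])))
      expect_identical(length(profile), orfs$nt_length[i])
      expect_equal(max(profile), truth[i, ln])
    }
  }
})

test_that("generator preconditions are enforced as config errors", {
  expect_error(generate_genome(toy_config(n_chromosomes = 1L)), "config error")
  expect_error(generate_genome(toy_config(chrom_length = 100000L)), "config error")
  expect_error(generate_genome(toy_config(planted_orf_nt = integer(0))), "config error")
  ## ORF too long for its host repeat block
  expect_error(generate_genome(toy_config(planted_orf_nt = c(60000L))), "config error")
  ## mutation catalogue beyond a short host protein
  cfg <- toy_config(planted_orf_nt = c(624L, 300L))
  g <- generate_genome(cfg, seed = 2)
  expect_error(generate_transcripts(g, cfg, seed = 3),
               "beyond protein length")
  ## too few cell lines for the 12+12 design
  sim <- sim_fixture(1)
  expect_error(generate_expression_matrix(sim$ledger, toy_config(n_cell_lines = 20L)),
               "config error")
})
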