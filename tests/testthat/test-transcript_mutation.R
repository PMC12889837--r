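## small constructed reference: 60-nt flank + ORF + 60-nt flank
make_region <- function(orf_codons, flank = 60L) {
  orf <- paste0("ATG", paste(orf_codons, collapse = ""), "TAA")
  list(region = paste0(random_dna_str(flank), orf, random_dna_str(flank)),
       orf = list(start = flank + 1L, end = flank + nchar(orf), gene = "g"),
       orf_nt = orf)
}

test_that("an exact genomic substring is intronless at 100% identity", {
  set.seed(7)
  region <- random_dna_str(1200)
  tx <- substr(region, 101, 1000)
  aln <- align_transcript(tx, region)
  expect_equal(aln$identity_pct, 100)
  expect_true(aln$intronless)
  expect_identical(nrow(aln$gaps_in_genome), 0L)
  expect_identical(aln$subject_start, 101L)
})

test_that("a spliced transcript yields one candidate intron at the planted gap", {
  set.seed(8)
  exon1 <- random_dna_str(200); intron <- random_dna_str(100)
  exon2 <- random_dna_str(200)
  region <- paste0(exon1, intron, exon2)
  aln <- align_transcript(paste0(exon1, exon2), region)
  expect_false(aln$intronless)
  expect_identical(nrow(aln$gaps_in_genome), 1L)
  expect_identical(aln$gaps_in_genome$width, 100L)
  expect_identical(aln$gaps_in_genome$start, 201L)
  expect_identical(aln$gaps_in_genome$end, 300L)

  ## synthetic spliced decoy recovered at the ledger coordinates
  sim <- sim_fixture(1)
  sp <- sim$ledger$spliced
  fl <- toy_config()$transcript_flank
  genomic <- as.character(Biostrings::subseq(sim$genome[[sp$chrom]],
                                             sp$exon1_start - fl,
                                             sp$exon2_end + fl))
  tx_id <- paste(toy_config()$transcript_samples[1], sp$gene, sep = "|")
  aln <- align_transcript(sim$transcripts[[tx_id]], genomic)
  expect_false(aln$intronless)
  offset <- sp$exon1_start - fl - 1L
  expect_identical(aln$gaps_in_genome$start + offset, sp$intron_start)
  expect_identical(aln$gaps_in_genome$end + offset, sp$intron_end)

  ## dissimilar sequences fail the identity floor
  expect_error(align_transcript(random_dna_str(300), random_dna_str(2000)),
               "no confident alignment")
})

test_that("substitutions are called with codon-level nomenclature", {
  set.seed(9)
  codons <- rep("AAA", 60)
  codons[42] <- "TTT"; codons[29] <- "CCA"; codons[32] <- "GGA"
  mk <- make_region(codons[-1])  # codon 1 is the ATG; codon c = codons[c]
  tx <- mk$region
  ## F42V (codon 42 = codons[41] after the start): TTT -> GTT
  p <- mk$orf$start + 41L * 3L
  substr(tx, p, p) <- "G"
  ## P129P-style silent at codon 29: CCA -> CCG
  p <- mk$orf$start + 28L * 3L + 2L
  substr(tx, p, p) <- "G"
  ## stop-gain at codon 32: GGA -> TGA
  p <- mk$orf$start + 31L * 3L
  substr(tx, p, p) <- "T"
  calls <- call_mutations(align_transcript(tx, mk$region), mk$orf)
  expect_identical(calls$name, c("P29P (silent)", "G32Stop", "F42V"))
  expect_identical(calls$mclass, c("silent", "stop-gain", "missense"))
  expect_identical(calls$codon_index, c(29L, 32L, 42L))
  ## names regenerate from fields
  expect_identical(format_mutation_name(calls$ref_aa, calls$codon_index,
                                        calls$alt_aa), calls$name)
  ## the truncated product ends right before the premature stop
  mut_orf <- substr(tx, mk$orf$start, mk$orf$end)
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(mut_orf))), "")[[1]]
  expect_identical(which(aa == "*")[1] - 1L,
                   calls$codon_index[calls$mclass == "stop-gain"] - 1L)
})

test_that("two substitutions in one codon give a single codon-level call", {
  mk <- make_region(rep("GCT", 50))
  tx <- mk$region
  p <- mk$orf$start + 3L  # codon 2: GCT -> TTT
  substr(tx, p, p + 2L) <- "TTT"
  calls <- call_mutations(align_transcript(tx, mk$region), mk$orf)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$ref_codon, "GCT")
  expect_identical(calls$alt_codon, "TTT")
  expect_identical(calls$name, "A2F")
})

test_that("indels inside the ORF are frameshift errors", {
  mk <- make_region(rep("GCT", 60))
  p <- mk$orf$start + 30L
  deleted <- paste0(substr(mk$region, 1, p - 1), substr(mk$region, p + 1,
                                                        nchar(mk$region)))
  expect_error(call_mutations(align_transcript(deleted, mk$region), mk$orf),
               "frameshift")
  inserted <- paste0(substr(mk$region, 1, p), "ACGT",
                     substr(mk$region, p + 1, nchar(mk$region)))
  expect_error(call_mutations(align_transcript(inserted, mk$region), mk$orf),
               "frameshift")
  ## an intron-sized gap over the ORF violates the intronless precondition
  spliced <- paste0(substr(mk$region, 1, p - 1),
                    substr(mk$region, p + 40, nchar(mk$region)))
  expect_error(call_mutations(align_transcript(spliced, mk$region), mk$orf),
               "intronless")
})

test_that("planted mutations are recovered exactly, per sample", {
  sim <- sim_fixture(1)
  cfg <- toy_config()
  mut <- sim$ledger$planted_mutations
  host <- unique(mut$gene)
  calls_by_sample <- list()
  for (sm in cfg$transcript_samples) {
    ref <- transcript_reference(sim, sm, host)
    tx <- sim$transcripts[[paste(sm, host, sep = "|")]]
    aln <- align_transcript(tx, ref$region, cfg, transcript_id = sm)
    expect_true(aln$intronless)
    calls <- call_mutations(aln, ref$orf)
    want <- mut[mut$sample == sm, ]
    want <- want[order(want$codon_index), ]
    expect_identical(calls$codon_index, want$codon_index)
    expect_identical(calls$ref_codon, want$ref_codon)
    expect_identical(calls$alt_codon, want$alt_codon)
    expect_identical(calls$name, want$name)
    expect_identical(calls$mclass, want$mclass)
    calls_by_sample[[sm]] <- calls
  }
  ## shared/unique partition matches the planted design
  cmp <- compare_samples(calls_by_sample)
  want_shared <- sort(unique(mut$name[mut$shared]))
  expect_identical(sort(cmp$shared$name), want_shared)
  uniq_all <- do.call(rbind, cmp$unique_per_sample)
  expect_identical(sort(uniq_all$name), sort(unique(mut$name[!mut$shared])))
  expect_true("G132Stop" %in% cmp$shared$name)
})

test_that("catalogue comparison handles identical, disjoint and mixed sets", {
  a <- data.frame(gene = "g", codon_index = c(5L, 9L), ref_codon = c("AAA", "CCC"),
                  alt_codon = c("AGA", "CCG"), ref_aa = c("K", "P"),
                  alt_aa = c("R", "P"), name = c("K5R", "P9P (silent)"),
                  mclass = c("missense", "silent"), stringsAsFactors = FALSE)
  b <- a
  cmp <- compare_samples(list(s1 = a, s2 = b))
  expect_identical(nrow(cmp$shared), 2L)
  expect_identical(nrow(cmp$unique_per_sample$s1), 0L)

  b2 <- a; b2$codon_index <- c(6L, 10L)
  cmp <- compare_samples(list(s1 = a, s2 = b2))
  expect_identical(nrow(cmp$shared), 0L)
  expect_identical(nrow(cmp$unique_per_sample$s1), 2L)
  expect_identical(nrow(cmp$unique_per_sample$s2), 2L)

  b3 <- a; b3$gene <- "other"
  expect_error(compare_samples(list(s1 = a, s2 = b3)), "different genes")
  expect_error(compare_samples(list(a)), "two samples")
})

test_that("truncation flags downstream motif hits as lost", {
  calls <- data.frame(gene = "g", codon_index = c(50L, 132L),
                      ref_codon = c("TTT", "GGA"), alt_codon = c("GTT", "TGA"),
                      ref_aa = c("F", "G"), alt_aa = c("V", "*"),
                      name = c("F50V", "G132Stop"),
                      mclass = c("missense", "stop-gain"),
                      stringsAsFactors = FALSE)
  hits <- data.frame(seq_id = "p", start = c(50L, 150L), window = "FPFP")
  out <- truncation_consequence(calls, hits)
  expect_identical(out$lost_by_truncation, c(FALSE, TRUE))
  out2 <- truncation_consequence(calls[1, ], hits)
  expect_false(any(out2$lost_by_truncation))
})
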