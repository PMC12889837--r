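gr1 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

test_that("pericentromeric windows flank but never overlap the centromere", {
  ## centromere [100,200) 0-based = [101,200]; flank 50 -> [51,100], [201,250]
  win <- pericentromeric_windows(gr1("chr1", 101, 200), 50,
                                 c(chr1 = 1000L))
  expect_length(win, 2)
  expect_identical(GenomicRanges::start(win), c(51L, 201L))
  expect_identical(GenomicRanges::end(win), c(100L, 250L))

  ## centromere at the chromosome start: single right-hand window
  win <- pericentromeric_windows(gr1("chr1", 1, 100), 100, c(chr1 = 1000L))
  expect_length(win, 1)
  expect_identical(GenomicRanges::start(win), 101L)
  expect_identical(GenomicRanges::end(win), 200L)

  ## clamped at both chromosome ends
  win <- pericentromeric_windows(gr1("chr1", 31, 70), 50, c(chr1 = 100L))
  expect_identical(GenomicRanges::start(win), c(1L, 71L))
  expect_identical(GenomicRanges::end(win), c(30L, 100L))

  expect_warning(
    pericentromeric_windows(gr1("chr1", 101, 200), 50,
                            c(chr1 = 1000L, chr2 = 1000L)),
    "chr2")

  set.seed(11)
  for (rep in 1:20) {
    cs <- sample(1:5000, 1); cw <- sample(10:500, 1)
    cen <- gr1("c", cs, cs + cw)
    win <- suppressWarnings(pericentromeric_windows(cen, sample(10:2000, 1),
                                                    c(c = 6000L)))
    expect_length(interval_intersect(win, cen), 0)
  }
})

test_that("peak calling thresholds, merges and width-filters runs", {
  cfg <- toy_config()
  flat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1, 951, 50),
                                                          seq(50, 1000, 50)),
                                 score = 1.99)
  expect_length(call_peaks(flat, 2, 200, 100), 0)

  block <- flat
  block$score[5:14] <- 4  # one 500-bp block at 2x threshold
  pk <- call_peaks(block, 2, 200, 100)
  expect_length(pk, 1)
  expect_identical(GenomicRanges::start(pk), 201L)
  expect_identical(GenomicRanges::end(pk), 700L)

  ## two runs separated by a 50-bp gap merge at merge_gap 100
  split2 <- flat
  split2$score[c(1:4, 6:10)] <- 4
  expect_length(call_peaks(split2, 2, 200, 100), 1)
  expect_length(call_peaks(split2, 2, 200, 10), 2)

  ## runs below min_width are dropped
  narrow <- flat
  narrow$score[5] <- 4
  expect_length(call_peaks(narrow, 2, 200, 100), 0)
  expect_length(call_peaks(narrow, 2, 50, 100), 1)
})

test_that("scan recovers planted loci and never the decoy", {
  cfg <- toy_config()
  sim <- sim_fixture(1)
  cand <- scan_fixture(sim, cfg)
  planted <- sim$ledger$orfs[sim$ledger$orfs$pericentromeric, ]
  expect_identical(nrow(cand), nrow(planted))
  ## every planted locus is contained in exactly one candidate
  for (i in seq_len(nrow(planted))) {
    hit <- cand$chrom == planted$chrom[i] & cand$start <= planted$start[i] &
      cand$end >= planted$end[i]
    expect_identical(sum(hit), 1L)
  }
  decoy <- sim$ledger$orfs[sim$ledger$orfs$gene == "decoy", ]
  expect_false(any(cand$chrom == decoy$chrom & cand$start <= decoy$end &
                     cand$end >= decoy$start))
  ## emitted candidates satisfy the three-way membership by re-intersection
  cand_gr <- GenomicRanges::GRanges(cand$chrom,
                                    IRanges::IRanges(cand$start, cand$end))
  win <- pericentromeric_windows(sim$centromeres, cfg$flank,
                                 sim$ledger$chromosomes)
  inside <- interval_intersect(interval_intersect(cand_gr, sim$repeats), win)
  expect_equal(sum(GenomicRanges::width(inside)),
               sum(cand$end - cand$start + 1))
  expect_true(all(cand$competent))
  expect_true(all(diff(cand$h3k27ac_max) <= 0))
})

test_that("competence is a flag, not a filter, and thresholds are monotone", {
  sim <- sim_fixture(1)
  cfg <- toy_config()
  win <- pericentromeric_windows(sim$centromeres, cfg$flank,
                                 sim$ledger$chromosomes)
  pk <- call_peaks(sim$h3k27ac, cfg$h3k27ac_threshold, cfg$min_peak_width,
                   cfg$merge_gap)
  strict <- toy_config(h3k27me3_threshold = Inf)
  cand <- scan_candidates(win, sim$repeats, pk, sim$h3k27ac, sim$h3k27me3,
                          sim$centromeres, strict)
  expect_gt(nrow(cand), 0)
  expect_false(any(cand$competent))

  ## raising the H3K27ac threshold never adds candidates
  base <- scan_fixture(sim, cfg)
  for (thr in c(3, 5, 7)) {
    pk2 <- call_peaks(sim$h3k27ac, thr, cfg$min_peak_width, cfg$merge_gap)
    cand2 <- scan_candidates(win, sim$repeats, pk2, sim$h3k27ac, sim$h3k27me3,
                             sim$centromeres, cfg)
    expect_lte(nrow(cand2), nrow(base))
    if (nrow(cand2))
      expect_true(all(paste(cand2$chrom, cand2$start) %in%
                        paste(base$chrom, base$start)))
  }
  ## threshold above every amplitude: no candidates
  pk3 <- call_peaks(sim$h3k27ac, 100, cfg$min_peak_width, cfg$merge_gap)
  expect_identical(nrow(scan_candidates(win, sim$repeats, pk3, sim$h3k27ac,
                                        sim$h3k27me3, sim$centromeres, cfg)), 0L)
})

test_that("a peak inside the centromere is not a candidate", {
  cfg <- toy_config()
  cen <- gr1("chr1", 1001, 2000)
  win <- pericentromeric_windows(cen, 500, c(chr1 = 5000L))
  reps <- gr1("chr1", c(501, 2001), c(1000, 2500))
  track <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1, 4951, 50), seq(50, 5000, 50)),
                                  score = 0)
  track$score[GenomicRanges::start(track) >= 1201 &
                GenomicRanges::end(track) <= 1800] <- 5  # centromeric peak
  pk <- call_peaks(track, 2, 200, 100)
  expect_length(pk, 1)
  cand <- scan_candidates(win, reps, pk, track, track, cen, cfg)
  expect_identical(nrow(cand), 0L)
})
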