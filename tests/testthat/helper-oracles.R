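## Independent oracles used by the property and equivalence tests. Each is
## a deliberately naive implementation kept free of the package's own code
## paths.

## per-base membership intersection of two interval data.frames
## (chrom, start, end; 1-based closed)
oracle_intersect <- function(a, b, max_pos = 200L) {
  out <- list()
  for (chrom in union(a$chrom, b$chrom)) {
    in_a <- rep(FALSE, max_pos)
    in_b <- rep(FALSE, max_pos)
    for (i in which(a$chrom == chrom)) in_a[a$start[i]:a$end[i]] <- TRUE
    for (i in which(b$chrom == chrom)) in_b[b$start[i]:b$end[i]] <- TRUE
    both <- in_a & in_b
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      out[[length(out) + 1L]] <- data.frame(chrom = chrom,
                                            start = starts[k], end = ends[k])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

## brute-force ORF enumeration: every (start codon, stop codon) pair in all
## six frames, no stop strictly between, longest ORF per stop (most
## upstream start); min length applied; ORFs spanning N dropped
oracle_find_orfs <- function(seq, min_len, starts = c("ATG", "CTG", "GTG", "TTG")) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      n <- (L - frame) %/% 3
      if (n < 2) next
      pos <- frame + 1L + 3L * (seq_len(n) - 1L)
      codons <- substring(s, pos, pos + 2L)
      start_idx <- which(codons %in% starts)
      stop_idx <- which(codons %in% stops)
      if (!length(start_idx) || !length(stop_idx)) next
      pairs <- expand.grid(a = start_idx, z = stop_idx)
      pairs <- pairs[pairs$z > pairs$a, , drop = FALSE]
      if (!nrow(pairs)) next
      ## no stop codon strictly between a and z
      clean <- vapply(seq_len(nrow(pairs)), function(i) {
        a <- pairs$a[i]; z <- pairs$z[i]
        if (z == a + 1L) TRUE else !any(codons[(a + 1L):(z - 1L)] %in% stops)
      }, logical(1))
      pairs <- pairs[clean, , drop = FALSE]
      if (!nrow(pairs)) next
      ## most upstream start per stop
      best <- stats::aggregate(a ~ z, data = pairs, FUN = min)
      for (i in seq_len(nrow(best))) {
        a <- best$a[i]; z <- best$z[i]
        lo <- pos[a]; hi <- pos[z] + 2L
        nt_len <- hi - lo + 1L
        if (nt_len < min_len) next
        if (grepl("N", substr(s, lo, hi), fixed = TRUE)) next
        g1 <- if (strand == "+") lo else L - hi + 1L
        g2 <- if (strand == "+") hi else L - lo + 1L
        rows[[length(rows) + 1L]] <- data.frame(start = g1, end = g2,
                                                strand = strand,
                                                nt_length = nt_len)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), nt_length = integer(0)))
  df <- do.call(rbind, rows)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

## exhaustive global alignment score with affine gaps (gap of length k
## costs open + extend * k, end gaps penalized); recursion over all paths
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               open = 5, extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      sub <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, sub + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(av)) {  # gap in b
      cost <- -extend - if (last != "GB") open else 0
      best <- max(best, cost + rec(i + 1L, j, "GB"))
    }
    if (j <= length(bv)) {  # gap in a
      cost <- -extend - if (last != "GA") open else 0
      best <- max(best, cost + rec(i, j + 1L, "GA"))
    }
    best
  }
  rec(1L, 1L, "M")
}

## grid-search isoelectric point at 0.001 pH resolution (EMBOSS pKa)
oracle_pi_grid <- function(protein, pka = emboss_pka()) {
  aa <- strsplit(toupper(protein), "")[[1]]
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(aa == a), numeric(1))
  grid <- seq(0, 14, by = 0.001)
  charge <- vapply(grid, function(pH) {
    pos <- 1 / (1 + 10^(pH - pka$nterm)) +
      sum(counts[c("K", "R", "H")] / (1 + 10^(pH - pka$side[c("K", "R", "H")])))
    neg <- 1 / (1 + 10^(pka$cterm - pH)) +
      sum(counts[c("D", "E", "C", "Y")] /
            (1 + 10^(pka$side[c("D", "E", "C", "Y")] - pH)))
    pos - neg
  }, numeric(1))
  grid[which.min(abs(charge))]
}

## naive quadratic substring scan
oracle_substring_positions <- function(s, motif) {
  n <- nchar(s); w <- nchar(motif)
  if (n < w) return(integer(0))
  which(vapply(seq_len(n - w + 1L),
               function(i) substr(s, i, i + w - 1L) == motif, logical(1)))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "*"),
               n, replace = TRUE), collapse = "")
}
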