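## Synthetic toy genome with recorded ground truth ("truth ledger"):
## centromeres with repeat flanks, intronless ORFs planted inside the
## pericentromeric repeats (plus a non-pericentromeric decoy and a spliced
## decoy gene), histone-mark signal peaks over the planted loci, mutated
## transcripts, per-base coverage, and a 100-cell-line expression matrix
## with a C19MC-high/GPS-high block and a double-negative block.
##
## Repeat blocks are tandem arrays of a 171-bp monomer (alpha-satellite
## scale) screened so that every reading frame on both strands hits a stop
## codon within one monomer; planted cassettes are flanked by a short
## "stop wall" carrying stops in all six frames. Together these guarantee
## that the planted ORFs are the only ORFs above the minimum length inside
## the repeat blocks, so ORF recovery is exact by construction.

.STOP_WALL <- "TTAATTAATTAA"  # own reverse complement; stop in all 6 frames
.MONOMER_NT <- 171L           # divisible by 3: reading frames are periodic

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## synonymous codon sets, stops excluded
.syn_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab[["*"]] <<- NULL
    }
    tab
  }
})

## a repeat monomer whose tandem array has a stop codon in every frame on
## both strands (so no ORF >= 2 monomers can live in a repeat block)
make_repeat_monomer <- function() {
  syn <- .syn_codons()
  repeat {
    mono <- random_dna(.MONOMER_NT)
    m2 <- paste0(mono, mono)
    ok <- TRUE
    for (s in c(m2, revcomp(m2))) {
      for (f in 0:2) {
        pos <- f + 1L + 3L * (0:(.MONOMER_NT %/% 3 - 1L))
        if (!any(substring(s, pos, pos + 2L) %in% .STOP_CODONS)) ok <- FALSE
      }
    }
    if (ok) return(mono)
  }
}

## protein with an S/T/Y-enriched composition, fixed residues, and the
## family's conserved motif planted at motif_pos
make_protein <- function(len_aa, motif, motif_pos, fixed = NULL) {
  aas <- setdiff(names(.syn_codons()), "*")
  probs <- stats::setNames(rep(0.66 / 17, length(aas)), aas)
  probs[c("S", "T", "Y")] <- c(0.12, 0.12, 0.10)
  aa <- sample(aas, len_aa, replace = TRUE, prob = probs[aas])
  aa[1] <- "M"
  aa[motif_pos:(motif_pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
  if (!is.null(fixed))
    aa[as.integer(names(fixed))] <- unname(fixed)
  aa
}

## back-translate: uniform choice among synonymous codons, with overrides
codons_for <- function(aa, start_codon, fixed_codons = NULL) {
  syn <- .syn_codons()
  cod <- vapply(aa, function(a) sample(syn[[a]], 1L), character(1))
  cod[1] <- start_codon
  if (!is.null(fixed_codons))
    cod[as.integer(names(fixed_codons))] <- unname(fixed_codons)
  cod
}

## residues fixed in the mutation-host protein so the default planted
## mutation catalogue (F42V, K97R, P129P silent, G132Stop shared; F13V,
## N133K, R215R silent unique) has its reference codons in place
.MUTATION_HOST_RESIDUES <- c("13" = "F", "42" = "F", "97" = "K",
                             "129" = "P", "132" = "G", "133" = "N",
                             "215" = "R")
.MUTATION_HOST_CODONS <- c("13" = "TTC", "42" = "TTT", "97" = "AAA",
                           "129" = "CCA", "132" = "GGA", "133" = "AAC",
                           "215" = "CGT")
.SHARED_MUTATIONS <- data.frame(
  codon_index = c(42L, 97L, 129L, 132L),
  alt_codon = c("GTT", "AGA", "CCG", "TGA"),
  name = c("F42V", "K97R", "P129P (silent)", "G132Stop"),
  mclass = c("missense", "missense", "silent", "stop-gain"),
  stringsAsFactors = FALSE)
.UNIQUE_MUTATIONS <- data.frame(
  codon_index = c(13L, 133L, 215L),
  alt_codon = c("GTC", "AAA", "CGC"),
  name = c("F13V", "N133K", "R215R (silent)"),
  mclass = c("missense", "missense", "silent"),
  stringsAsFactors = FALSE)

## conserved 12-13 aa family window; FPFP at offset 3 (1-based)
.FAMILY_MOTIF <- "SKFPFPDYTLSRW"
.CASSETTE_MARGIN <- 2000L

#' Generate the toy genome with planted pericentromeric ORFs
#'
#' Each chromosome carries a central centromere with repeat blocks on both
#' flanks. Planted ORFs are embedded inside repeat blocks (round-robin over
#' chromosomes and flanks, alternating strand), each preceded in frame by a
#' stop codon so that ORF discovery recovers it at exactly its recorded
#' coordinates. A decoy ORF sits in unique sequence far from any centromere
#' (negative control for the pericentromere scan) and a two-exon spliced
#' decoy gene provides the splicing control. All planted proteins share a
#' conserved 13-residue window containing the FPFP motif, and the second
#' planted ORF (792 nt, 263 residues by default) carries the fixed
#' reference residues used by the default mutation catalogue.
#'
#' @param config a \code{\link{periscan_config}} (synthetic keys).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with \code{genome} (\code{DNAStringSet}),
#'   \code{centromeres}, \code{repeats} (\code{GRanges}) and \code{ledger}
#'   (the truth ledger: chromosomes, centromeres, repeats, planted ORFs
#'   with protein and nucleotide sequences, motif coordinates, spliced
#'   gene).
#' @export
generate_genome <- function(config = toy_config(), seed = config$seed) {
  n_chr <- as.integer(config$n_chromosomes)
  L <- as.integer(config$chrom_length)
  cen_len <- as.integer(config$centromere_length)
  rf <- as.integer(config$repeat_flank)
  orf_nt <- as.integer(config$planted_orf_nt)
  if (n_chr < 2) stop("config error: need at least 2 chromosomes")
  if (L < 200000L) stop("config error: chromosome length must be >= 200 kb")
  if (!length(orf_nt)) stop("config error: need at least 1 planted ORF")
  if (any(orf_nt %% 3 != 0 | orf_nt < 150L))
    stop("config error: planted ORF lengths must be multiples of 3, >= 150 nt")
  cassette_len <- orf_nt + 2L * nchar(.STOP_WALL) + 3L
  if (any(cassette_len + 2L * .CASSETTE_MARGIN > rf))
    stop("config error: planted ORF longer than its host repeat block")
  with_seed(seed, {
    monomers <- replicate(n_chr, make_repeat_monomer())
    chroms <- paste0("chr", seq_len(n_chr))
    seqs <- vapply(seq_len(n_chr), function(i) random_dna(L), character(1))
    cen_start <- as.integer(L %/% 2 - cen_len %/% 2 + 1L)
    cen_end <- cen_start + cen_len - 1L
    cen_df <- data.frame(chrom = chroms, start = cen_start, end = cen_end,
                         stringsAsFactors = FALSE)
    rep_df <- rbind(
      data.frame(chrom = chroms, start = cen_start - rf, end = cen_start - 1L),
      data.frame(chrom = chroms, start = cen_end + 1L, end = cen_end + rf))
    rep_df <- rep_df[order(rep_df$chrom, rep_df$start), , drop = FALSE]
    rownames(rep_df) <- NULL
    ## tandem-repeat fill of the flanks
    for (i in seq_len(n_chr)) {
      arr <- substr(paste(rep(monomers[i], ceiling(rf / .MONOMER_NT)),
                          collapse = ""), 1L, rf)
      substr(seqs[i], cen_start - rf, cen_start - 1L) <- arr
      substr(seqs[i], cen_end + 1L, cen_end + rf) <- arr
    }
    ## plant the pericentromeric ORFs
    n_orfs <- length(orf_nt)
    gene_ids <- paste0("GPS", seq_len(n_orfs))
    host_chr <- ((seq_len(n_orfs) - 1L) %% n_chr) + 1L
    host_side <- ifelse(seq_len(n_orfs) %% 2 == 1L, "left", "right")
    strands <- ifelse(seq_len(n_orfs) %% 2 == 1L, "+", "-")
    start_codons <- rep("ATG", n_orfs)
    if (n_orfs >= 4) start_codons[4] <- "GTG"
    orf_rows <- list()
    for (k in seq_len(n_orfs)) {
      len_aa <- orf_nt[k] %/% 3L - 1L
      is_host <- k == 2L && len_aa >= 215L
      fixed_res <- if (is_host) .MUTATION_HOST_RESIDUES else NULL
      motif_pos <- if (len_aa >= 170L) 150L else len_aa - 20L
      aa <- make_protein(len_aa, .FAMILY_MOTIF, motif_pos, fixed_res)
      cod <- codons_for(aa, start_codons[k],
                        if (is_host) .MUTATION_HOST_CODONS else NULL)
      nt <- paste0(paste(cod, collapse = ""), sample(.STOP_CODONS, 1L))
      cassette <- paste0(.STOP_WALL, "TAA", nt, .STOP_WALL)
      M <- nchar(cassette)
      block_start <- if (host_side[k] == "left") cen_start - rf else cen_end + 1L
      lo <- block_start + .CASSETTE_MARGIN
      hi <- block_start + rf - 1L - .CASSETTE_MARGIN - M
      P <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      ins <- if (strands[k] == "+") cassette else revcomp(cassette)
      substr(seqs[host_chr[k]], P, P + M - 1L) <- ins
      g_start <- if (strands[k] == "+") P + 15L else P + 12L
      g_end <- g_start + orf_nt[k] - 1L
      orf_rows[[k]] <- data.frame(
        gene = gene_ids[k], chrom = chroms[host_chr[k]],
        start = g_start, end = g_end, strand = strands[k],
        nt_length = orf_nt[k], start_codon = start_codons[k],
        protein = paste(aa, collapse = ""), nt = nt,
        pericentromeric = TRUE, motif_start = motif_pos,
        stringsAsFactors = FALSE)
    }
    ## decoy ORF outside the pericentromeric window, in unique sequence
    decoy_nt <- as.integer(config$decoy_orf_nt)
    decoy_aa <- make_protein(decoy_nt %/% 3L - 1L, .FAMILY_MOTIF,
                             decoy_nt %/% 3L - 21L)
    decoy_seq <- paste0(paste(codons_for(decoy_aa, "ATG"), collapse = ""), "TAA")
    decoy_cassette <- paste0(.STOP_WALL, "TAA", decoy_seq, .STOP_WALL)
    decoy_P <- as.integer(L %/% 20)
    substr(seqs[1], decoy_P, decoy_P + nchar(decoy_cassette) - 1L) <- decoy_cassette
    orf_rows[[n_orfs + 1L]] <- data.frame(
      gene = "decoy", chrom = chroms[1],
      start = decoy_P + 15L, end = decoy_P + 15L + decoy_nt - 1L,
      strand = "+", nt_length = decoy_nt, start_codon = "ATG",
      protein = paste(decoy_aa, collapse = ""), nt = decoy_seq,
      pericentromeric = FALSE,
      motif_start = decoy_nt %/% 3L - 21L, stringsAsFactors = FALSE)
    orfs <- do.call(rbind, orf_rows)
    ## spliced decoy gene: exon1 - intron (GT...AG) - exon2 on chr2
    sp_P <- as.integer(L %/% 20)
    exon_w <- 300L; intron_w <- 100L
    ex1 <- c(sp_P, sp_P + exon_w - 1L)
    intr <- c(ex1[2] + 1L, ex1[2] + intron_w)
    ex2 <- c(intr[2] + 1L, intr[2] + exon_w)
    intron_seq <- paste0("GT", random_dna(intron_w - 4L), "AG")
    substr(seqs[2], intr[1], intr[2]) <- intron_seq
    spliced <- list(gene = "spliced_decoy", chrom = chroms[2], strand = "+",
                    exon1_start = ex1[1], exon1_end = ex1[2],
                    intron_start = intr[1], intron_end = intr[2],
                    exon2_start = ex2[1], exon2_end = ex2[2])
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
    ledger <- list(
      seed = seed,
      chromosomes = stats::setNames(rep(L, n_chr), chroms),
      centromeres = cen_df,
      repeats = rep_df,
      orfs = orfs,
      motif = list(sequence = .FAMILY_MOTIF, fpfp_offset = 3L),
      spliced = spliced)
    ps_log("generate_genome: %d chromosomes x %d bp, %d planted ORFs + decoys (seed %d)",
           n_chr, L, n_orfs, seed)
    list(genome = genome,
         centromeres = gi(cen_df$chrom, cen_df$start, cen_df$end),
         repeats = gi(rep_df$chrom, rep_df$start, rep_df$end),
         ledger = ledger)
  })
}

bin_track <- function(chrom_lengths, bin, values_fun) {
  parts <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    starts <- seq(1L, L, by = bin)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + bin - 1L, L),
               score = values_fun(chrom, length(starts)))
  })
  df <- do.call(rbind, parts)
  gi(df$chrom, df$start, df$end, score = df$score)
}

#' Generate H3K27ac / H3K27me3 signal tracks over the toy genome
#'
#' Both tracks get a qualifying flat-top peak (amplitude
#' \code{peak_amplitude}, at least the calling threshold) centred on every
#' planted pericentromeric ORF, clipped to the host repeat block; the decoy
#' ORF gets none. Off-peak bins carry uniform noise in
#' [0, threshold/2] (exactly 0 with \code{signal_noise = FALSE}), so peak
#' calling at the configured threshold separates signal from baseline by
#' construction.
#'
#' @param genome result of \code{\link{generate_genome}} (or its ledger).
#' @param config a \code{\link{periscan_config}}.
#' @param seed integer seed.
#' @return list with \code{h3k27ac}, \code{h3k27me3} (\code{GRanges} with
#'   \code{score}) and \code{ledger} updated with \code{planted_peaks}.
#' @export
generate_signal_tracks <- function(genome, config = toy_config(),
                                   seed = config$seed + 1L) {
  ledger <- if (!is.null(genome$ledger)) genome$ledger else genome
  bin <- as.integer(config$signal_bin)
  with_seed(seed, {
    tracks <- list()
    peaks <- list()
    for (mark in c("h3k27ac", "h3k27me3")) {
      thr <- config[[paste0(mark, "_threshold")]]
      tr <- bin_track(ledger$chromosomes, bin, function(chrom, n) {
        if (isTRUE(config$signal_noise)) stats::runif(n, 0, thr / 2) else rep(0, n)
      })
      orfs <- ledger$orfs[ledger$orfs$pericentromeric, , drop = FALSE]
      tr_chrom <- as.character(GenomicRanges::seqnames(tr))
      tr_start <- GenomicRanges::start(tr)
      tr_end <- GenomicRanges::end(tr)
      for (i in seq_len(nrow(orfs))) {
        host <- ledger$repeats[ledger$repeats$chrom == orfs$chrom[i] &
                                 ledger$repeats$start <= orfs$start[i] &
                                 ledger$repeats$end >= orfs$end[i], ][1, ]
        span_s <- max(orfs$start[i] - config$peak_pad, host$start)
        span_e <- min(orfs$end[i] + config$peak_pad, host$end)
        amp <- config$peak_amplitude +
          if (isTRUE(config$signal_noise)) stats::runif(1, 0, 1) else 0
        sel <- tr_chrom == orfs$chrom[i] &
          tr_end >= span_s & tr_start <= span_e
        tr$score[sel] <- amp
        covered <- range(which(sel))
        peaks[[length(peaks) + 1L]] <- data.frame(
          gene = orfs$gene[i], chrom = orfs$chrom[i],
          start = tr_start[covered[1]], end = tr_end[covered[2]],
          mark = mark, amplitude = amp, stringsAsFactors = FALSE)
      }
      tracks[[mark]] <- tr
    }
    ledger$planted_peaks <- do.call(rbind, peaks)
    ps_log("generate_signal_tracks: %d planted peaks per mark",
           sum(ledger$planted_peaks$mark == "h3k27ac"))
    list(h3k27ac = tracks$h3k27ac, h3k27me3 = tracks$h3k27me3, ledger = ledger)
  })
}

#' Generate transcripts with planted mutations
#'
#' Per sample cell line, a transcript copy of each pericentromeric ORF plus
#' \code{transcript_flank} nt of genomic context on each side, on the
#' coding strand. The mutation-host gene (the second planted ORF) carries
#' the default catalogue: shared across both samples F42V, K97R,
#' P129P (silent) and the truncation G132Stop; unique to the second sample
#' F13V, N133K and R215R (silent). The first sample also receives the
#' spliced decoy transcript (its two exons joined, intron spliced out).
#' With \code{plant_mutations = FALSE} transcripts are exact genomic
#' copies.
#'
#' @param genome result of \code{\link{generate_genome}}.
#' @param config a \code{\link{periscan_config}}.
#' @param seed integer seed.
#' @return list with \code{transcripts} (\code{DNAStringSet}, names
#'   "sample|gene") and \code{ledger} updated with
#'   \code{planted_mutations} and \code{transcript_regions}.
#' @export
generate_transcripts <- function(genome, config = toy_config(),
                                 seed = config$seed + 2L) {
  ledger <- genome$ledger
  seqs <- genome$genome
  fl <- as.integer(config$transcript_flank)
  samples <- config$transcript_samples
  orfs <- ledger$orfs[ledger$orfs$pericentromeric, , drop = FALSE]
  host_row <- if (nrow(orfs) >= 2) 2L else 1L
  host_gene <- orfs$gene[host_row]
  plant <- isTRUE(config$plant_mutations)
  if (plant) {
    plen <- nchar(orfs$protein[host_row])
    wanted <- rbind(.SHARED_MUTATIONS, .UNIQUE_MUTATIONS)
    if (any(wanted$codon_index > plen))
      stop("config error: requested mutation at codon index beyond protein length (",
           plen, " aa)")
  }
  with_seed(seed, {
    tx <- character(0)
    regions <- list(); muts <- list()
    for (si in seq_along(samples)) {
      sm <- samples[si]
      for (i in seq_len(nrow(orfs))) {
        chrom <- orfs$chrom[i]
        a <- orfs$start[i] - fl; z <- orfs$end[i] + fl
        s <- as.character(Biostrings::subseq(seqs[[chrom]], a, z))
        if (orfs$strand[i] == "-") s <- revcomp(s)
        if (plant && orfs$gene[i] == host_gene) {
          selected <- .SHARED_MUTATIONS
          if (si >= 2) selected <- rbind(selected, .UNIQUE_MUTATIONS)
          for (r in seq_len(nrow(selected))) {
            ci <- selected$codon_index[r]
            p0 <- fl + (ci - 1L) * 3L + 1L
            ref <- substr(s, p0, p0 + 2L)
            substr(s, p0, p0 + 2L) <- selected$alt_codon[r]
            muts[[length(muts) + 1L]] <- data.frame(
              sample = sm, gene = host_gene, codon_index = ci,
              ref_codon = ref, alt_codon = selected$alt_codon[r],
              name = selected$name[r], mclass = selected$mclass[r],
              shared = r <= nrow(.SHARED_MUTATIONS),
              stringsAsFactors = FALSE)
          }
        }
        tx[paste(sm, orfs$gene[i], sep = "|")] <- s
        regions[[length(regions) + 1L]] <- data.frame(
          sample = sm, gene = orfs$gene[i], chrom = chrom,
          region_start = a, region_end = z, strand = orfs$strand[i],
          orf_offset = fl + 1L, stringsAsFactors = FALSE)
      }
    }
    ## spliced decoy transcript for the first sample
    sp <- ledger$spliced
    sp_seq <- paste0(
      as.character(Biostrings::subseq(seqs[[sp$chrom]],
                                      sp$exon1_start - fl, sp$exon1_end)),
      as.character(Biostrings::subseq(seqs[[sp$chrom]],
                                      sp$exon2_start, sp$exon2_end + fl)))
    tx[paste(samples[1], sp$gene, sep = "|")] <- sp_seq
    ledger$planted_mutations <- if (length(muts)) do.call(rbind, muts) else NULL
    ledger$transcript_regions <- do.call(rbind, regions)
    ps_log("generate_transcripts: %d transcripts, %d planted mutation records",
           length(tx), length(muts))
    list(transcripts = Biostrings::DNAStringSet(tx), ledger = ledger)
  })
}

#' Generate the cell-line expression matrices
#'
#' 100 synthetic cell lines (configurable) in five blocks: 12 planted
#' double-positive lines (highest cumulative C19MC, GPS-positive), a larger
#' block of weaker double-positives, GPS-only lines (GPS expressed without
#' C19MC, as observed in a minority of real lines), exactly 12 planted
#' double-zero lines, and miRNA-only lines. GPS MRSP values are Poisson
#' counts whose means make the first two planted genes the top combined
#' scorers; background genes carry planted log2 fold changes between the
#' two planted groups (some beyond the +/-2 screen threshold, some within)
#' on a log-normal depth model (sd 0.3 in log2 units).
#'
#' @param ledger a truth ledger (for the GPS gene ids), or the result list
#'   holding one.
#' @param config a \code{\link{periscan_config}}.
#' @param seed integer seed.
#' @return list with \code{genes} (GPS + background genes x lines matrix),
#'   \code{mirna} (miRNAs x lines), \code{c19mc_members}, and
#'   \code{ledger} updated with \code{expression} truth (MRSP matrix,
#'   cumulative C19MC, group memberships, background log2FC truth).
#' @export
generate_expression_matrix <- function(ledger, config = toy_config(),
                                       seed = config$seed + 3L) {
  if (!is.null(ledger$ledger)) ledger <- ledger$ledger
  n <- as.integer(config$n_cell_lines)
  n_grp <- as.integer(config$n_per_group)
  if (n < 2L * n_grp)
    stop("config error: need at least ", 2L * n_grp, " cell lines")
  gps_genes <- ledger$orfs$gene[ledger$orfs$pericentromeric]
  with_seed(seed, {
    lines <- sprintf("line%03d", seq_len(n))
    rest <- n - 2L * n_grp
    n_low <- rest %/% 2L
    n_gpsonly <- ((rest - n_low) * 2L) %/% 3L
    n_mironly <- rest - n_low - n_gpsonly
    status <- sample(c(rep("pos", n_grp), rep("neg", n_grp),
                       rep("low", n_low), rep("gps_only", n_gpsonly),
                       rep("mir_only", n_mironly)))
    names(status) <- lines
    ## GPS gene MRSP values
    lambda <- c(30, 22, 6, 4, rep(3, max(0, length(gps_genes) - 4L)))[
      seq_along(gps_genes)]
    gps_m <- matrix(0, length(gps_genes), n, dimnames = list(gps_genes, lines))
    gps_on <- status %in% c("pos", "low", "gps_only")
    for (gi in seq_along(gps_genes)) {
      v <- stats::rpois(sum(gps_on), lambda[gi])
      if (gi == 1L) v <- v + 1L  # anchors GPS positivity of every GPS-on line
      gps_m[gi, gps_on] <- v
    }
    ## C19MC and other miRNAs
    members <- c("miR-512", "miR-515", "miR-516B", "miR-517A",
                 "miR-519D", "miR-520G", "miR-522", "miR-526B")
    others <- c("miR-21", "miR-155", "let-7A", "miR-200C")
    mir_m <- matrix(0, length(members) + length(others), n,
                    dimnames = list(c(members, others), lines))
    for (ln in lines) {
      mir_m[members, ln] <- switch(status[[ln]],
        pos = stats::runif(length(members), 10, 25),
        low = stats::runif(length(members), 0.5, 3),
        mir_only = stats::runif(length(members), 1, 5),
        rep(0, length(members)))
      mir_m[others, ln] <- stats::runif(length(others), 0, 10)
    }
    ## background genes with planted log2 fold changes (pos vs neg group)
    n_bg <- as.integer(config$n_background_genes)
    planted_lfc <- c(5, 5, 4, 4, 3, 3, 1, 1, -1, -1, -3, -3, -4, -4, -5, -5)
    lfc <- c(planted_lfc, rep(0, max(0, n_bg - length(planted_lfc))))[seq_len(n_bg)]
    bg_genes <- sprintf("BG%03d", seq_len(n_bg))
    bg_m <- matrix(0, n_bg, n, dimnames = list(bg_genes, lines))
    base_mu <- 6
    for (gi in seq_len(n_bg)) {
      mu <- ifelse(status == "pos", base_mu + lfc[gi], base_mu)
      bg_m[gi, ] <- pmax(0, round(2^stats::rnorm(n, mu, 0.3) - 1))
    }
    genes <- rbind(gps_m, bg_m)
    c19 <- colSums(mir_m[members, , drop = FALSE])
    ledger$expression <- list(
      gps_genes = gps_genes,
      mrsp = gps_m,
      c19mc_members = members,
      c19mc_cumulative = c19,
      groups = list(positive = sort(lines[status == "pos"]),
                    negative = sort(lines[status == "neg"])),
      background_truth = data.frame(gene = bg_genes, planted_log2fc = lfc,
                                    stringsAsFactors = FALSE),
      de_truth = bg_genes[abs(lfc) > config$de_log2fc])
    ps_log("generate_expression_matrix: %d lines (%d pos / %d neg planted), %d genes",
           n, n_grp, n_grp, nrow(genes))
    list(genes = genes, mirna = mir_m, c19mc_members = members, ledger = ledger)
  })
}

#' Generate per-base coverage tracks matching the MRSP truth
#'
#' For every cell line and planted GPS gene with non-zero MRSP truth m, a
#' depth profile over the ORF: a baseline of floor(m/2) with a single base
#' at depth m (the maximum-at-single-point the MRSP statistic reads out).
#' Zero-expression (gene, line) pairs get no records (flat 0).
#'
#' @param ledger a truth ledger carrying \code{expression} (from
#'   \code{\link{generate_expression_matrix}}), or a result list holding
#'   one.
#' @param config a \code{\link{periscan_config}}.
#' @param seed integer seed.
#' @return named list (cell line -> \code{GRanges} with \code{score}).
#' @export
generate_coverage <- function(ledger, config = toy_config(),
                              seed = config$seed + 4L) {
  if (!is.null(ledger$ledger)) ledger <- ledger$ledger
  if (is.null(ledger$expression))
    stop("ledger has no expression truth; run generate_expression_matrix first")
  mrsp_truth <- ledger$expression$mrsp
  orfs <- ledger$orfs[match(rownames(mrsp_truth), ledger$orfs$gene), , drop = FALSE]
  with_seed(seed, {
    out <- list()
    for (ln in colnames(mrsp_truth)) {
      recs <- list()
      for (i in seq_len(nrow(orfs))) {
        m <- mrsp_truth[i, ln]
        if (m == 0) next
        a <- orfs$start[i]; z <- orfs$end[i]
        p <- a + sample.int(z - a + 1L, 1L) - 1L
        b <- floor(m / 2)
        df <- data.frame(start = p, end = p, score = m)
        if (b > 0) {
          if (p > a) df <- rbind(data.frame(start = a, end = p - 1L, score = b), df)
          if (p < z) df <- rbind(df, data.frame(start = p + 1L, end = z, score = b))
        }
        df$chrom <- orfs$chrom[i]
        recs[[length(recs) + 1L]] <- df
      }
      out[[ln]] <- if (length(recs)) {
        d <- do.call(rbind, recs)
        d <- d[order(d$chrom, d$start), , drop = FALSE]
        gi(d$chrom, d$start, d$end, score = d$score)
      } else GenomicRanges::GRanges(score = numeric(0))
    }
    out
  })
}

ledger_to_json <- function(ledger, path) {
  clean <- rapply(ledger, unclass, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Run every generator and optionally write the file bundle
#'
#' Chains \code{\link{generate_genome}},
#' \code{\link{generate_signal_tracks}}, \code{\link{generate_transcripts}},
#' \code{\link{generate_expression_matrix}} and
#' \code{\link{generate_coverage}} with seeds derived from \code{seed}
#' (seed, seed+1, ..., seed+4). With \code{out_dir}, writes genome.fa,
#' centromeres.bed, repeats.bed, h3k27ac.bedGraph, h3k27me3.bedGraph,
#' transcripts.fa, genes_mrsp.tsv, mirna.tsv, c19mc_members.txt, per-line
#' coverage bedGraphs under coverage/, and truth_ledger.json.
#'
#' @param config a \code{\link{periscan_config}}.
#' @param seed base integer seed.
#' @param out_dir optional output directory (created if missing).
#' @return list with all in-memory products and the final \code{ledger}.
#' @export
simulate_all <- function(config = toy_config(), seed = config$seed,
                         out_dir = NULL) {
  g <- generate_genome(config, seed)
  sig <- generate_signal_tracks(g, config, seed + 1L)
  g$ledger <- sig$ledger
  tx <- generate_transcripts(g, config, seed + 2L)
  g$ledger <- tx$ledger
  em <- generate_expression_matrix(g$ledger, config, seed + 3L)
  g$ledger <- em$ledger
  cov <- generate_coverage(g$ledger, config, seed + 4L)
  out <- list(genome = g$genome, centromeres = g$centromeres,
              repeats = g$repeats,
              h3k27ac = sig$h3k27ac, h3k27me3 = sig$h3k27me3,
              transcripts = tx$transcripts,
              genes = em$genes, mirna = em$mirna,
              c19mc_members = em$c19mc_members,
              coverage = cov, ledger = g$ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$genome, file.path(out_dir, "genome.fa"))
    write_bed(out$centromeres, file.path(out_dir, "centromeres.bed"))
    write_bed(out$repeats, file.path(out_dir, "repeats.bed"))
    write_bedgraph(out$h3k27ac, file.path(out_dir, "h3k27ac.bedGraph"))
    write_bedgraph(out$h3k27me3, file.path(out_dir, "h3k27me3.bedGraph"))
    write_fasta(out$transcripts, file.path(out_dir, "transcripts.fa"))
    write_matrix_tsv(out$genes, file.path(out_dir, "genes_mrsp.tsv"), "gene")
    write_matrix_tsv(out$mirna, file.path(out_dir, "mirna.tsv"), "mirna")
    writeLines(out$c19mc_members, file.path(out_dir, "c19mc_members.txt"))
    covdir <- file.path(out_dir, "coverage")
    dir.create(covdir, showWarnings = FALSE)
    for (ln in names(cov))
      if (length(cov[[ln]]))
        write_bedgraph(cov[[ln]], file.path(covdir, paste0(ln, ".bedGraph")))
    ledger_to_json(out$ledger, file.path(out_dir, "truth_ledger.json"))
    ps_log("simulate_all: bundle written to %s", out_dir)
  }
  out
}
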