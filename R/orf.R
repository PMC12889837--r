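## Six-frame ORF discovery, translation, and protein-level annotation.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Find open reading frames in all six frames
#'
#' Scans both strands in all three frames. Within each stop-delimited
#' reading segment the single reported ORF runs from the most upstream
#' qualifying start codon through the bounding stop codon (the
#' "maximum ORF length" convention); segments without a terminal stop are
#' not reported. ORFs containing N, or shorter than
#' \code{config$min_orf_length} (stop codon included), are dropped.
#'
#' @param sequence nucleotide sequence: a character scalar or
#'   \code{DNAString}; A/C/G/T/N only.
#' @param config a \code{\link{periscan_config}}; uses \code{min_orf_length}
#'   and \code{start_codons}.
#' @return data.frame with one row per ORF: \code{start}, \code{end}
#'   (1-based, closed, on the input sequence, stop codon included),
#'   \code{strand}, \code{frame} (0-2 on the scanned strand),
#'   \code{nt_length}, \code{start_codon}, \code{protein} (stop excluded).
#'   Sorted by \code{nt_length} descending, ties by leftmost start then
#'   \code{+} before \code{-}.
#' @examples
#' find_orfs("ATGGCTTAA", periscan_config(min_orf_length = 6))
#' @export
find_orfs <- function(sequence, config = periscan_config()) {
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside A/C/G/T/N")
  L <- nchar(s)
  starts <- toupper(config$start_codons)
  out <- list()
  for (str in c("+", "-")) {
    sc <- if (str == "+") s else revcomp(s)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < 2) next
      pos <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(sc, pos, pos + 2L)
      stop_idx <- which(codons %in% .STOP_CODONS)
      if (!length(stop_idx)) next
      seg_begin <- c(1L, stop_idx + 1L)[seq_along(stop_idx)]
      for (k in seq_along(stop_idx)) {
        b <- seg_begin[k]; e <- stop_idx[k]
        if (b > e - 1L) next
        cand <- which(codons[b:(e - 1L)] %in% starts)
        if (!length(cand)) next
        i0 <- b + cand[1L] - 1L
        a_local <- pos[i0]
        z_local <- pos[e] + 2L
        nt_len <- z_local - a_local + 1L
        if (nt_len < config$min_orf_length) next
        orf_nt <- substr(sc, a_local, z_local)
        if (grepl("N", orf_nt, fixed = TRUE)) next
        g_start <- if (str == "+") a_local else L - z_local + 1L
        g_end <- if (str == "+") z_local else L - a_local + 1L
        out[[length(out) + 1L]] <- data.frame(
          start = g_start, end = g_end, strand = str, frame = frame,
          nt_length = nt_len, start_codon = codons[i0],
          protein = translate_orf(orf_nt, starts),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      nt_length = integer(0), start_codon = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  ord <- order(-df$nt_length, df$start, match(df$strand, c("+", "-")))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code; the terminal stop codon is required and excluded
#' from the protein; an alternative initiation codon in \code{start_codons}
#' is translated as methionine at position 1 (initiator convention).
#'
#' @param nt ORF nucleotide sequence (start through stop codon).
#' @param start_codons allowed initiation codons.
#' @return protein sequence (character scalar).
#' @examples
#' translate_orf("ATGGCTTAA")
#' translate_orf("TTGGCTTAA")  # initiator-Met convention
#' @export
translate_orf <- function(nt, start_codons = c("ATG", "CTG", "GTG", "TTG")) {
  nt <- toupper(as.character(nt))
  if (nchar(nt) %% 3 != 0)
    stop("ORF length must be a multiple of 3, got ", nchar(nt))
  n <- nchar(nt) %/% 3
  pos <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(nt, pos, pos + 2L)
  if (!codons[n] %in% .STOP_CODONS)
    stop("ORF must end with a stop codon, found ", codons[n])
  if (!codons[1] %in% start_codons)
    stop("ORF must begin with a start codon (", paste(start_codons, collapse = "/"),
         "), found ", codons[1])
  aa <- unname(.codon_table()[codons[-n]])
  if (anyNA(aa)) stop("untranslatable codon in ORF")
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon at codon index ", internal[1])
  aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Find and annotate ORFs within candidate loci
#'
#' Extracts each candidate interval from the genome, padded by
#' \code{config$candidate_pad} on both sides to avoid truncating ORFs at
#' peak edges, runs \code{\link{find_orfs}}, and maps coordinates back to
#' the genome.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param candidates a \code{GRanges} (e.g. from \code{\link{scan_candidates}})
#'   or the data.frame that function returns.
#' @param config a \code{\link{periscan_config}}.
#' @return data.frame as \code{\link{find_orfs}} plus \code{chrom} and
#'   \code{candidate} (index of the source locus), coordinates genomic.
#' @export
orfs_in_candidates <- function(genome, candidates, config = periscan_config()) {
  if (is.data.frame(candidates))
    candidates <- gi(candidates$chrom, candidates$start, candidates$end)
  out <- list()
  for (i in seq_along(candidates)) {
    chrom <- as.character(GenomicRanges::seqnames(candidates)[i])
    if (!chrom %in% names(genome)) stop("candidate chromosome not in genome: ", chrom)
    clen <- length(genome[[chrom]])
    a <- max(1L, GenomicRanges::start(candidates)[i] - config$candidate_pad)
    z <- min(clen, GenomicRanges::end(candidates)[i] + config$candidate_pad)
    seq <- as.character(Biostrings::subseq(genome[[chrom]], a, z))
    orfs <- find_orfs(seq, config)
    if (!nrow(orfs)) next
    orfs$start <- orfs$start + a - 1L
    orfs$end <- orfs$end + a - 1L
    orfs$chrom <- chrom
    orfs$candidate <- i
    out[[length(out) + 1L]] <- orfs
  }
  if (!length(out))
    return(cbind(find_orfs("TTTTTT", periscan_config(min_orf_length = 30L)),
                 chrom = character(0), candidate = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(-df$nt_length, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Approximate molecular weight from protein length
#'
#' The average-residue-mass rule: 110 Da per amino acid, reported in kDa to
#' two decimals (e.g. 207 residues -> 22.77 kDa).
#'
#' @param length_aa protein length in residues.
#' @return kDa, rounded to 2 decimals.
#' @examples
#' approx_molecular_weight(207)
#' @export
approx_molecular_weight <- function(length_aa) {
  if (any(length_aa < 0)) stop("protein length must be non-negative")
  round(110 * length_aa / 1000, 2)
}

## Average residue masses (Da) for the exact average-mass computation
## (monomer residue masses; one water is added per chain).
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

exact_molecular_weight <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  bad <- setdiff(aa, names(.AA_AVG_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ""))
  (sum(.AA_AVG_MASS[aa]) + .WATER_MASS) / 1000
}

#' EMBOSS pKa table
#'
#' The default, swappable pKa set for \code{\link{isoelectric_point}}:
#' N-terminus 8.6, C-terminus 3.6, side chains C 8.5, D 3.9, E 4.1, H 6.5,
#' K 10.8, R 12.5, Y 10.1.
#'
#' @return list with \code{nterm}, \code{cterm} and named \code{side}
#'   pKa values.
#' @export
emboss_pka <- function() {
  list(nterm = 8.6, cterm = 3.6,
       side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1))
}

protein_net_charge <- function(counts, nterm, cterm, pka, pH) {
  pos <- nterm / (1 + 10^(pH - pka$nterm)) +
    sum(counts[c("K", "R", "H")] / (1 + 10^(pH - pka$side[c("K", "R", "H")])))
  neg <- cterm / (1 + 10^(pka$cterm - pH)) +
    sum(counts[c("D", "E", "C", "Y")] / (1 + 10^(pka$side[c("D", "E", "C", "Y")] - pH)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Henderson-Hasselbalch net charge over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R), with the pH where the charge
#' crosses zero found by bisection on [0, 14]. Net charge is strictly
#' decreasing in pH, so the root exists and is unique. Depends only on
#' residue composition, not order.
#'
#' @param protein protein sequence (character scalar), no stop character.
#' @param pka a pKa table as returned by \code{\link{emboss_pka}} (the
#'   default); a named list with \code{nterm}, \code{cterm} and \code{side}.
#' @param tol reporting tolerance in pH units.
#' @return pH of zero net charge.
#' @examples
#' isoelectric_point("G")  # midpoint of the two termini, 6.10
#' @export
isoelectric_point <- function(protein, pka = emboss_pka(), tol = 0.01) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (!length(aa)) stop("empty protein")
  if (any(aa == "*")) stop("protein contains a stop character")
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(aa == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > tol / 10) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, 1, 1, pka, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Residue composition and enrichment over background
#'
#' @param protein protein sequence.
#' @param background named per-residue background frequencies summing to 1;
#'   default uniform (0.05 each over the 20 amino acids).
#' @param cutoff enrichment ratio at or above which a residue is reported
#'   as enriched.
#' @return list with \code{composition} (fractions over the 20 residues,
#'   summing to 1), \code{ratio} (fraction/background), and
#'   \code{enriched} (residues with ratio >= cutoff, ratio-descending).
#' @export
residue_enrichment <- function(protein, background = NULL, cutoff = 1.5) {
  aas <- setdiff(.AA_ALPHABET, "*")
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), aas)
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  aa <- aa[aa != "*"]
  if (!length(aa)) stop("empty protein")
  comp <- vapply(aas, function(a) mean(aa == a), numeric(1))
  ratio <- comp / background[aas]
  enriched <- names(sort(ratio[ratio >= cutoff], decreasing = TRUE))
  list(composition = comp, ratio = ratio, enriched = enriched)
}

#' Annotate a protein
#'
#' One row of protein-level annotation: length, approximate molecular
#' weight (110 Da per residue, the number quoted in reports), exact
#' average-mass molecular weight (auxiliary), isoelectric point, and the
#' residues enriched over background.
#'
#' @inheritParams residue_enrichment
#' @param pka pKa table for the isoelectric point.
#' @return data.frame with columns \code{length_aa}, \code{approx_mw_kda},
#'   \code{exact_mw_kda}, \code{pI}, \code{enriched_residues}.
#' @export
annotate_protein <- function(protein, background = NULL, cutoff = 1.5,
                             pka = emboss_pka()) {
  n <- nchar(protein)
  enr <- residue_enrichment(protein, background, cutoff)
  data.frame(
    length_aa = n,
    approx_mw_kda = approx_molecular_weight(n),
    exact_mw_kda = round(exact_molecular_weight(protein), 2),
    pI = round(isoelectric_point(protein, pka), 2),
    enriched_residues = paste(enr$enriched, collapse = ","),
    stringsAsFactors = FALSE)
}
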