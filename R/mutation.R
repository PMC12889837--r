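## Transcript-to-genome alignment (intronless determination) and
## codon-level mutation calling with silent / missense / stop-gain
## nomenclature (e.g. "F42V", "P129P (silent)", "G132Stop").

nt_substitution_matrix <- function(match, mismatch) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Align a transcript to its genomic region
#'
#' Global-on-transcript alignment with affine gaps (the genomic region may
#' extend past the transcript). Genome-side gaps at least
#' \code{config$intron_threshold} nt long are recorded as candidate introns;
#' a transcript is intronless when it has none. Identity is computed over
#' all aligned columns (terminal overhangs of the genomic region are not
#' columns of a global-on-transcript alignment).
#'
#' @param transcript nucleotide sequence (character or \code{DNAString}).
#' @param genome_region genomic reference sequence on the transcript's
#'   coding strand.
#' @param config a \code{\link{periscan_config}} (nucleotide scoring,
#'   \code{intron_threshold}, \code{identity_floor}).
#' @param transcript_id label carried into reports.
#' @return object of class \code{transcript_alignment}: aligned strings,
#'   \code{subject_start} (region coordinate of the first aligned base),
#'   \code{identity_pct}, \code{gaps_in_genome} (data.frame of candidate
#'   introns in region coordinates, 1-based closed) and \code{intronless}.
#' @export
align_transcript <- function(transcript, genome_region,
                             config = periscan_config(),
                             transcript_id = "transcript") {
  tx <- toupper(as.character(transcript))
  rg <- toupper(as.character(genome_region))
  if (!nzchar(tx) || !nzchar(rg)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(tx), Biostrings::DNAString(rg),
    type = "global-local",
    substitutionMatrix = nt_substitution_matrix(config$nt_match, config$nt_mismatch),
    gapOpening = abs(config$nt_gap_open), gapExtension = abs(config$nt_gap_extend))
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  sub_start <- Biostrings::start(Biostrings::subject(aln))
  ncol <- length(p)
  matches <- sum(p == s & p != "-")
  identity <- 100 * matches / ncol
  if (identity < config$identity_floor)
    stop("no confident alignment for '", transcript_id, "': identity ",
         sprintf("%.1f", identity), "% below floor ", config$identity_floor, "%")
  ## subject coordinate of each column (position of the subject base, or of
  ## the last subject base seen for subject-gap columns)
  s_pos <- cumsum(s != "-") + sub_start - 1L
  gap_runs <- rle(p == "-")
  ends <- cumsum(gap_runs$lengths)
  starts <- ends - gap_runs$lengths + 1L
  gaps <- data.frame(start = integer(0), end = integer(0), width = integer(0))
  for (k in which(gap_runs$values)) {
    g_start <- s_pos[starts[k]]
    g_end <- s_pos[ends[k]]
    gaps <- rbind(gaps, data.frame(start = g_start, end = g_end,
                                   width = ends[k] - starts[k] + 1L))
  }
  introns <- gaps[gaps$width >= config$intron_threshold, , drop = FALSE]
  rownames(introns) <- NULL
  structure(list(
    transcript_id = transcript_id,
    region = rg,
    pattern_aligned = p,
    subject_aligned = s,
    subject_start = sub_start,
    identity_pct = identity,
    genome_gaps = gaps,
    gaps_in_genome = introns,
    intronless = nrow(introns) == 0L,
    intron_threshold = config$intron_threshold), class = "transcript_alignment")
}

#' @export
print.transcript_alignment <- function(x, ...) {
  cat(sprintf("transcript_alignment '%s': identity %.1f%%, %s (%d candidate intron%s)\n",
              x$transcript_id, x$identity_pct,
              if (x$intronless) "intronless" else "spliced",
              nrow(x$gaps_in_genome), if (nrow(x$gaps_in_genome) == 1) "" else "s"))
  invisible(x)
}

#' Format a codon-level mutation name
#'
#' \code{refAA + index + altAA} for missense, \code{refAA + index + refAA
#' + " (silent)"} for silent, \code{refAA + index + "Stop"} for stop-gain.
#'
#' @param ref_aa,alt_aa one-letter residues (\code{*} = stop).
#' @param codon_index 1-based codon index (initiator Met = 1).
#' @return the mutation name.
#' @examples
#' format_mutation_name("G", 132, "*")
#' @export
format_mutation_name <- function(ref_aa, codon_index, alt_aa) {
  ifelse(alt_aa == "*", paste0(ref_aa, codon_index, "Stop"),
         ifelse(ref_aa == alt_aa, paste0(ref_aa, codon_index, ref_aa, " (silent)"),
                paste0(ref_aa, codon_index, alt_aa)))
}

translate_codon <- function(codon, initiator = FALSE) {
  if (initiator) return("M")
  aa <- unname(.codon_table()[codon])
  if (is.na(aa)) stop("untranslatable codon: ", codon)
  aa
}

empty_mutation_calls <- function() {
  data.frame(gene = character(0), codon_index = integer(0),
             ref_codon = character(0), alt_codon = character(0),
             ref_aa = character(0), alt_aa = character(0),
             name = character(0), mclass = character(0),
             stringsAsFactors = FALSE)
}

#' Call codon-level mutations from a transcript alignment
#'
#' Substitutions within the ORF span are grouped by codon; each altered
#' codon yields one call with a 1-based codon index (initiator Met =
#' codon 1). The alignment must be intronless over the ORF span, and any
#' sub-intron-threshold indel inside the ORF is a frameshift error: the
#' nomenclature covers substitutions only.
#'
#' @param alignment a \code{\link{align_transcript}} result whose
#'   \code{genome_region} contains the reference ORF.
#' @param reference_orf list or one-row data.frame with \code{start},
#'   \code{end} (ORF span in region coordinates, 1-based closed, stop codon
#'   included) and optionally \code{gene}.
#' @return data.frame of calls sorted by codon index: \code{gene},
#'   \code{codon_index}, \code{ref_codon}, \code{alt_codon}, \code{ref_aa},
#'   \code{alt_aa}, \code{name}, \code{mclass} (silent / missense /
#'   stop-gain).
#' @export
call_mutations <- function(alignment, reference_orf) {
  stopifnot(inherits(alignment, "transcript_alignment"))
  orf_start <- reference_orf$start
  orf_end <- reference_orf$end
  gene <- if (!is.null(reference_orf$gene)) reference_orf$gene else "gene"
  if ((orf_end - orf_start + 1L) %% 3 != 0)
    stop("reference ORF span is not a multiple of 3")
  introns <- alignment$gaps_in_genome
  if (nrow(introns) && any(introns$start <= orf_end & introns$end >= orf_start))
    stop("alignment is not intronless over the ORF span; cannot call codon mutations")
  small_gaps <- alignment$genome_gaps
  small_gaps <- small_gaps[small_gaps$width < alignment$intron_threshold, , drop = FALSE]
  if (nrow(small_gaps) && any(small_gaps$start <= orf_end & small_gaps$end >= orf_start))
    stop("frameshift: deletion within the ORF (indels are outside the ",
         "substitution nomenclature)")
  p <- alignment$pattern_aligned
  s <- alignment$subject_aligned
  s_pos <- cumsum(s != "-") + alignment$subject_start - 1L
  ins_in_orf <- s == "-" & s_pos >= orf_start & s_pos < orf_end
  if (any(ins_in_orf))
    stop("frameshift: insertion within the ORF (indels are outside the ",
         "substitution nomenclature)")
  subs <- which(p != s & p != "-" & s != "-" & s_pos >= orf_start & s_pos <= orf_end)
  if (!length(subs)) return(empty_mutation_calls())
  off <- s_pos[subs] - orf_start
  codon_index <- off %/% 3L + 1L
  pos_in_codon <- off %% 3L + 1L
  calls <- list()
  for (ci in sort(unique(codon_index))) {
    sel <- codon_index == ci
    codon_start <- orf_start + (ci - 1L) * 3L
    ref_codon <- substr(alignment$region, codon_start, codon_start + 2L)
    alt <- strsplit(ref_codon, "")[[1]]
    alt[pos_in_codon[sel]] <- p[subs[sel]]
    alt_codon <- paste(alt, collapse = "")
    ref_aa <- translate_codon(ref_codon, initiator = ci == 1L)
    alt_aa <- translate_codon(alt_codon)
    calls[[length(calls) + 1L]] <- data.frame(
      gene = gene, codon_index = ci, ref_codon = ref_codon,
      alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
      name = format_mutation_name(ref_aa, ci, alt_aa),
      mclass = if (alt_aa == "*") "stop-gain"
               else if (ref_aa == alt_aa) "silent" else "missense",
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, calls)
  rownames(df) <- NULL
  df
}

#' Flag motif hits lost by a truncation mutation
#'
#' For the earliest stop-gain call, every motif hit starting at or after
#' that codon is translated downstream of the premature stop and is flagged
#' as lost from the truncated product.
#'
#' @param calls mutation calls (from \code{\link{call_mutations}}).
#' @param motif_hits data.frame with a 1-based protein \code{start} column
#'   (e.g. from \code{\link{fpfp_scan}}).
#' @return \code{motif_hits} with a logical \code{lost_by_truncation}
#'   column.
#' @export
truncation_consequence <- function(calls, motif_hits) {
  stops <- calls$codon_index[calls$mclass == "stop-gain"]
  motif_hits$lost_by_truncation <-
    if (length(stops)) motif_hits$start >= min(stops) else
      rep(FALSE, nrow(motif_hits))
  motif_hits
}

#' Compare mutation catalogues across samples
#'
#' Two calls are identical when their (codon index, alt codon) match.
#' Shared calls are present in every sample; unique calls in exactly one.
#'
#' @param calls_by_sample named list of call data.frames over the same gene
#'   (at least two samples).
#' @return list with \code{shared} (calls present in all samples) and
#'   \code{unique_per_sample} (named list).
#' @export
compare_samples <- function(calls_by_sample) {
  if (length(calls_by_sample) < 2) stop("need at least two samples")
  if (is.null(names(calls_by_sample)) || any(!nzchar(names(calls_by_sample))))
    stop("samples must be named")
  genes <- unique(unlist(lapply(calls_by_sample, function(d) unique(d$gene))))
  if (length(genes) > 1)
    stop("samples cover different genes: ", paste(genes, collapse = ", "))
  keys <- lapply(calls_by_sample, function(d) paste(d$codon_index, d$alt_codon))
  all_keys <- unlist(keys, use.names = FALSE)
  shared_keys <- Reduce(intersect, keys)
  singleton_keys <- names(which(table(all_keys) == 1L))
  first <- calls_by_sample[[1]]
  shared <- first[keys[[1]] %in% shared_keys, , drop = FALSE]
  shared <- shared[order(shared$codon_index), , drop = FALSE]
  rownames(shared) <- NULL
  uniq <- lapply(seq_along(calls_by_sample), function(i) {
    d <- calls_by_sample[[i]][keys[[i]] %in% singleton_keys, , drop = FALSE]
    d <- d[order(d$codon_index), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(uniq) <- names(calls_by_sample)
  list(shared = shared, unique_per_sample = uniq)
}
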