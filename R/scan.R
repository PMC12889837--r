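## Candidate-locus scanning: centromere-flanking windows, signal-threshold
## peak calling, and the three-way intersection (window x repeat x H3K27ac
## peak) that defines a candidate pericentromeric locus.

#' Pericentromeric windows around centromeres
#'
#' For each centromere, up to two windows of width \code{flank}: one ending
#' at the centromere start and one beginning at its end, clipped to the
#' chromosome. The centromere itself is excluded. Chromosomes listed in
#' \code{chrom_sizes} without a centromere are skipped with a warning.
#'
#' @param centromeres \code{GRanges} of centromere intervals (one per
#'   chromosome).
#' @param flank window width in bp (> 0).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return \code{GRanges} of windows.
#' @export
pericentromeric_windows <- function(centromeres, flank, chrom_sizes) {
  stopifnot(flank > 0)
  cen_chrom <- as.character(GenomicRanges::seqnames(centromeres))
  missing <- setdiff(names(chrom_sizes), cen_chrom)
  if (length(missing))
    warning("no centromere annotated for: ", paste(missing, collapse = ", "),
            "; skipped")
  out <- list()
  for (i in seq_along(centromeres)) {
    chrom <- cen_chrom[i]
    if (!chrom %in% names(chrom_sizes))
      stop("centromere on unknown chromosome: ", chrom)
    len <- chrom_sizes[[chrom]]
    cs <- GenomicRanges::start(centromeres)[i]
    ce <- GenomicRanges::end(centromeres)[i]
    if (cs > 1)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = max(1L, cs - flank), end = cs - 1L)
    if (ce < len)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = ce + 1L, end = min(len, ce + flank))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, out)
  gi(df$chrom, df$start, df$end)
}

#' Call peaks on a signal track by thresholding
#'
#' Maximal runs of signal at or above \code{threshold}; runs separated by a
#' gap narrower than \code{merge_gap} are merged; merged runs narrower than
#' \code{min_width} are dropped.
#'
#' @param track \code{GRanges} with a \code{score} column (fold-change over
#'   control).
#' @param threshold signal threshold (> 0).
#' @param min_width minimum peak width, bp.
#' @param merge_gap gap below which adjacent runs merge, bp.
#' @return \code{GRanges} of peak intervals.
#' @export
call_peaks <- function(track, threshold, min_width = 200L, merge_gap = 100L) {
  stopifnot(threshold > 0, !is.null(track$score))
  hot <- track[track$score >= threshold]
  if (!length(hot)) return(GenomicRanges::GRanges())
  peaks <- GenomicRanges::reduce(unstranded(hot), min.gapwidth = max(1L, merge_gap))
  peaks[GenomicRanges::width(peaks) >= min_width]
}

max_signal_over <- function(track, region) {
  hits <- GenomicRanges::findOverlaps(region, unstranded(track), ignore.strand = TRUE)
  if (!length(hits)) return(0)
  max(track$score[S4Vectors::subjectHits(hits)])
}

#' Scan for candidate pericentromeric loci
#'
#' A candidate is a maximal interval of (H3K27ac peak) intersect (repeat
#' annotation) intersect (pericentromeric window). Each candidate carries
#' the maximum H3K27ac and H3K27me3 signal over its span and a
#' \code{competent} flag that is true when both marks reach their
#' thresholds. Competence is a flag, not a filter: loci lacking the
#' repressive mark in one cell type may carry it in another, so candidates
#' are emitted regardless and ranked by H3K27ac.
#'
#' @param windows pericentromeric windows (\code{GRanges}), from
#'   \code{\link{pericentromeric_windows}}.
#' @param repeats repeat annotation (\code{GRanges}).
#' @param h3k27ac_peaks called H3K27ac peaks (\code{GRanges}), from
#'   \code{\link{call_peaks}}.
#' @param h3k27ac_track,h3k27me3_track signal tracks (\code{GRanges} with
#'   \code{score}).
#' @param centromeres centromere intervals, used for the distance column.
#' @param config a \code{\link{periscan_config}} (thresholds).
#' @return data.frame sorted by \code{h3k27ac_max} descending with columns
#'   \code{chrom}, \code{start}, \code{end} (1-based closed),
#'   \code{distance_to_centromere} (bp, 0 if abutting),
#'   \code{h3k27ac_max}, \code{h3k27me3_max}, \code{in_repeat},
#'   \code{competent}.
#' @export
scan_candidates <- function(windows, repeats, h3k27ac_peaks,
                            h3k27ac_track, h3k27me3_track, centromeres,
                            config = periscan_config()) {
  cand <- interval_intersect(interval_intersect(h3k27ac_peaks, repeats), windows)
  if (!length(cand)) {
    ps_log("scan_candidates: 0 candidates (peaks=%d, windows=%d)",
           length(h3k27ac_peaks), length(windows))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      distance_to_centromere = integer(0),
                      h3k27ac_max = numeric(0), h3k27me3_max = numeric(0),
                      in_repeat = logical(0), competent = logical(0)))
  }
  ac_max <- vapply(seq_along(cand),
                   function(i) max_signal_over(h3k27ac_track, cand[i]), numeric(1))
  me3_max <- vapply(seq_along(cand),
                    function(i) max_signal_over(h3k27me3_track, cand[i]), numeric(1))
  dist <- as.data.frame(GenomicRanges::distanceToNearest(
    unstranded(cand), unstranded(centromeres)))$distance
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cand)),
    start = GenomicRanges::start(cand),
    end = GenomicRanges::end(cand),
    distance_to_centromere = dist,
    h3k27ac_max = ac_max,
    h3k27me3_max = me3_max,
    in_repeat = TRUE,
    competent = ac_max >= config$h3k27ac_threshold &
      me3_max >= config$h3k27me3_threshold,
    stringsAsFactors = FALSE)
  df <- df[order(-df$h3k27ac_max, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  ps_log("scan_candidates: %d candidates from %d peaks (ac>=%.2f, me3>=%.2f)",
         nrow(df), length(h3k27ac_peaks), config$h3k27ac_threshold,
         config$h3k27me3_threshold)
  df
}
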