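## Expression statistics: MRSP (maximum reads at single point) per gene
## per cell line, combined and GPS scores, C19MC integration and sorting,
## matched positive/negative group selection, the log2FC / t-test
## differential-expression screen, and delta-delta-Ct fold change.

#' Maximum reads at single point (MRSP)
#'
#' The expression level of a gene in a cell line: the maximum per-base read
#' depth over the gene's ORF interval. Order-free and monotone under added
#' reads.
#'
#' @param profile integer vector of per-base depths over the ORF
#'   (non-negative).
#' @return the maximum depth (integer-valued).
#' @examples
#' mrsp(c(0, 3, 17, 9))
#' @export
mrsp <- function(profile) {
  if (!length(profile)) stop("empty coverage profile")
  if (any(profile < 0)) stop("depths must be non-negative")
  max(profile)
}

#' Per-base depth profile of an interval from a coverage track
#'
#' Expands a run-length coverage track (bedGraph-style \code{GRanges} with
#' \code{score}) into the per-base depth vector over one interval; bases
#' not covered by any record have depth 0.
#'
#' @param track \code{GRanges} with \code{score} (depth).
#' @param interval a single-range \code{GRanges}.
#' @return integer vector of length \code{width(interval)}.
#' @export
coverage_profile <- function(track, interval) {
  stopifnot(length(interval) == 1)
  out <- numeric(GenomicRanges::width(interval))
  ## an empty track shares no seqlevels with the interval; that is a valid
  ## zero-coverage case, not a genome mismatch worth warning about
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(unstranded(interval), unstranded(track),
                                ignore.strand = TRUE))
  a <- GenomicRanges::start(interval)
  for (j in S4Vectors::subjectHits(hits)) {
    lo <- max(GenomicRanges::start(track)[j], a) - a + 1L
    hi <- min(GenomicRanges::end(track)[j], GenomicRanges::end(interval)) - a + 1L
    out[lo:hi] <- out[lo:hi] + track$score[j]
  }
  out
}

#' MRSP matrix from coverage tracks
#'
#' @param coverage named list (cell line -> coverage \code{GRanges}).
#' @param orfs data.frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based closed ORF intervals).
#' @return genes x cell lines numeric matrix of MRSP values.
#' @export
mrsp_matrix <- function(coverage, orfs) {
  m <- matrix(0, nrow(orfs), length(coverage),
              dimnames = list(orfs$gene, names(coverage)))
  for (line in names(coverage)) {
    tr <- coverage[[line]]
    for (i in seq_len(nrow(orfs))) {
      iv <- gi(orfs$chrom[i], orfs$start[i], orfs$end[i])
      m[i, line] <- mrsp(coverage_profile(tr, iv))
    }
  }
  m
}

check_in <- function(x, pool, what) {
  missing <- setdiff(x, pool)
  if (length(missing))
    stop("unknown ", what, ": ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Combined score of one gene across all cell lines
#'
#' Sum of the gene's MRSP values over every cell line in the matrix.
#'
#' @param matrix genes x cell lines expression matrix.
#' @param gene gene row label.
#' @return the combined score.
#' @export
combined_gene_score <- function(matrix, gene) {
  check_in(gene, rownames(matrix), "gene")
  sum(matrix[gene, ])
}

#' GPS score of one cell line
#'
#' Sum over the GPS-family gene rows for that cell line.
#'
#' @param matrix genes x cell lines expression matrix.
#' @param cell_line column label.
#' @param gps_genes the GPS-family rows to sum (default all rows).
#' @return the GPS score.
#' @export
gps_score <- function(matrix, cell_line, gps_genes = rownames(matrix)) {
  check_in(cell_line, colnames(matrix), "cell line")
  check_in(gps_genes, rownames(matrix), "gene")
  sum(matrix[gps_genes, cell_line])
}

#' Integrate GPS scores with cumulative C19MC miRNA expression
#'
#' Per cell line, cumulative C19MC = sum over the member miRNAs; the table
#' is sorted by cumulative C19MC descending, ties by GPS score descending,
#' then by cell line id.
#'
#' @param gps_scores named numeric vector of per-line GPS scores.
#' @param mirna_matrix miRNAs x cell lines matrix.
#' @param c19mc_members row labels of the C19MC member miRNAs.
#' @return data.frame with \code{cell_line}, \code{c19mc}, \code{gps},
#'   sorted.
#' @export
integrate_and_sort <- function(gps_scores, mirna_matrix, c19mc_members) {
  lines_g <- names(gps_scores)
  lines_m <- colnames(mirna_matrix)
  only_g <- setdiff(lines_g, lines_m)
  only_m <- setdiff(lines_m, lines_g)
  if (length(only_g) || length(only_m))
    stop("cell lines present in one input only: ",
         paste(c(only_g, only_m), collapse = ", "))
  check_in(c19mc_members, rownames(mirna_matrix), "miRNA")
  c19 <- colSums(mirna_matrix[c19mc_members, lines_g, drop = FALSE])
  df <- data.frame(cell_line = lines_g, c19mc = unname(c19),
                   gps = unname(gps_scores), stringsAsFactors = FALSE)
  df <- df[order(-df$c19mc, -df$gps, df$cell_line), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select matched positive and negative cell-line groups
#'
#' Positive group: the top \code{n} lines that express both classes of RNA
#' (cumulative C19MC above zero and GPS score above the positivity
#' threshold), ranked by cumulative C19MC. Negative group: \code{n} lines
#' expressing neither (both exactly at zero), lowest C19MC first, ties by
#' cell line id. Equal group sizes keep the downstream test balanced.
#'
#' @param sorted_table table from \code{\link{integrate_and_sort}}.
#' @param n group size (default 12).
#' @param gps_positive_threshold GPS score strictly above which a line
#'   counts as GPS-positive.
#' @return list with \code{positive} and \code{negative} character vectors
#'   of cell line ids.
#' @export
select_groups <- function(sorted_table, n = 12L, gps_positive_threshold = 0) {
  df <- sorted_table[order(-sorted_table$c19mc, -sorted_table$gps,
                           sorted_table$cell_line), , drop = FALSE]
  pos_pool <- df[df$c19mc > 0 & df$gps > gps_positive_threshold, , drop = FALSE]
  neg_pool <- df[df$c19mc == 0 & df$gps == 0, , drop = FALSE]
  if (nrow(pos_pool) < n || nrow(neg_pool) < n)
    stop("insufficient qualifying cell lines: ", nrow(pos_pool),
         " double-positive and ", nrow(neg_pool),
         " double-negative available, need ", n, " each")
  neg_pool <- neg_pool[order(neg_pool$c19mc, neg_pool$cell_line), , drop = FALSE]
  list(positive = pos_pool$cell_line[seq_len(n)],
       negative = neg_pool$cell_line[seq_len(n)])
}

#' Differential expression between the positive and negative groups
#'
#' Per gene, on \code{log2(x + 1)} values: log2 fold change = positive
#' group mean minus negative group mean; p-value from a two-sided
#' equal-variance (Student) two-sample t-test. No multiple-testing
#' correction by default; set \code{fdr = "bh"} for Benjamini-Hochberg
#' adjusted p-values in an extra column. A gene with zero variance in both
#' groups and equal means gets p = 1 (and p = 0 when such means differ).
#'
#' @param matrix genes x cell lines expression matrix (non-negative).
#' @param groups list with \code{positive} and \code{negative} cell line
#'   ids (from \code{\link{select_groups}}).
#' @param log2fc_threshold fold-change gate (absolute, log2 units).
#' @param alpha p-value gate.
#' @param fdr "none" (default) or "bh".
#' @return data.frame with \code{gene}, \code{log2fc}, \code{p_value},
#'   \code{significant_up}, \code{significant_down} (and \code{p_adj} when
#'   \code{fdr = "bh"}).
#' @export
differential_expression <- function(matrix, groups, log2fc_threshold = 2,
                                    alpha = 0.05, fdr = c("none", "bh")) {
  fdr <- match.arg(fdr)
  check_in(groups$positive, colnames(matrix), "cell line")
  check_in(groups$negative, colnames(matrix), "cell line")
  if (any(matrix < 0)) stop("expression values must be non-negative")
  lp <- log2(matrix[, groups$positive, drop = FALSE] + 1)
  ln <- log2(matrix[, groups$negative, drop = FALSE] + 1)
  res <- lapply(rownames(matrix), function(g) {
    x <- lp[g, ]; y <- ln[g, ]
    lfc <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = TRUE)$p.value
    }
    data.frame(gene = g, log2fc = lfc, p_value = p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df$significant_up <- df$log2fc > log2fc_threshold & df$p_value < alpha
  df$significant_down <- df$log2fc < -log2fc_threshold & df$p_value < alpha
  if (fdr == "bh") df$p_adj <- stats::p.adjust(df$p_value, method = "BH")
  rownames(df) <- NULL
  df
}

#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' Per target: delta-Ct = target Ct minus normalizer Ct per sample;
#' delta-delta-Ct = mean treated delta-Ct minus mean control delta-Ct;
#' fold change = 2^(-delta-delta-Ct). Controls are reported at a fold of 1.
#'
#' @param records data.frame with columns \code{target}, \code{sample},
#'   \code{target_ct}, \code{normalizer_ct}, \code{condition} ("control" or
#'   "treated"); at least one control and one treated record per target.
#' @return data.frame with \code{target}, \code{ddct}, \code{fold_change},
#'   \code{control_fold} (always 1).
#' @examples
#' recs <- data.frame(target = "miR", sample = 1:4,
#'                    target_ct = c(25, 20, 22, 20),
#'                    normalizer_ct = c(15, 15, 15, 18),
#'                    condition = c("control", "control", "treated", "treated"))
#' ddct_fold_change(recs)  # ddct -3, fold 8
#' @export
ddct_fold_change <- function(records) {
  need <- c("target", "target_ct", "normalizer_ct", "condition")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(records$normalizer_ct)))
    stop("missing normalizer Ct value")
  if (any(records$target_ct <= 0 | records$normalizer_ct <= 0))
    stop("Ct values must be positive")
  if (!all(records$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  out <- lapply(unique(records$target), function(tg) {
    d <- records[records$target == tg, , drop = FALSE]
    dct <- d$target_ct - d$normalizer_ct
    ctl <- dct[d$condition == "control"]
    trt <- dct[d$condition == "treated"]
    if (!length(ctl) || !length(trt))
      stop("target '", tg, "' needs at least one control and one treated record")
    ddct <- mean(trt) - mean(ctl)
    data.frame(target = tg, ddct = ddct, fold_change = 2^(-ddct),
               control_fold = 1, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
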