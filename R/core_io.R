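## Readers/writers for the plain-text formats the pipeline touches, plus
## shared interval arithmetic. Intervals live in GRanges (1-based, closed)
## throughout the package; the 0-based half-open convention of BED/bedGraph
## is converted at the file boundary only.

.NUC_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "*")

#' Read a FASTA file
#'
#' Sequences are upper-cased and validated against the declared alphabet
#' (A/C/G/T/N for nucleotide, the 20 one-letter amino acids plus \code{*}
#' for protein). Malformed headers, empty sequences and illegal characters
#' raise an error naming the offending line.
#'
#' @param path file path.
#' @param mode "nucleotide" or "protein".
#' @return a \code{DNAStringSet} (nucleotide) or \code{AAStringSet} (protein),
#'   in file order.
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 1 & lines == "") | seq_along(lines) == 1]
  if (!length(lines) || !startsWith(lines[[1]], ">"))
    stop("malformed FASTA (line 1): expected '>' header in ", path)
  hdr <- startsWith(lines, ">")
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, character(1), 1L)
  bad_id <- which(!nzchar(ids))
  if (length(bad_id))
    stop("malformed FASTA header (line ", which(hdr)[bad_id[1]], ") in ", path)
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1), collapse = "")
  seqs <- toupper(seqs[match(seq_along(ids), as.integer(names(seqs)))])
  empty <- which(is.na(seqs) | !nzchar(seqs))
  if (length(empty))
    stop("empty sequence for record '", ids[empty[1]], "' (line ",
         which(hdr)[empty[1]], ") in ", path)
  alphabet <- if (mode == "nucleotide") .NUC_ALPHABET else .AA_ALPHABET
  for (i in seq_along(seqs)) {
    ch <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(ch, alphabet)
    if (length(bad))
      stop("illegal character(s) ", paste(bad, collapse = ""),
           " in record '", ids[i], "' (header line ", which(hdr)[i], ") in ", path)
  }
  names(seqs) <- ids
  if (mode == "nucleotide") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param x a named \code{XStringSet} or named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' BED coordinates (0-based half-open) are converted to the package's
#' internal GRanges convention (1-based closed). A start not strictly below
#' its end is a format error.
#'
#' @param path file path.
#' @return a \code{GRanges}; strand from column 6 when present, otherwise
#'   \code{*}; column 4 becomes \code{name} metadata when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (!length(fields)) return(GenomicRanges::GRanges())
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop("BED line ", lineno[which(ncols < 3)[1]], " has fewer than 3 columns in ", path)
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0 | !nzchar(chrom))
  if (length(bad))
    stop("invalid BED interval (line ", lineno[bad[1]], ") in ", path,
         ": start must satisfy 0 <= start < end")
  strand <- rep("*", length(fields))
  has6 <- ncols >= 6
  strand[has6] <- vapply(fields[has6], `[`, character(1), 6L)
  if (!all(strand %in% c("+", "-", ".", "*")))
    stop("invalid strand value in ", path)
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  has4 <- ncols >= 4
  if (any(has4)) {
    nm <- rep(NA_character_, length(fields))
    nm[has4] <- vapply(fields[has4], `[`, character(1), 4L)
    S4Vectors::mcols(gr)$name <- nm
  }
  gr
}

#' Write a GRanges as BED
#'
#' @param gr a \code{GRanges}; a \code{name} metadata column is written as
#'   BED column 4, and strand as column 6, when present.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  nm <- S4Vectors::mcols(gr)$name
  strand <- as.character(GenomicRanges::strand(gr))
  if (all(strand == "*") && is.null(nm)) {
    out <- paste(chrom, s0, e0, sep = "\t")
  } else {
    if (is.null(nm)) nm <- "."
    strand[strand == "*"] <- "."
    out <- paste(chrom, s0, e0, nm, 0L, strand, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' The track is validated as a fold-change-over-control signal: values must
#' be non-negative and per-chromosome intervals must not overlap
#' (overlapping records are a format error, not summed — these are signal
#' tracks, not fragment piles). Records are returned sorted by
#' (chromosome, start).
#'
#' @param path file path.
#' @return a \code{GRanges} with a numeric \code{score} column.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (!length(fields))
    return(GenomicRanges::GRanges(score = numeric(0)))
  if (any(lengths(fields) < 4))
    stop("bedGraph line ", lineno[which(lengths(fields) < 4)[1]],
         " has fewer than 4 columns in ", path)
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("invalid bedGraph interval (line ", lineno[bad[1]], ") in ", path)
  neg <- which(is.na(value) | value < 0)
  if (length(neg))
    stop("invalid signal value (line ", lineno[neg[1]], ") in ", path,
         ": fold-change values must be non-negative numbers")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               score = value)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (sum(GenomicRanges::countOverlaps(gr, gr)) > length(gr))
    stop("overlapping intervals within one chromosome in ", path,
         " (signal tracks must tile, not pile)")
  gr
}

#' Write a signal track as bedGraph
#'
#' @param track a \code{GRanges} with a \code{score} column.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(!is.null(track$score))
  track <- GenomicRanges::sort(track, ignore.strand = TRUE)
  writeLines(paste(as.character(GenomicRanges::seqnames(track)),
                   GenomicRanges::start(track) - 1L,
                   GenomicRanges::end(track),
                   format(track$score, trim = TRUE, scientific = FALSE),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Read/write a labelled numeric matrix as TSV
#'
#' Header row = column labels; first column = row labels. Used for
#' expression matrices (genes or miRNAs by cell lines).
#'
#' @param path file path.
#' @return \code{read_matrix_tsv}: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing or non-numeric cells in ", path)
  m
}

#' @param m numeric matrix with dimnames.
#' @param label name for the row-label column header.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect two interval sets
#'
#' Returns the maximal intervals covered by both sets (strand-blind,
#' half-open touch does not count as overlap). Commutative; intersecting a
#' set with itself returns the set merged to maximal intervals.
#'
#' @param a,b \code{GRanges}.
#' @return a \code{GRanges} of the intersection.
#' @export
interval_intersect <- function(a, b) {
  GenomicRanges::intersect(unstranded(a), unstranded(b), ignore.strand = TRUE)
}

unstranded <- function(gr) {
  GenomicRanges::strand(gr) <- "*"
  gr
}

## 1-based closed GRanges constructor used throughout tests and generators.
gi <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand, ...)
}
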