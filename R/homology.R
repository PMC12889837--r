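## Family-level homology: pairwise global alignment identity, UPGMA
## cladograms with Newick output, conserved-window scoring and exact
## FPFP-motif scanning.

as_named_character <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch with affine gaps; nucleotide mode uses the configured
#' match/mismatch scores, protein mode BLOSUM62. Identity is matches
#' divided by aligned columns (a global alignment has no columns where both
#' sequences carry terminal gaps) and is therefore independent of the
#' scoring used to produce the alignment only up to alignment choice.
#'
#' @param a,b sequences (character or \code{XString}).
#' @param mode "nucleotide" or "protein".
#' @param config a \code{\link{periscan_config}} (scoring).
#' @return list with \code{aligned_a}, \code{aligned_b}, \code{score} and
#'   \code{identity_pct}.
#' @export
global_align <- function(a, b, mode = c("nucleotide", "protein"),
                         config = periscan_config()) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (mode == "nucleotide") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = nt_substitution_matrix(config$nt_match, config$nt_mismatch),
      gapOpening = abs(config$nt_gap_open), gapExtension = abs(config$nt_gap_extend))
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = abs(config$aa_gap_open), gapExtension = abs(config$aa_gap_extend))
  }
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  pav <- strsplit(pa, "")[[1]]
  pbv <- strsplit(pb, "")[[1]]
  list(aligned_a = pa, aligned_b = pb, score = Biostrings::score(aln),
       identity_pct = 100 * sum(pav == pbv & pav != "-") / length(pav))
}

#' Pairwise percent-identity matrix over a sequence family
#'
#' @param family named sequences (\code{XStringSet} or named character),
#'   at least two, labels unique.
#' @inheritParams global_align
#' @return symmetric numeric matrix in [0, 100] with 100 on the diagonal,
#'   dimnames = family labels.
#' @export
identity_matrix <- function(family, mode = c("nucleotide", "protein"),
                            config = periscan_config()) {
  mode <- match.arg(mode)
  seqs <- as_named_character(family)
  if (length(seqs) < 2) stop("need at least two sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- global_align(seqs[[i]], seqs[[j]], mode, config)$identity_pct
      m[i, j] <- id
      m[j, i] <- id
    }
  }
  m
}

#' UPGMA cladogram from an identity matrix
#'
#' Average-linkage (UPGMA) clustering on distance 100 - identity, with
#' branch lengths in distance units (leaf-to-merge height = d/2, so the
#' tree is ultrametric). Ties are broken deterministically by merging the
#' pair whose smallest member label is lexicographically first.
#'
#' @param m identity matrix from \code{\link{identity_matrix}} (or any
#'   symmetric percent-identity matrix with 100 on the diagonal).
#' @return list with \code{tree} (an \pkg{ape} \code{phylo}),
#'   \code{newick} (Newick text with branch lengths) and \code{heights}
#'   (merge heights, ascending).
#' @export
upgma_tree <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2)
  if (max(abs(m - t(m))) > 1e-8) stop("identity matrix must be symmetric")
  if (any(abs(diag(m) - 100) > 1e-8)) stop("identity matrix diagonal must be 100")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(m)))
  d <- (100 - m)
  clusters <- lapply(seq_along(labels), function(i)
    list(newick = labels[i], height = 0, size = 1L, label = labels[i]))
  dist <- d
  dimnames(dist) <- NULL
  active <- seq_along(labels)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- NULL; best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        dij <- dist[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-12) {
          cand <- sort(c(clusters[[i]]$label, clusters[[j]]$label))
          incumbent <- sort(c(clusters[[best[1]]]$label, clusters[[best[2]]]$label))
          if (cand[1] < incumbent[1] ||
              (cand[1] == incumbent[1] && cand[2] < incumbent[2]))
            best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    heights <- c(heights, h)
    bl_i <- h - clusters[[i]]$height
    bl_j <- h - clusters[[j]]$height
    merged <- list(
      newick = sprintf("(%s:%.10g,%s:%.10g)", clusters[[i]]$newick, bl_i,
                       clusters[[j]]$newick, bl_j),
      height = h,
      size = clusters[[i]]$size + clusters[[j]]$size,
      label = min(clusters[[i]]$label, clusters[[j]]$label))
    ni <- clusters[[i]]$size; nj <- clusters[[j]]$size
    for (k in active) {
      if (k == i || k == j) next
      dnew <- (ni * dist[i, k] + nj * dist[j, k]) / (ni + nj)
      dist[i, k] <- dnew; dist[k, i] <- dnew
    }
    clusters[[i]] <- merged
    active <- setdiff(active, j)
  }
  newick <- paste0(clusters[[active]]$newick, ";")
  list(tree = ape::read.tree(text = newick), newick = newick, heights = heights)
}

#' Conserved-window scan over a protein family
#'
#' Slides windows of length \code{window_min} to \code{window_max} along an
#' anchor sequence; for each window, conservation is the fraction of the
#' other family members containing a same-length substring matching at a
#' scaled minimum of \code{window_min_matches} identical positions (10/12
#' by default). Windows at or above \code{conservation_fraction} are hits;
#' overlapping hits merge into maximal spans. Members shorter than a window
#' count as non-matching for it.
#'
#' @param proteins named protein sequences (\code{AAStringSet} or named
#'   character), at least two.
#' @param config a \code{\link{periscan_config}}.
#' @param anchor index or name of the anchor sequence (default the first
#'   member).
#' @return data.frame of merged hits: \code{seq_id} (anchor), \code{start},
#'   \code{end} (1-based on the anchor), \code{window} (anchor substring),
#'   \code{conservation} (best window conservation within the span).
#' @export
conserved_windows <- function(proteins, config = periscan_config(), anchor = 1L) {
  seqs <- as_named_character(proteins)
  if (length(seqs) < 2) stop("need at least two proteins")
  if (is.character(anchor)) anchor <- match(anchor, names(seqs))
  if (is.na(anchor) || anchor < 1 || anchor > length(seqs))
    stop("anchor not found in family")
  anc <- strsplit(seqs[[anchor]], "")[[1]]
  others <- lapply(seqs[-anchor], function(s) strsplit(s, "")[[1]])
  wmin <- config$window_min; wmax <- config$window_max
  hits <- list()
  for (w in wmin:wmax) {
    min_matches <- ceiling(config$window_min_matches * w / wmin)
    if (length(anc) < w) next
    n_pos <- length(anc) - w + 1L
    ## straightforward loop (families here are a handful of sequences)
    member_best <- matrix(0L, n_pos, length(others))
    for (mi in seq_along(others)) {
      mv <- others[[mi]]
      Lm <- length(mv)
      if (Lm < w) next
      n_off <- Lm - w + 1L
      for (p in seq_len(n_pos)) {
        wv <- anc[p:(p + w - 1L)]
        bm <- 0L
        for (o in seq_len(n_off)) {
          mcount <- sum(wv == mv[o:(o + w - 1L)])
          if (mcount > bm) bm <- mcount
          if (bm >= w) break
        }
        member_best[p, mi] <- bm
      }
    }
    conservation <- rowMeans(member_best >= min_matches)
    hit_pos <- which(conservation >= config$conservation_fraction)
    for (p in hit_pos)
      hits[[length(hits) + 1L]] <- data.frame(start = p, end = p + w - 1L,
                                              conservation = conservation[p])
  }
  if (!length(hits))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), window = character(0),
                      conservation = numeric(0), stringsAsFactors = FALSE))
  hdf <- do.call(rbind, hits)
  ir <- IRanges::reduce(IRanges::IRanges(hdf$start, hdf$end))
  merged <- data.frame(
    seq_id = names(seqs)[anchor],
    start = IRanges::start(ir), end = IRanges::end(ir),
    stringsAsFactors = FALSE)
  merged$window <- substring(seqs[[anchor]], merged$start, merged$end)
  merged$conservation <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- hdf$start >= merged$start[i] & hdf$end <= merged$end[i]
    max(hdf$conservation[sel])
  }, numeric(1))
  merged
}

#' Exact FPFP motif scan
#'
#' Every exact occurrence of the motif (default the four-residue
#' Phe-Pro-Phe-Pro), overlaps allowed: "FPFPFP" hits at 1 and 3.
#'
#' @param protein protein sequence, or named sequence (name used as
#'   \code{seq_id}).
#' @param motif motif to scan for.
#' @return data.frame with \code{seq_id}, \code{start} (1-based),
#'   \code{window}.
#' @export
fpfp_scan <- function(protein, motif = "FPFP") {
  id <- if (!is.null(names(protein)) && nzchar(names(protein)[1]))
    names(protein)[1] else "protein"
  s <- toupper(as.character(protein)[1])
  starts <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  if (starts[1] == -1)
    return(data.frame(seq_id = character(0), start = integer(0),
                      window = character(0), stringsAsFactors = FALSE))
  data.frame(seq_id = id, start = as.integer(starts), window = motif,
             stringsAsFactors = FALSE)
}
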