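#' Pipeline configuration
#'
#' A single flat key-value list holds every tunable of the pipeline, each
#' with a default. Unknown keys are rejected so that typos in a config file
#' fail loudly rather than silently falling back to a default.
#'
#' Key groups:
#' \describe{
#'   \item{scan}{\code{flank} (bp searched on either side of a centromere),
#'     \code{h3k27ac_threshold} / \code{h3k27me3_threshold} (fold-change over
#'     control), \code{min_peak_width}, \code{merge_gap}, \code{candidate_pad}.}
#'   \item{orf}{\code{min_orf_length} (nt, stop included), \code{start_codons}.}
#'   \item{alignment}{nucleotide \code{nt_match}/\code{nt_mismatch}/
#'     \code{nt_gap_open}/\code{nt_gap_extend}; protein
#'     \code{aa_gap_open}/\code{aa_gap_extend} (BLOSUM62 substitution).}
#'   \item{transcript}{\code{intron_threshold} (nt of genome-side gap that
#'     counts as an intron), \code{identity_floor} (percent).}
#'   \item{annotation}{\code{enrichment_cutoff} (ratio over background).}
#'   \item{homology}{\code{window_min}, \code{window_max} (aa),
#'     \code{window_min_matches} (matches required out of \code{window_min}),
#'     \code{conservation_fraction}.}
#'   \item{expression}{\code{de_log2fc}, \code{de_alpha}, \code{n_per_group},
#'     \code{gps_positive_threshold}.}
#'   \item{synthetic}{toy-genome scale and planting parameters, see
#'     \code{\link{generate_genome}}.}
#' }
#'
#' @param ... name = value overrides of the defaults.
#' @param file optional path to a flat \code{key<TAB>value} (or
#'   \code{key=value}) text file applied before \code{...}.
#' @return named list of settings with class \code{"periscan_config"}.
#' @examples
#' cfg <- periscan_config(min_orf_length = 150)
#' cfg$min_orf_length
#' @export
periscan_config <- function(..., file = NULL) {
  defaults <- list(
    ## pericentromere scan
    flank              = 2e6,
    h3k27ac_threshold  = 2.0,
    h3k27me3_threshold = 2.0,
    min_peak_width     = 200L,
    merge_gap          = 100L,
    candidate_pad      = 1000L,
    ## ORF discovery
    min_orf_length     = 300L,
    start_codons       = c("ATG", "CTG", "GTG", "TTG"),
    ## nucleotide alignment (transcript-to-genome and nucleotide homology)
    nt_match           = 2,
    nt_mismatch        = -3,
    nt_gap_open        = -5,
    nt_gap_extend      = -2,
    ## protein alignment (BLOSUM62)
    aa_gap_open        = -11,
    aa_gap_extend      = -1,
    ## transcript / splicing
    intron_threshold   = 20L,
    identity_floor     = 70,
    ## protein annotation
    enrichment_cutoff  = 1.5,
    ## conserved-window scan
    window_min            = 12L,
    window_max            = 13L,
    window_min_matches    = 10L,
    conservation_fraction = 0.8,
    ## expression / differential expression
    de_log2fc              = 2,
    de_alpha               = 0.05,
    n_per_group            = 12L,
    gps_positive_threshold = 0,
    ## synthetic toy genome
    n_chromosomes       = 3L,
    chrom_length        = 300000L,
    centromere_length   = 30000L,
    repeat_flank        = 50000L,
    planted_orf_nt      = c(624L, 792L, 450L, 900L),
    decoy_orf_nt        = 453L,
    signal_bin          = 50L,
    peak_pad            = 200L,
    peak_amplitude      = 5,
    signal_noise        = TRUE,
    transcript_flank    = 60L,
    transcript_samples  = c("lineA", "lineB"),
    plant_mutations     = TRUE,
    n_cell_lines        = 100L,
    n_background_genes  = 50L,
    seed                = 1L
  )
  overrides <- list(...)
  if (!is.null(file)) {
    overrides <- c(read_config_file(file), overrides)
    overrides <- overrides[!duplicated(names(overrides), fromLast = TRUE)]
  }
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults[nm] <- overrides
  }
  structure(defaults, class = "periscan_config")
}

#' Toy-scale configuration for the synthetic genome
#'
#' Same keys as \code{\link{periscan_config}} with the scan flank scaled to
#' the toy genome (the pericentromeric window equals the 50 kb repeat flank,
#' so planted loci fall inside it and the decoy outside).
#'
#' @param ... overrides forwarded to \code{\link{periscan_config}}.
#' @return a \code{periscan_config}.
#' @export
toy_config <- function(...) {
  periscan_config(flank = 50000L, ...)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", perl = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @export
print.periscan_config <- function(x, ...) {
  cat("periscan configuration (", length(x), " keys)\n", sep = "")
  for (k in names(x))
    cat(sprintf("  %-24s %s\n", k, paste(format(x[[k]]), collapse = ",")))
  invisible(x)
}

## ---- logging ---------------------------------------------------------------

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L)

#' Set pipeline log verbosity
#'
#' @param level one of "DEBUG", "INFO", "WARN".
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("INFO", "DEBUG", "WARN")) {
  level <- match.arg(level)
  old <- getOption("periscan.log_level", "INFO")
  options(periscan.log_level = level)
  invisible(old)
}

ps_log <- function(fmt, ..., level = "INFO") {
  threshold <- .log_levels[[getOption("periscan.log_level", "INFO")]]
  if (.log_levels[[level]] >= threshold)
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
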