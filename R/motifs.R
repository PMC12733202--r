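#' Global pairwise alignment of a query against the reference
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (a gap of length k costs `gap_open + gap_extend * k`), computed with
#' `Biostrings::pairwiseAlignment()`. Percent identity is the number of
#' identical aligned columns divided by the number of columns containing at
#' least one residue (in a pairwise global alignment that is every column),
#' times 100.
#'
#' @param query,reference Nonempty amino-acid sequence strings.
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 10 and 0.5).
#' @return Object of class `pairwise_alignment`: list with `query_aln`,
#'   `ref_aln` (equal-length gapped strings, gap = `-`), `score`,
#'   `percent_identity`.
#' @examples
#' global_align("ACDE", "ACE")
#' @export
global_align <- function(query, reference, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(query) || !nzchar(reference)) {
    stop("validation error: empty sequence in global_align()")
  }
  mat <- get(data(list = substitution, package = "Biostrings",
                  envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  q <- as.character(Biostrings::alignedPattern(aln))
  r <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  informative <- qc != "-" | rc != "-"
  pid <- 100 * sum(qc == rc & qc != "-") / sum(informative)
  structure(list(query_aln = unname(q), ref_aln = unname(r),
                 score = Biostrings::score(aln),
                 percent_identity = pid),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score ", format(x$score), ", identity ",
      sprintf("%.1f%%", x$percent_identity), ")\n", sep = "")
  cat("  query: ", x$query_aln, "\n  ref:   ", x$ref_aln, "\n", sep = "")
  invisible(x)
}

#' Extract motif windows from a reference-anchored alignment
#'
#' For each annotated reference motif, takes all query residues in the
#' alignment columns spanning the motif's first through last reference
#' residue, including insertion columns strictly inside that span.
#' Deletions shorten the window (possibly to the empty string); a window
#' whose length differs from the motif's canonical length is flagged
#' `length_deviant` and excluded from positional statistics downstream.
#'
#' @param alignment `pairwise_alignment` of a query against the annotated
#'   reference ([global_align()]).
#' @param annotation Motif annotation data frame with columns `motif_id`,
#'   `start`, `end`, `canonical_length` (1-based inclusive reference
#'   coordinates); see [derive_motif_annotation()].
#' @param protein_id Query identifier carried into the instances.
#' @return Data frame `motif_id`, `protein_id`, `window`, `length`,
#'   `length_deviant`, one row per annotated motif.
#' @export
extract_motifs <- function(alignment, annotation, protein_id = NA) {
  rc <- strsplit(alignment$ref_aln, "", fixed = TRUE)[[1L]]
  qc <- strsplit(alignment$query_aln, "", fixed = TRUE)[[1L]]
  ref_len <- sum(rc != "-")
  refpos <- cumsum(rc != "-")         # reference position of each column
  rows <- lapply(seq_len(nrow(annotation)), function(k) {
    s <- annotation$start[[k]]
    e <- annotation$end[[k]]
    if (s < 1L || e > ref_len) {
      stop("validation error: motif ", annotation$motif_id[[k]],
           " coordinates [", s, ",", e, "] outside reference length ", ref_len)
    }
    first <- which(refpos == s & rc != "-")[1L]
    last <- tail(which(refpos == e & rc != "-"), 1L)
    window_chars <- qc[first:last]
    window <- paste(window_chars[window_chars != "-"], collapse = "")
    data.frame(motif_id = annotation$motif_id[[k]],
               protein_id = protein_id,
               window = window,
               length = nchar(window),
               length_deviant = nchar(window) != annotation$canonical_length[[k]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-position amino-acid predominance of a motif
#'
#' Computes the percentage predominance of each residue at each motif
#' position over the canonical-length instances (length-deviant instances,
#' and instances containing the unknown residue `X`, are excluded from the
#' counted set). Percentages at each position are computed assuming the
#' total number of counted amino acids is 100%. The consensus pattern lists,
#' per position, the residues contributing strictly more than 10%, as
#' `R(pct)` terms joined by `/`, positions joined by `-`; percentages are
#' rounded to the nearest integer after thresholding. A position where one
#' residue reaches 100% is flagged fully conserved.
#'
#' @param instances Motif-instance data frame ([extract_motifs()]) for one
#'   motif (rows with other `motif_id`s are an error).
#' @param canonical_length Expected instance length; defaults to the modal
#'   non-deviant length in `instances`.
#' @param display_threshold Display cut-off in percent (default 10,
#'   strictly-greater-than).
#' @return Object of class `motif_consensus`: list with `motif_id`,
#'   `n_counted`, `position_freq` (positions x 20 percentage matrix),
#'   `position_counts`, `consensus_pattern`, `fully_conserved`.
#' @export
position_frequencies <- function(instances, canonical_length = NULL,
                                 display_threshold = 10) {
  motif_id <- unique(instances$motif_id)
  if (length(motif_id) != 1L) {
    stop("validation error: position_frequencies() expects one motif, got: ",
         paste(motif_id, collapse = ", "))
  }
  if (is.null(canonical_length)) {
    ok <- instances$length[!instances$length_deviant]
    if (length(ok) == 0L) {
      stop("validation error: motif ", motif_id,
           " has no canonical-length instances")
    }
    canonical_length <- ok[[1L]]
  }
  windows <- instances$window[instances$length == canonical_length &
                                !grepl("X", instances$window, fixed = TRUE)]
  n <- length(windows)
  if (n == 0L) {
    stop("validation error: motif ", motif_id,
         " has no canonical-length instances")
  }
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  counts <- t(apply(mat, 2L, function(col) {
    tabulate(factor(col, levels = AA20), nbins = 20L)
  }))
  dimnames(counts) <- list(paste0("pos", seq_len(canonical_length)), AA20)
  freq <- counts / n * 100
  structure(list(motif_id = motif_id,
                 n_counted = n,
                 position_freq = freq,
                 position_counts = counts,
                 consensus_pattern = consensus_pattern(freq, display_threshold),
                 fully_conserved = apply(freq, 1L,
                                         function(x) any(x >= 100 - 1e-9))),
            class = "motif_consensus")
}

#' Format a consensus pattern from a position-frequency matrix
#'
#' @param freq Positions x 20 percentage matrix (rows sum to 100).
#' @param display_threshold Strictly-greater-than display cut-off in percent.
#' @return Consensus string, e.g. `"L(95)-L(95)-S(85)-L(54)/M(21)-L(92)"`.
#' @export
consensus_pattern <- function(freq, display_threshold = 10) {
  per_pos <- apply(freq, 1L, function(x) {
    shown <- x[x > display_threshold]
    shown <- shown[order(-shown, names(shown))]
    if (length(shown) == 0L) return(".")
    paste(sprintf("%s(%d)", names(shown), as.integer(round(shown))),
          collapse = "/")
  })
  paste(per_pos, collapse = "-")
}

#' @export
print.motif_consensus <- function(x, ...) {
  cat(x$motif_id, " (n = ", x$n_counted, "): ", x$consensus_pattern, "\n",
      sep = "")
  invisible(x)
}

#' Export a position-frequency matrix as TSV
#'
#' Writes the per-position residue table of a motif consensus: rows are
#' motif positions, columns the 20 canonical residues, values either
#' percentages (rows sum to 100) or raw instance counts.
#'
#' @param consensus `motif_consensus` from [position_frequencies()].
#' @param path Output TSV path.
#' @param what `"percent"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
export_pfm <- function(consensus, path, what = c("percent", "counts")) {
  what <- match.arg(what)
  mat <- switch(what, percent = consensus$position_freq,
                counts = consensus$position_counts)
  df <- data.frame(pos = seq_len(nrow(mat)), mat, check.names = FALSE)
  write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a position-frequency matrix written by [export_pfm()]
#'
#' @param path TSV path.
#' @return Numeric matrix, positions x 20 residues.
#' @export
read_pfm <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(tab[, AA20, drop = FALSE])
  rownames(mat) <- paste0("pos", tab$pos)
  mat
}

#' De novo scan for canonical LxxLL and PxxP motifs
#'
#' Finds all (1-based) start positions of the wildcard patterns `L..LL` and
#' `P..P` in a sequence, allowing overlapping matches, and additionally
#' reports the match count obtained by a greedy left-to-right sweep in
#' which consecutive matches may share at most their boundary residue (so
#' the tandem `LxxLLxxLL` counts as two `LxxLL` boxes).
#'
#' @param sequence Nonempty amino-acid sequence string.
#' @return List with elements `LxxLL` and `PxxP`, each a list of `starts`
#'   (integer vector of all, possibly overlapping, match starts),
#'   `n_overlapping`, and `n_greedy`.
#' @examples
#' scan_denovo("PAAPAAP")$PxxP
#' @export
scan_denovo <- function(sequence) {
  if (!nzchar(sequence)) {
    stop("validation error: empty sequence in scan_denovo()")
  }
  one <- function(pattern, width) {
    m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1L]]
    starts <- as.integer(m[m > 0L])
    greedy <- 0L
    last_end <- 0L
    for (s in starts) {
      if (s >= last_end) {  # a shared boundary residue is allowed
        greedy <- greedy + 1L
        last_end <- s + width - 1L
      }
    }
    list(starts = starts, n_overlapping = length(starts), n_greedy = greedy)
  }
  list(LxxLL = one("L..LL", 5L), PxxP = one("P..P", 4L))
}
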