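# Motif ids in N-to-C order along the reference RIX1 region. LM motifs are
# canonical 5-residue LxxLL nuclear-receptor boxes except LM5, a 9-residue
# tandem LxxLLxxLL; PM motifs are 4-residue PxxP.
MOTIF_ID_ORDER <- c("LM1", "PM1", "PM2", "LM2", "LM3", "LM4", "LM5",
                    "LM6", "LM7", "LM8", "LM9", "PM3", "LM10", "LM11")

motif_canonical_length <- function(motif_id) {
  ifelse(motif_id == "LM5", 9L, ifelse(startsWith(motif_id, "LM"), 5L, 4L))
}

#' Synthetic PELP1-like reference protein
#'
#' A deterministic, fully synthetic stand-in for a PELP1 reference sequence:
#' an N-terminal region carrying the canonical eleven LxxLL and three PxxP
#' motifs in their N-to-C order (with LM5 as the 9-residue tandem
#' LxxLLxxLL), separated by leucine/proline-free spacers so that pattern
#' scanning recovers exactly the annotated motifs, followed by a
#' glutamic-acid-rich low-complexity C-terminal tail. It is *not* the human
#' PELP1 sequence; it reproduces its motif architecture for testing and
#' simulation.
#'
#' @param tail_length Length of the C-terminal tail (default 500).
#' @return List with `sequence` (character string) and `annotation` (motif
#'   annotation data frame: `motif_id`, `start`, `end`, `canonical_length`).
#' @examples
#' ref <- synthetic_reference()
#' ref$annotation
#' @export
synthetic_reference <- function(tail_length = 500L) {
  spacer <- "GSNQTAGH"                       # no L, no P: cannot seed motifs
  windows <- c(LM1 = "LRSLL", PM1 = "PVHP", PM2 = "PEHP", LM2 = "LMALL",
               LM3 = "LLSLL", LM4 = "LRDLL", LM5 = "LPGLLTSLL",
               LM6 = "LHSLL", LM7 = "LHSLL", LM8 = "LRMLL", LM9 = "LTHLL",
               PM3 = "PSAP", LM10 = "LYRLL", LM11 = "LALLL")
  windows <- windows[MOTIF_ID_ORDER]
  lead <- paste0("M", strrep(spacer, 2L))
  pieces <- character(0L)
  starts <- integer(length(windows))
  pos <- nchar(lead) + 1L
  for (k in seq_along(windows)) {
    starts[[k]] <- pos
    pieces <- c(pieces, windows[[k]], spacer)
    pos <- pos + nchar(windows[[k]]) + nchar(spacer)
  }
  tail_unit <- "ESEDQCESEDT"                 # E/D-rich tail, no L, no P
  tail <- substr(strrep(tail_unit, ceiling(tail_length / nchar(tail_unit))),
                 1L, tail_length)
  sequence <- paste0(lead, paste(pieces, collapse = ""), tail)
  annotation <- data.frame(
    motif_id = MOTIF_ID_ORDER,
    start = starts,
    end = starts + nchar(windows) - 1L,
    canonical_length = nchar(windows),
    stringsAsFactors = FALSE)
  list(sequence = sequence, annotation = annotation)
}

#' Derive a motif annotation by scanning a reference sequence
#'
#' Greedy N-to-C scan of the reference for the canonical wildcard patterns,
#' trying at each position the 9-residue tandem `L..LL..LL` first, then
#' `L..LL`, then `P..P`, and consuming each match. The scan must yield
#' exactly fourteen motifs whose L/P types match the canonical order
#' (LM1, PM1, PM2, LM2, ..., PM3, LM10, LM11, with the single 9-mer as
#' LM5); otherwise an explicit annotation file must be supplied via
#' [read_motif_annotation()].
#'
#' @param reference Reference amino-acid sequence string.
#' @return Motif annotation data frame (`motif_id`, `start`, `end`,
#'   `canonical_length`).
#' @export
derive_motif_annotation <- function(reference) {
  chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  found <- list()
  i <- 1L
  is_m <- function(at, pat) {
    end <- at + nchar(pat) - 1L
    end <= n && grepl(paste0("^", pat), paste(chars[at:end], collapse = ""))
  }
  while (i <= n) {
    if (is_m(i, "L..LL..LL")) {
      found[[length(found) + 1L]] <- list(type = "LM9", start = i, len = 9L)
      i <- i + 9L
    } else if (is_m(i, "L..LL")) {
      found[[length(found) + 1L]] <- list(type = "LM", start = i, len = 5L)
      i <- i + 5L
    } else if (is_m(i, "P..P")) {
      found[[length(found) + 1L]] <- list(type = "PM", start = i, len = 4L)
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  expected_type <- ifelse(MOTIF_ID_ORDER == "LM5", "LM9",
                          substr(MOTIF_ID_ORDER, 1L, 2L))
  types <- vapply(found, `[[`, character(1L), "type")
  if (length(found) != 14L || !all(types == expected_type)) {
    stop("validation error: reference scan found ", length(found),
         " motif(s) with type order [", paste(types, collapse = ","),
         "]; expected the canonical 14-motif order. ",
         "Supply an explicit annotation with read_motif_annotation().")
  }
  starts <- vapply(found, `[[`, integer(1L), "start")
  lens <- vapply(found, `[[`, integer(1L), "len")
  out <- data.frame(motif_id = MOTIF_ID_ORDER, start = starts,
                    end = starts + lens - 1L, canonical_length = lens,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a motif annotation table
#'
#' Reads a TSV with columns `motif_id`, `start`, `end` (1-based inclusive
#' reference coordinates). The canonical length is `end - start + 1`; for
#' the known motif ids it must equal 5 (LM), 9 (LM5) or 4 (PM).
#'
#' @param path TSV path.
#' @return Motif annotation data frame.
#' @export
read_motif_annotation <- function(path) {
  if (!file.exists(path)) {
    stop("input error: motif annotation file not found: ", path)
  }
  tab <- read.delim(path, header = TRUE, sep = "\t")
  required <- c("motif_id", "start", "end")
  if (!all(required %in% names(tab))) {
    stop("validation error: annotation needs columns motif_id, start, end")
  }
  out <- data.frame(motif_id = as.character(tab$motif_id),
                    start = as.integer(tab$start), end = as.integer(tab$end),
                    stringsAsFactors = FALSE)
  out$canonical_length <- out$end - out$start + 1L
  known <- out$motif_id %in% MOTIF_ID_ORDER
  want <- motif_canonical_length(out$motif_id[known])
  if (any(out$canonical_length[known] != want)) {
    bad <- out$motif_id[known][out$canonical_length[known] != want]
    stop("validation error: wrong span length for motif(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(out$start < 1L | out$end < out$start)) {
    stop("validation error: invalid motif coordinates")
  }
  out
}
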