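# Inclusive fold-change threshold for an enrichment call. A small epsilon
# absorbs floating-point division error so that an observed/background ratio
# that is exactly 1.5 in real arithmetic is always called enriched.
ENRICH_THRESHOLD <- 1.5
ENRICH_EPS <- 1e-9

#' Read a background amino-acid frequency table
#'
#' Reads a two-column TSV (`residue`, `frequency`) giving the expected
#' proteome-wide frequency of each of the 20 canonical residues, as fractions
#' in (0, 1). Lines starting with `#` are treated as provenance comments and
#' kept in the `provenance` attribute. Frequencies are renormalised to sum
#' exactly to 1; a deviation larger than 1e-2 before renormalisation is an
#' error (it indicates percentages rather than fractions).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of length 20 (names `AA20`), summing to 1,
#'   with a `provenance` attribute.
#' @export
read_background <- function(path) {
  if (!file.exists(path)) {
    stop("input error: background table not found: ", path)
  }
  lines <- readLines(path)
  prov <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  tab <- read.delim(textConnection(lines[!startsWith(lines, "#")]),
                    header = TRUE, sep = "\t")
  if (!all(c("residue", "frequency") %in% names(tab))) {
    stop("validation error: background table needs columns residue, frequency")
  }
  bg <- setNames(as.numeric(tab$frequency), as.character(tab$residue))
  missing <- setdiff(AA20, names(bg))
  if (length(missing) > 0L) {
    stop("validation error: background table missing residues: ",
         paste(missing, collapse = ", "))
  }
  bg <- bg[AA20]
  if (any(!is.finite(bg) | bg <= 0)) {
    stop("validation error: background frequencies must be positive")
  }
  if (abs(sum(bg) - 1) > 1e-2) {
    stop("validation error: background frequencies sum to ", sum(bg),
         "; expected fractions summing to ~1")
  }
  bg <- bg / sum(bg)
  attr(bg, "provenance") <- paste(prov, collapse = "; ")
  bg
}

#' Packaged default background frequencies
#'
#' Amino-acid background frequencies from the UniProtKB/Swiss-Prot release
#' composition statistics, shipped with the package as
#' `extdata/background_swissprot.tsv`. Used as the default expected
#' frequency table for fold-change enrichment.
#'
#' @return Named numeric vector as from [read_background()].
#' @export
default_background <- function() {
  read_background(system.file("extdata", "background_swissprot.tsv",
                              package = "pelpscope", mustWork = TRUE))
}

#' Amino-acid composition and enrichment profile of one protein
#'
#' Counts each canonical residue (the unknown residue `X` is excluded from
#' both numerator and denominator), computes percentage composition,
#' fold-change against the background (`observed frequency / expected
#' frequency`), log2 fold-change (undefined, `NA`, where the count is zero),
#' an enrichment call at fold-change >= 1.5 (inclusive), and contribution
#' ranks over all 20 residues (rank 1 = highest percentage; ties get the
#' mean of the tied rank positions).
#'
#' @param sequence Amino-acid sequence string (or a one-row cohort data
#'   frame, in which case `protein_id` defaults to its id).
#' @param bg Background frequencies ([read_background()],
#'   [default_background()]).
#' @param protein_id Identifier carried into the profile.
#' @return Object of class `composition_profile`: a list with `protein_id`,
#'   `counts`, `length_counted`, `percentage`, `fold_change`, `log2_fc`,
#'   `enriched`, `ranks` (all residue-named length-20 vectors).
#' @examples
#' p <- compose("PPPPELLE", default_background(), "demo")
#' p$fold_change[c("P", "E", "L")]
#' @export
compose <- function(sequence, bg = default_background(), protein_id = NA) {
  if (is.data.frame(sequence)) {
    if (nrow(sequence) != 1L) stop("compose() expects a single record")
    if (is.na(protein_id)) protein_id <- sequence$id[[1L]]
    sequence <- sequence$sequence[[1L]]
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA21)
  if (length(bad) > 0L) {
    stop("validation error: illegal residue(s) ", paste(bad, collapse = ", "),
         " in '", protein_id, "'")
  }
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) {
    stop("validation error: sequence of '", protein_id,
         "' has no canonical residues (only X)")
  }
  counts <- setNames(tabulate(factor(chars, levels = AA20), nbins = 20L), AA20)
  len <- length(chars)
  pct <- counts / len * 100
  fc <- (counts / len) / bg[AA20]
  l2 <- ifelse(counts > 0L, log2(fc), NA_real_)
  structure(list(protein_id = protein_id,
                 counts = counts,
                 length_counted = len,
                 percentage = pct,
                 fold_change = unname2(fc),
                 log2_fc = setNames(l2, AA20),
                 enriched = setNames(fc >= ENRICH_THRESHOLD - ENRICH_EPS, AA20),
                 ranks = rank_residues_pct(pct)),
            class = "composition_profile")
}

unname2 <- function(x) setNames(as.numeric(x), AA20)

rank_residues_pct <- function(pct) {
  setNames(rank(-pct, ties.method = "average"), AA20)
}

#' Contribution ranks of a composition profile
#'
#' Residues are ranked by descending percentage composition: the highest
#' contributing residue gets rank 1, the second rank 2, and so on; tied
#' residues receive the mean of the tied rank positions.
#'
#' @param profile A `composition_profile` from [compose()].
#' @return Named numeric vector of ranks over the 20 canonical residues.
#' @export
rank_residues <- function(profile) {
  rank_residues_pct(profile$percentage)
}

#' Combine per-protein ranks across a cohort
#'
#' Sums each tracked residue's per-protein contribution rank over the cohort
#' and orders tracked residues by ascending rank sum: the lower the sum, the
#' larger the residue's overall contribution (overall rank 1 = largest).
#'
#' @param profiles List of `composition_profile` objects.
#' @param tracked Residues to aggregate (default the five PELP1 signature
#'   residues L, E, P, D, C).
#' @return Data frame `residue`, `rank_sum`, `overall_rank`, ordered by
#'   `overall_rank`.
#' @export
aggregate_ranks <- function(profiles, tracked = c("L", "E", "P", "D", "C")) {
  if (length(profiles) == 0L) {
    stop("validation error: empty cohort")
  }
  stopifnot(all(tracked %in% AA20))
  sums <- rowSums(vapply(profiles, function(p) p$ranks[tracked],
                         numeric(length(tracked))))
  out <- data.frame(residue = tracked, rank_sum = unname(sums),
                    overall_rank = unname(rank(sums, ties.method = "average")),
                    stringsAsFactors = FALSE)
  out[order(out$overall_rank), , drop = FALSE]
}

#' Count proteins enriched per residue
#'
#' @param profiles List of `composition_profile` objects.
#' @return Named integer vector: for each of the 20 residues, the number of
#'   proteins whose profile flags it enriched (fold-change >= 1.5).
#' @export
enrichment_counts <- function(profiles) {
  if (length(profiles) == 0L) {
    stop("validation error: empty cohort")
  }
  counts <- rowSums(vapply(profiles, function(p) p$enriched[AA20],
                           logical(20L)))
  setNames(as.integer(counts), AA20)
}

#' Validate enrichment calls on labelled reference proteins
#'
#' For each record with a known expected-enrichment label (e.g. a
#' glycine-rich or a proline/serine-rich protein), checks that every
#' expected residue is flagged enriched by [compose()].
#'
#' @param cohort Cohort data frame.
#' @param expected Data frame with columns `id` and `residues`
#'   (comma-separated expected-enriched one-letter codes).
#' @param bg Background frequencies.
#' @return Data frame `id`, `expected`, `called`, `pass` with one row per
#'   labelled record.
#' @export
validate_against_known <- function(cohort, expected,
                                   bg = default_background()) {
  rows <- lapply(seq_len(nrow(expected)), function(k) {
    id <- expected$id[[k]]
    want <- trimws(strsplit(expected$residues[[k]], ",")[[1L]])
    rec <- cohort[cohort$id == id, , drop = FALSE]
    if (nrow(rec) != 1L) {
      stop("validation error: record '", id, "' not found exactly once")
    }
    prof <- compose(rec$sequence[[1L]], bg, id)
    called <- names(which(prof$enriched))
    data.frame(id = id,
               expected = paste(want, collapse = ","),
               called = paste(called, collapse = ","),
               pass = all(want %in% called),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compose every protein of a cohort
#'
#' @param cohort Cohort data frame.
#' @param bg Background frequencies.
#' @return Named list of `composition_profile` objects (names = protein ids).
#' @export
compose_cohort <- function(cohort, bg = default_background()) {
  profiles <- lapply(seq_len(nrow(cohort)), function(k) {
    compose(cohort$sequence[[k]], bg, cohort$id[[k]])
  })
  setNames(profiles, cohort$id)
}
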