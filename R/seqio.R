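#' Read a protein cohort from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a cohort
#' data frame. Headers in the native dialect `id|species|clade|kingdom|
#' phylum|class` are split on `|`; trailing fields may be omitted. A header
#' without pipes degrades gracefully to an id-only record. Sequences are
#' uppercased and validated against the 21-letter alphabet (20 canonical
#' residues plus `X` for an unknown residue).
#'
#' @param path Path to a FASTA file. An empty file yields a zero-row cohort.
#' @return A `data.frame` with columns `id`, `species`, `clade`, `kingdom`,
#'   `phylum`, `class`, `sequence` (one row per record).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|Homo sapiens|Opisthokonta|Metazoa|Chordata|Mammalia",
#'              "MKLLAVE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("input error: FASTA file not found: ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  n <- length(aa)
  cohort <- empty_cohort()
  if (n == 0L) {
    return(cohort)
  }
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  meta <- parse_fasta_headers(headers)
  for (k in seq_len(n)) {
    bad <- regexpr(paste0("[^", paste(AA21, collapse = ""), "]"), seqs[[k]])
    if (bad > 0L) {
      stop("validation error: illegal residue '",
           substr(seqs[[k]], bad, bad), "' at position ", bad,
           " in record '", meta$id[[k]], "'")
    }
    if (nchar(seqs[[k]]) < 1L) {
      stop("validation error: empty sequence in record '", meta$id[[k]], "'")
    }
  }
  meta$sequence <- unname(seqs)
  meta
}

empty_cohort <- function() {
  data.frame(id = character(), species = character(), clade = character(),
             kingdom = character(), phylum = character(), class = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

parse_fasta_headers <- function(headers) {
  fields <- strsplit(headers, "|", fixed = TRUE)
  pad <- function(x) {
    x <- trimws(x)
    length(x) <- 6L
    x[is.na(x)] <- ""
    x
  }
  m <- do.call(rbind, lapply(fields, pad))
  data.frame(id = m[, 1L], species = m[, 2L], clade = m[, 3L],
             kingdom = m[, 4L], phylum = m[, 5L], class = m[, 6L],
             stringsAsFactors = FALSE)
}

#' Write a protein cohort to a FASTA file
#'
#' Writes the pipe-delimited native header dialect
#' (`id|species|clade|kingdom|phylum|class`); metadata-free records are
#' written with a bare id header. Round-trips exactly through [read_fasta()].
#'
#' @param cohort Cohort data frame as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(cohort, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(cohort))) {
    meta <- c(cohort$species[[k]], cohort$clade[[k]], cohort$kingdom[[k]],
              cohort$phylum[[k]], cohort$class[[k]])
    header <- if (all(meta == "")) {
      cohort$id[[k]]
    } else {
      paste(c(cohort$id[[k]], meta), collapse = "|")
    }
    writeLines(paste0(">", header), con)
    s <- cohort$sequence[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Remove same-species exact-duplicate sequences
#'
#' Two records are duplicates when they share 100% sequence identity *and*
#' come from the same species; the rule is conjunctive, so identical
#' sequences from different species are all retained. Within each duplicate
#' group the first record in input order is kept.
#'
#' @param cohort Cohort data frame ([read_fasta()]).
#' @return A list with `kept` (the deduplicated cohort) and `removed`
#'   (a data frame of `kept_id`, `removed_id` pairs, one row per removed
#'   record). `nrow(kept) + nrow(removed) == nrow(cohort)` always holds.
#' @export
deduplicate <- function(cohort) {
  removed <- data.frame(kept_id = character(), removed_id = character(),
                        stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L) {
    return(list(kept = cohort, removed = removed))
  }
  key <- paste(cohort$species, cohort$sequence, sep = "\r")
  first <- !duplicated(key)
  if (any(!first)) {
    keeper <- cohort$id[first][match(key[!first], key[first])]
    removed <- data.frame(kept_id = keeper, removed_id = cohort$id[!first],
                          stringsAsFactors = FALSE)
  }
  kept <- cohort[first, , drop = FALSE]
  rownames(kept) <- NULL
  dup_ids <- kept$id[duplicated(kept$id)]
  if (length(dup_ids) > 0L) {
    stop("validation error: duplicated ids after deduplication: ",
         paste(unique(dup_ids), collapse = ", "))
  }
  list(kept = kept, removed = removed)
}

#' Read a taxonomy table
#'
#' Reads a tab-delimited taxonomy table with header columns `id`, `clade`,
#' `kingdom`, `phylum`, `class`. Blank cells are preserved as empty ranks;
#' extra columns are ignored (with a message). Duplicated ids are an error.
#'
#' @param path Path to the TSV file.
#' @return Data frame mapping `id` to the four taxonomy ranks.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    stop("input error: taxonomy file not found: ", path)
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = NULL, check.names = FALSE)
  required <- c("id", "clade", "kingdom", "phylum", "class")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("validation error: taxonomy file missing columns: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(tab), required)
  if (length(extra) > 0L) {
    message("read_taxonomy: ignoring extra columns: ",
            paste(extra, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("validation error: duplicated ids in taxonomy file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  out <- tab[, required, drop = FALSE]
  out[is.na(out)] <- ""
  rownames(out) <- NULL
  out
}
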