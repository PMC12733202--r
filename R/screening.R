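#' Parse a domain-hit table
#'
#' Reads per-protein domain hits either from an HMMER3 `--domtblout` file
#' (whitespace-delimited, `#` comment lines) or from a plain TSV with header
#' `protein_id`, `domain_name`, `start`, `end`, `evalue`, `score` (an
#' optional `pfam_acc` column is carried through). For `domtblout` input the
#' envelope coordinates (columns 20-21) and the per-domain independent
#' E-value (column 13) are used. Hits with E-value above `evalue_threshold`
#' are dropped and reported via a message.
#'
#' @param path Path to the hit table.
#' @param dialect `"tsv"` or `"domtblout"`.
#' @param evalue_threshold Acceptance threshold on the per-domain E-value
#'   (default 0.01); hits above it are discarded.
#' @return Data frame with columns `protein_id`, `domain_name`, `pfam_acc`,
#'   `start`, `end`, `evalue`, `score`. Coordinates are 1-based inclusive.
#' @export
parse_domain_hits <- function(path, dialect = c("tsv", "domtblout"),
                              evalue_threshold = 0.01) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("input error: domain-hit file not found: ", path)
  }
  hits <- switch(dialect,
                 tsv = parse_hits_tsv(path),
                 domtblout = parse_hits_domtblout(path))
  bad <- !is.finite(hits$evalue) | hits$evalue < 0 |
    !is.finite(hits$start) | !is.finite(hits$end) |
    hits$start < 1 | hits$start > hits$end
  if (any(bad)) {
    stop("validation error in ", path, ": malformed hit at line ",
         hits$line[which(bad)[1L]])
  }
  drop <- hits$evalue > evalue_threshold
  if (any(drop)) {
    message("parse_domain_hits: dropped ", sum(drop),
            " hit(s) above E-value threshold ", evalue_threshold)
  }
  hits <- hits[!drop, setdiff(names(hits), "line"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}

parse_hits_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = NULL, check.names = FALSE)
  required <- c("protein_id", "domain_name", "start", "end", "evalue", "score")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("validation error: hit TSV missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"pfam_acc" %in% names(tab)) tab$pfam_acc <- ""
  data.frame(protein_id = tab$protein_id,
             domain_name = tab$domain_name,
             pfam_acc = tab$pfam_acc,
             start = suppressWarnings(as.integer(tab$start)),
             end = suppressWarnings(as.integer(tab$end)),
             evalue = suppressWarnings(as.numeric(tab$evalue)),
             score = suppressWarnings(as.numeric(tab$score)),
             line = seq_len(nrow(tab)) + 1L,  # +1 for the header line
             stringsAsFactors = FALSE)
}

parse_hits_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(cbind(empty_hits(), line = integer()))
  }
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(f) < 22L) {
      stop("validation error in domtblout: malformed row at line ", i)
    }
    data.frame(protein_id = f[[4L]], domain_name = f[[1L]], pfam_acc = f[[2L]],
               start = suppressWarnings(as.integer(f[[20L]])),
               end = suppressWarnings(as.integer(f[[21L]])),
               evalue = suppressWarnings(as.numeric(f[[13L]])),
               score = suppressWarnings(as.numeric(f[[14L]])),
               line = i, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             pfam_acc = character(), start = integer(), end = integer(),
             evalue = numeric(), score = numeric(), stringsAsFactors = FALSE)
}

#' Resolve overlapping same-domain hits
#'
#' Among hits of the *same* domain on the *same* protein that overlap by
#' more than 50% of the shorter hit's length, only the best hit survives
#' (lowest E-value; ties broken by higher score, then smaller start). Hits
#' of different domains never suppress each other.
#'
#' @param hits Hit data frame from [parse_domain_hits()]; may cover several
#'   proteins.
#' @return Hit data frame with suppressed hits removed.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$protein_id, hits$domain_name, sep = "\r"))
  keep <- logical(nrow(hits))
  for (g in groups) {
    sub <- hits[g, , drop = FALSE]
    ord <- order(sub$evalue, -sub$score, sub$start)
    kept <- integer()
    for (j in ord) {
      clash <- FALSE
      for (i in kept) {
        ov <- min(sub$end[[i]], sub$end[[j]]) -
          max(sub$start[[i]], sub$start[[j]]) + 1L
        shorter <- min(sub$end[[i]] - sub$start[[i]],
                       sub$end[[j]] - sub$start[[j]]) + 1L
        if (ov > 0.5 * shorter) {
          clash <- TRUE
          break
        }
      }
      if (!clash) kept <- c(kept, j)
    }
    keep[g[kept]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a protein's domain architecture
#'
#' Counts overlap-resolved RIX1 and NUC202 hits and assigns the family
#' label: `(n_rix >= 1, n_nuc == 2)` is `PELP1_2NUC`, `(n_rix >= 1,
#' n_nuc == 1)` is `PELP1_1NUC`, `(n_rix >= 1, n_nuc >= 3)` is
#' `PELP1_multiNUC`, `(n_rix >= 1, n_nuc == 0)` is `RIX_only`,
#' `(n_rix == 0, n_nuc >= 1)` is `NUC_only`, anything else `other`. Every
#' `PELP1_*` label counts as a PELP1 protein.
#'
#' @param hits Overlap-resolved hits for one protein (possibly zero rows).
#' @param protein_id Protein identifier; defaults to the id found in `hits`.
#' @return One-row data frame `protein_id`, `n_rix`, `n_nuc`, `label`.
#' @seealso [classify_cohort()] for whole-cohort classification.
#' @export
classify_architecture <- function(hits, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- if (nrow(hits) > 0L) hits$protein_id[[1L]] else NA_character_
  }
  n_rix <- sum(hits$domain_name == "RIX1")
  n_nuc <- sum(hits$domain_name == "NUC202")
  data.frame(protein_id = protein_id, n_rix = n_rix, n_nuc = n_nuc,
             label = architecture_label(n_rix, n_nuc),
             stringsAsFactors = FALSE)
}

architecture_label <- function(n_rix, n_nuc) {
  if (n_rix >= 1L && n_nuc == 2L) "PELP1_2NUC"
  else if (n_rix >= 1L && n_nuc == 1L) "PELP1_1NUC"
  else if (n_rix >= 1L && n_nuc >= 3L) "PELP1_multiNUC"
  else if (n_rix >= 1L && n_nuc == 0L) "RIX_only"
  else if (n_rix == 0L && n_nuc >= 1L) "NUC_only"
  else "other"
}

#' Classify every protein of a cohort
#'
#' Applies [resolve_overlaps()] and [classify_architecture()] per protein.
#' Proteins listed in `protein_ids` but absent from the hit table are
#' classified `other` (no domains).
#'
#' @param hits Hit data frame covering the cohort.
#' @param protein_ids Character vector of all protein ids to classify.
#' @return Data frame of architecture calls, one row per protein id.
#' @export
classify_cohort <- function(hits, protein_ids) {
  empty <- data.frame(protein_id = character(), n_rix = integer(),
                      n_nuc = integer(), label = character(),
                      stringsAsFactors = FALSE)
  if (length(protein_ids) == 0L) return(empty)
  hits <- resolve_overlaps(hits)
  calls <- lapply(protein_ids, function(id) {
    classify_architecture(hits[hits$protein_id == id, , drop = FALSE], id)
  })
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}

#' Summarise architecture calls by taxonomy
#'
#' Groups architecture calls by (clade, kingdom, phylum, class) and counts
#' PELP1 proteins (any `PELP1_*` label), RIX-domain-only proteins, and
#' NUC-only proteins split by NUC202 copy number, with a grand-totals row.
#' Proteins missing from the taxonomy table fall into an `unassigned` group
#' and are reported via a message.
#'
#' @param calls Architecture-call data frame ([classify_cohort()]).
#' @param taxonomy Taxonomy data frame ([read_taxonomy()]).
#' @return Data frame with taxonomy rank columns and count columns
#'   `n_PELP1`, `n_RIX_only`, `n_2NUC_only`, `n_1NUC_only`; the final row
#'   (`clade == "Total"`) carries column totals.
#' @export
taxonomy_summary <- function(calls, taxonomy) {
  ranks <- c("clade", "kingdom", "phylum", "class")
  m <- match(calls$protein_id, taxonomy$id)
  tax <- taxonomy[m, ranks, drop = FALSE]
  unassigned <- is.na(m)
  if (any(unassigned)) {
    message("taxonomy_summary: ", sum(unassigned),
            " protein(s) missing from taxonomy; counted as 'unassigned'")
    tax[unassigned, ] <- ""
    tax$clade[unassigned] <- "unassigned"
  }
  df <- cbind(tax, calls[, c("label", "n_nuc"), drop = FALSE])
  rownames(df) <- NULL
  counts <- function(sub) {
    c(n_PELP1 = sum(startsWith(sub$label, "PELP1")),
      n_RIX_only = sum(sub$label == "RIX_only"),
      n_2NUC_only = sum(sub$label == "NUC_only" & sub$n_nuc == 2L),
      n_1NUC_only = sum(sub$label == "NUC_only" & sub$n_nuc == 1L))
  }
  key <- do.call(paste, c(df[ranks], sep = "\r"))
  groups <- split(df, key)
  rows <- lapply(groups, function(sub) {
    cbind(sub[1L, ranks, drop = FALSE], as.data.frame(as.list(counts(sub))))
  })
  out <- if (length(rows) == 0L) {
    data.frame(clade = character(), kingdom = character(),
               phylum = character(), class = character(),
               n_PELP1 = integer(), n_RIX_only = integer(),
               n_2NUC_only = integer(), n_1NUC_only = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out <- out[order(out$clade, out$kingdom, out$phylum, out$class), ,
             drop = FALSE]
  total <- data.frame(clade = "Total", kingdom = "", phylum = "", class = "",
                      n_PELP1 = sum(out$n_PELP1),
                      n_RIX_only = sum(out$n_RIX_only),
                      n_2NUC_only = sum(out$n_2NUC_only),
                      n_1NUC_only = sum(out$n_1NUC_only),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
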