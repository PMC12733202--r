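# Independent oracles used across the suite. These re-derive expected
# values by enumeration or direct tallying and never call the package code
# paths they are checking.

AA_ALL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive-enumeration optimum of a global alignment with affine gaps
# (a gap run of length k costs open + ext * k). Pure recursion over all
# monotone alignments; feasible for sequences up to ~6 residues.
bf_align_score <- function(a, b, mat = blosum62, open = 10, ext = 0.5) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  la <- length(ac)
  lb <- length(bc)
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, mat[ac[[i]], bc[[j]]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= la) {
      best <- max(best, -(ext + if (prev == "D") 0 else open) +
                    rec(i + 1L, j, "D"))
    }
    if (j <= lb) {
      best <- max(best, -(ext + if (prev == "I") 0 else open) +
                    rec(i, j + 1L, "I"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Direct per-character tally of a sequence's composition (X excluded).
tally_composition <- function(sequence) {
  counts <- setNames(integer(length(AA_ALL)), AA_ALL)
  for (ch in strsplit(sequence, "", fixed = TRUE)[[1L]]) {
    if (ch != "X") counts[[ch]] <- counts[[ch]] + 1L
  }
  counts
}

# Brute-force architecture rule table, written independently of the
# package's classifier.
bf_architecture <- function(n_rix, n_nuc) {
  if (n_rix >= 1 && n_nuc == 2) return("PELP1_2NUC")
  if (n_rix >= 1 && n_nuc == 1) return("PELP1_1NUC")
  if (n_rix >= 1 && n_nuc >= 3) return("PELP1_multiNUC")
  if (n_rix >= 1 && n_nuc == 0) return("RIX_only")
  if (n_rix == 0 && n_nuc >= 1) return("NUC_only")
  "other"
}

# Naive agglomerative clustering with (unweighted pair-group) average
# linkage on a distance matrix; returns the sorted merge heights.
bf_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- seq_along(members)
  heights <- numeric(0)
  pair_dist <- function(c1, c2) {
    mean(d[members[[c1]], members[[c2]]])
  }
  while (length(active) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (x in seq_along(active)) {
      for (y in seq_len(x - 1L)) {
        dd <- pair_dist(active[[x]], active[[y]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(active[[x]], active[[y]])
        }
      }
    }
    heights <- c(heights, best_d)
    members[[length(members) + 1L]] <- c(members[[best[[1L]]]],
                                         members[[best[[2L]]]])
    active <- c(setdiff(active, best), length(members))
  }
  sort(heights)
}

# Sliding-window scan for a wildcard pattern; overlapping start positions.
bf_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  w <- length(pat)
  starts <- integer(0)
  for (s in seq_len(max(0L, length(chars) - w + 1L))) {
    ok <- TRUE
    for (p in seq_len(w)) {
      if (pat[[p]] != "." && chars[[s + p - 1L]] != pat[[p]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# Random amino-acid string (canonical residues only).
random_seq <- function(n, alphabet = AA_ALL) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Published per-position predominance values used by recovery checks:
# motif id -> list of per-position named percent vectors.
published_predominance <- function(motif_id) {
  pelpscope:::MOTIF_PREDOMINANCE[[motif_id]]
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
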