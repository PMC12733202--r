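#' Specification of a synthetic protein cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults describe the PELP1 study cohort the package emulates: 646
#' proteins; compositional enrichment planted at the published per-residue
#' prevalence (proline in 469/646 proteins, glutamic acid 459, cysteine
#' 252, glutamine 119, serine 95, leucine 64, glycine 20) with a 2.0x
#' multiplier; domain architectures of one RIX1 plus two NUC202 domains in
#' 589 proteins and one RIX1 plus a single NUC202 in 57; no planted
#' duplicates. Lengths are drawn from N(1000, 150) residues, the scale of
#' real PELP1 proteins.
#'
#' @param n_proteins Cohort size.
#' @param length_mean,length_sd Normal length distribution (residues);
#'   draws are clamped below at 660 for proteins that carry domain hits so
#'   the fabricated domain coordinates always fit.
#' @param background Background frequencies ([default_background()]).
#' @param enrichment_plan Data frame `residue`, `multiplier`, `fraction`:
#'   each residue's frequency is multiplied by `multiplier` (then
#'   renormalised) in a random `fraction` of the cohort.
#' @param motif_plan Optional data frame `motif_id`, `insertion_prob`,
#'   `deletion_prob`: motif windows sampled from [emission_for_table4()]
#'   emissions are spliced at the synthetic reference's annotated offsets;
#'   indels inside the window occur at the stated probabilities and produce
#'   length-deviant instances. When a motif plan is given, the non-motif
#'   backbone is the synthetic reference with a fraction
#'   `backbone_divergence` of sites substituted (draws from the adjusted
#'   background), so that every protein stays globally alignable to the
#'   reference and motif extraction is anchored.
#' @param backbone_divergence Fraction of non-motif backbone sites
#'   substituted when `motif_plan` is used (default 0.2).
#' @param architecture_plan Named probability vector over labels
#'   `PELP1_2NUC`, `PELP1_1NUC`, `PELP1_multiNUC`, `RIX_only`, `NUC_only`,
#'   `other`; converted to exact per-label counts by largest remainder.
#' @param duplicate_fraction Fraction of the cohort that are exact
#'   duplicates (same sequence and species, new id) of earlier proteins.
#' @param taxonomy_labels Data frame `species`, `clade`, `kingdom`,
#'   `phylum`, `class` cycled over the cohort.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_proteins = 646L,
                        length_mean = 1000, length_sd = 150,
                        background = default_background(),
                        enrichment_plan = default_enrichment_plan(),
                        motif_plan = NULL,
                        backbone_divergence = 0.2,
                        architecture_plan = c(PELP1_2NUC = 589 / 646,
                                              PELP1_1NUC = 57 / 646),
                        duplicate_fraction = 0,
                        taxonomy_labels = default_taxonomy_labels(),
                        seed = 1L) {
  stopifnot(n_proteins >= 0L, length_mean > 0, length_sd >= 0,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  if (!is.null(enrichment_plan) && nrow(enrichment_plan) > 0L) {
    stopifnot(all(enrichment_plan$multiplier > 0),
              all(enrichment_plan$fraction >= 0),
              all(enrichment_plan$fraction <= 1),
              all(enrichment_plan$residue %in% AA20))
  }
  known <- c("PELP1_2NUC", "PELP1_1NUC", "PELP1_multiNUC",
             "RIX_only", "NUC_only", "other")
  stopifnot(all(names(architecture_plan) %in% known),
            abs(sum(architecture_plan) - 1) < 1e-9)
  if (!is.null(motif_plan) && nrow(motif_plan) > 0L) {
    stopifnot(all(motif_plan$motif_id %in% MOTIF_ID_ORDER),
              all(motif_plan$insertion_prob >= 0),
              all(motif_plan$deletion_prob >= 0))
    for (m in motif_plan$motif_id) {
      em <- emission_for_table4(m)
      stopifnot(all(abs(rowSums(em) - 1) < 1e-9))
    }
  }
  stopifnot(backbone_divergence >= 0, backbone_divergence <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_mean = length_mean, length_sd = length_sd,
                 background = background,
                 enrichment_plan = enrichment_plan,
                 motif_plan = motif_plan,
                 backbone_divergence = backbone_divergence,
                 architecture_plan = architecture_plan,
                 duplicate_fraction = duplicate_fraction,
                 taxonomy_labels = taxonomy_labels,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_enrichment_plan <- function() {
  data.frame(residue = c("P", "E", "C", "Q", "S", "L", "G"),
             multiplier = 2.0,
             fraction = c(469, 459, 252, 119, 95, 64, 20) / 646,
             stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_taxonomy_labels <- function() {
  data.frame(
    species = c("Simulomys primus", "Simulopiscis secundus",
                "Simulavis tertius", "Simulinsecta quartus",
                "Simulomollusca quintus", "Simulofungus sextus",
                "Simulofungus septimus", "Simulofilasterea octavus"),
    clade = "Opisthokonta",
    kingdom = c(rep("Metazoa", 5L), "Fungi", "Fungi", ""),
    phylum = c("Chordata", "Chordata", "Chordata", "Arthropoda", "Mollusca",
               "Mucoromycota", "Zoopagomycota", ""),
    class = c("Mammalia", "Actinopteri", "Aves", "Insecta", "Bivalvia",
              "Glomeromycetes", "Kickxellomycetes", "Filasterea"),
    stringsAsFactors = FALSE)
}

#' Multiply-and-renormalise background frequencies
#'
#' Applies per-residue multipliers to a background distribution and
#' renormalises: `f'(r) = m(r) f(r) / Z`. The expected frequency of a
#' planted residue is therefore analytically known, which the generator's
#' recovery tests exploit.
#'
#' @param bg Background frequencies.
#' @param residues Residues to boost.
#' @param multipliers Multipliers (recycled to `length(residues)`).
#' @return Adjusted named frequency vector summing to 1.
#' @export
adjust_background <- function(bg, residues, multipliers) {
  f <- setNames(as.numeric(bg[AA20]), AA20)
  multipliers <- rep_len(multipliers, length(residues))
  f[residues] <- f[residues] * multipliers
  f / sum(f)
}

# Exact integer allocation of n items to probabilities (largest remainder).
largest_remainder <- function(n, probs) {
  raw <- n * probs
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  setNames(as.integer(counts), names(probs))
}

protein_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 48611 * k) %% 2147483647)
}

#' Generate a synthetic protein cohort
#'
#' Draws a cohort according to a [cohort_spec()]: sequences are sampled
#' residue-wise from the (per-protein multiplied-and-renormalised)
#' background; motif windows, when planned, are sampled from per-position
#' emission tables and spliced at the synthetic reference's annotated
#' offsets; domain hits are fabricated consistently with each protein's
#' architecture label (RIX1 near the N-terminus, NUC202 copies downstream,
#' non-overlapping); duplicates copy sequence and species under a new id;
#' taxonomy labels cycle over the label table. Per-protein RNG streams are
#' derived from the cohort seed by counter offsets, so protein `k` is
#' reproducible independently of `n`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, writes `cohort.fasta`,
#'   `hits.tsv`, `taxonomy.tsv` and `truth.json` there.
#' @return List with `cohort` (data frame), `hits` (data frame),
#'   `taxonomy` (data frame) and `truth` (per-protein ground-truth list).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_proteins
  ref <- if (!is.null(spec$motif_plan) && nrow(spec$motif_plan) > 0L) {
    synthetic_reference()
  } else NULL
  if (!is.null(ref)) {
    min_needed <- max(ref$annotation$end)
    if (min_needed > nchar(ref$sequence)) {
      stop("validation error: infeasible spec (motif beyond reference)")
    }
  }

  ids <- sprintf("SYN%04d", seq_len(n))
  n_dup <- as.integer(floor(n * spec$duplicate_fraction))
  n_orig <- n - n_dup
  if (n > 0L && n_orig < 1L) {
    stop("validation error: infeasible spec (no original proteins)")
  }

  # Cohort-level assignments (exact counts, randomised placement).
  set.seed(spec$seed)
  arch_counts <- largest_remainder(n_orig, spec$architecture_plan)
  arch <- if (n_orig > 0L) {
    sample(rep(names(arch_counts), arch_counts))
  } else character()
  planted <- matrix(FALSE, nrow = n_orig,
                    ncol = if (is.null(spec$enrichment_plan)) 0L
                           else nrow(spec$enrichment_plan))
  if (ncol(planted) > 0L && n_orig > 0L) {
    for (j in seq_len(ncol(planted))) {
      n_planted <- round(n_orig * spec$enrichment_plan$fraction[[j]])
      planted[sample(n_orig, n_planted), j] <- TRUE
    }
  }
  dup_source <- if (n_dup > 0L) sample(n_orig, n_dup, replace = TRUE)
                else integer()

  tax <- spec$taxonomy_labels
  species_idx <- ((seq_len(n_orig) - 1L) %% nrow(tax)) + 1L

  cohort <- empty_cohort()
  hits <- empty_hits()
  truth <- list()

  for (k in seq_len(n_orig)) {
    set.seed(protein_seed(spec$seed, k))
    label <- arch[[k]]
    res <- if (ncol(planted) > 0L) {
      spec$enrichment_plan$residue[planted[k, ]]
    } else character()
    mult <- if (ncol(planted) > 0L) {
      spec$enrichment_plan$multiplier[planted[k, ]]
    } else numeric()
    freq <- adjust_background(spec$background, res, mult)

    gen <- generate_sequence(spec, freq, ref)
    prot_hits <- fabricate_hits(ids[[k]], label, nchar(gen$sequence))
    ti <- species_idx[[k]]
    cohort <- rbind(cohort, data.frame(
      id = ids[[k]], species = tax$species[[ti]], clade = tax$clade[[ti]],
      kingdom = tax$kingdom[[ti]], phylum = tax$phylum[[ti]],
      class = tax$class[[ti]], sequence = gen$sequence,
      stringsAsFactors = FALSE))
    hits <- rbind(hits, prot_hits)
    truth[[ids[[k]]]] <- list(id = ids[[k]], label = label,
                              planted_residues = res,
                              duplicate_of = NA_character_,
                              motifs = gen$motifs)
  }

  for (d in seq_len(n_dup)) {
    k <- n_orig + d
    src <- dup_source[[d]]
    src_row <- cohort[src, , drop = FALSE]
    cohort <- rbind(cohort, within(src_row, id <- ids[[k]]))
    src_hits <- hits[hits$protein_id == ids[[src]], , drop = FALSE]
    if (nrow(src_hits) > 0L) {
      src_hits$protein_id <- ids[[k]]
      hits <- rbind(hits, src_hits)
    }
    src_truth <- truth[[ids[[src]]]]
    truth[[ids[[k]]]] <- list(id = ids[[k]], label = src_truth$label,
                              planted_residues = src_truth$planted_residues,
                              duplicate_of = ids[[src]],
                              motifs = src_truth$motifs)
  }
  rownames(cohort) <- NULL
  rownames(hits) <- NULL
  taxonomy <- cohort[, c("id", "clade", "kingdom", "phylum", "class"),
                     drop = FALSE]

  out <- list(cohort = cohort, hits = hits, taxonomy = taxonomy,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(cohort, file.path(dir, "cohort.fasta"))
    write.table(hits, file.path(dir, "hits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

# One protein's sequence (and realised motif positions) under adjusted
# frequencies. With a motif plan the backbone length equals the reference
# and windows are spliced at the annotated offsets; indels inside a window
# shift only positions downstream of that window.
generate_sequence <- function(spec, freq, ref) {
  if (is.null(ref)) {
    len <- max(60L, as.integer(round(rnorm(1L, spec$length_mean,
                                           spec$length_sd))))
    len <- max(len, 660L)  # fabricated domain coordinates must fit
    return(list(sequence = paste(sample(AA20, len, replace = TRUE,
                                        prob = freq), collapse = ""),
                motifs = list()))
  }
  ann <- ref$annotation
  backbone_len <- nchar(ref$sequence)
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  n_mut <- round(backbone_len * spec$backbone_divergence)
  if (n_mut > 0L) {
    at <- sample(backbone_len, n_mut)
    chars[at] <- sample(AA20, n_mut, replace = TRUE, prob = freq)
  }
  plan <- spec$motif_plan
  pieces <- character()
  motifs <- list()
  cursor <- 1L   # next backbone position to copy
  shift <- 0L    # accumulated indel length change
  for (k in seq_len(nrow(ann))) {
    m <- ann$motif_id[[k]]
    row <- plan[plan$motif_id == m, , drop = FALSE]
    s <- ann$start[[k]]
    e <- ann$end[[k]]
    pieces <- c(pieces, paste(chars[cursor:(s - 1L)], collapse = ""))
    if (nrow(row) == 1L) {
      em <- emission_for_table4(m)
      window <- vapply(seq_len(nrow(em)), function(p) {
        sample(AA20, 1L, prob = em[p, ])
      }, character(1L))
      if (runif(1L) < row$insertion_prob && length(window) >= 2L) {
        at <- sample(length(window) - 1L, 1L)  # strictly interior boundary
        window <- append(window, sample(AA20, 1L, prob = freq), after = at)
      }
      if (runif(1L) < row$deletion_prob && length(window) >= 1L) {
        window <- window[-sample(length(window), 1L)]
      }
      window <- paste(window, collapse = "")
    } else {
      window <- paste(chars[s:e], collapse = "")
    }
    motifs[[m]] <- list(motif_id = m, start = s + shift, window = window)
    shift <- shift + nchar(window) - (e - s + 1L)
    pieces <- c(pieces, window)
    cursor <- e + 1L
  }
  pieces <- c(pieces, paste(chars[cursor:backbone_len], collapse = ""))
  list(sequence = paste(pieces, collapse = ""), motifs = unname(motifs))
}

# Domain hits consistent with an architecture label: RIX1 near the
# N-terminus, NUC202 copies downstream, all non-overlapping.
fabricate_hits <- function(protein_id, label, protein_length) {
  coords <- list(RIX1 = c(31L, 210L), NUC1 = c(290L, 400L),
                 NUC2 = c(460L, 570L), NUC3 = c(600L, 650L))
  stopifnot(protein_length >= 660L || label == "other")
  rows <- list()
  add <- function(domain, acc, span, evalue, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = protein_id, domain_name = domain, pfam_acc = acc,
      start = span[[1L]], end = span[[2L]], evalue = evalue, score = score,
      stringsAsFactors = FALSE)
  }
  n_rix <- if (label %in% c("PELP1_2NUC", "PELP1_1NUC", "PELP1_multiNUC",
                            "RIX_only")) 1L else 0L
  n_nuc <- switch(label, PELP1_2NUC = 2L, PELP1_1NUC = 1L,
                  PELP1_multiNUC = 3L, NUC_only = 1L, 0L)
  if (n_rix >= 1L) add("RIX1", "PF08167.15", coords$RIX1, 1e-40, 150)
  if (n_nuc >= 1L) add("NUC202", "PF08166.15", coords$NUC1, 1e-35, 120)
  if (n_nuc >= 2L) add("NUC202", "PF08166.15", coords$NUC2, 1e-30, 110)
  if (n_nuc >= 3L) add("NUC202", "PF08166.15", coords$NUC3, 1e-20, 80)
  if (length(rows) == 0L) return(empty_hits())
  do.call(rbind, rows)
}

#' Sample motif instances directly from an emission table
#'
#' Draws `n` canonical-length windows from a per-position emission
#' distribution (by default the published consensus emission of
#' `motif_id`), bypassing full cohort generation. Used by the end-to-end
#' consensus-recovery checks.
#'
#' @param motif_id Motif identifier.
#' @param n Number of instances.
#' @param emission Positions x 20 emission matrix
#'   ([emission_for_table4()]).
#' @param seed Integer seed.
#' @return Motif-instance data frame as from [extract_motifs()].
#' @export
generate_motif_instances <- function(motif_id, n,
                                     emission = emission_for_table4(motif_id),
                                     seed = 1L) {
  set.seed(seed)
  windows <- vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(nrow(emission)), function(p) {
      sample(AA20, 1L, prob = emission[p, ])
    }, character(1L)), collapse = "")
  }, character(1L))
  data.frame(motif_id = motif_id,
             protein_id = sprintf("INST%04d", seq_len(n)),
             window = windows, length = nchar(windows),
             length_deviant = nchar(windows) != nrow(emission),
             stringsAsFactors = FALSE)
}

#' Simulate sequence families descended from a common ancestor
#'
#' A single ancestor sequence is drawn from the background; each family
#' founder is the ancestor with a fraction `founder_divergence` of sites
#' substituted, and each family member is its founder with a further
#' fraction `within_divergence` substituted (substitutions only, no
#' indels). Within-family identity therefore exceeds between-family
#' identity by construction, which the identity-module tests verify.
#'
#' @param n_families,members_per_family Family structure.
#' @param seq_length Sequence length.
#' @param founder_divergence,within_divergence Substitution fractions in
#'   `[0, 1]` (defaults 0.4 and 0.1).
#' @param bg Background frequencies.
#' @param seed Integer seed.
#' @return Cohort data frame with a `family` column appended.
#' @export
generate_families <- function(n_families = 3L, members_per_family = 4L,
                              seq_length = 300L, founder_divergence = 0.4,
                              within_divergence = 0.1,
                              bg = default_background(), seed = 1L) {
  set.seed(seed)
  mutate <- function(chars, rate) {
    k <- round(length(chars) * rate)
    if (k == 0L) return(chars)
    at <- sample(length(chars), k)
    for (i in at) {
      chars[[i]] <- sample(setdiff(AA20, chars[[i]]), 1L)
    }
    chars
  }
  ancestor <- sample(AA20, seq_length, replace = TRUE, prob = bg)
  rows <- list()
  for (f in seq_len(n_families)) {
    founder <- mutate(ancestor, founder_divergence)
    for (m in seq_len(members_per_family)) {
      member <- mutate(founder, within_divergence)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("FAM%d_M%d", f, m),
        species = sprintf("Familia %s", letters[[f]]),
        clade = "", kingdom = "", phylum = "", class = "",
        sequence = paste(member, collapse = ""),
        family = f, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
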