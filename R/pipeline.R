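# Orchestration over the module functions. Each step reads the standard
# file dialects, runs one pipeline stage, and writes tab-delimited tables
# (with JSON mirrors where a downstream machine consumer is likely). The
# numbered scripts under analysis/ are thin drivers over these functions.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run cohort simulation to files
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [generate_cohort()] result.
#' @export
run_simulate <- function(spec, out_dir) {
  res <- generate_cohort(spec, dir = out_dir)
  invisible(res)
}

#' Run the screening stage: read, deduplicate, classify, summarise
#'
#' Reads a cohort FASTA, a domain-hit table and a taxonomy TSV, removes
#' same-species exact duplicates, classifies every kept protein's
#' RIX1/NUC202 architecture and writes the per-protein calls, the removed
#' duplicates and the taxonomy summary (TSV plus a JSON mirror of the
#' summary).
#'
#' @param fasta,hits_path,taxonomy_path Input files.
#' @param out_dir Output directory.
#' @param hits_dialect `"tsv"` or `"domtblout"`.
#' @param evalue_threshold Hit acceptance threshold (default 0.01).
#' @return Invisibly, a list with `calls`, `summary`, `removed`.
#' @export
run_screen <- function(fasta, hits_path, taxonomy_path, out_dir,
                       hits_dialect = "tsv", evalue_threshold = 0.01) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_fasta(fasta)
  dd <- deduplicate(cohort)
  taxonomy <- read_taxonomy(taxonomy_path)
  if (nrow(dd$kept) == 0L) {
    calls <- classify_cohort(empty_hits(), character())
    summary <- taxonomy_summary(calls, taxonomy)
  } else {
    hits <- parse_domain_hits(hits_path, hits_dialect, evalue_threshold)
    calls <- classify_cohort(hits, dd$kept$id)
    summary <- taxonomy_summary(calls, taxonomy)
  }
  write_tsv(calls, file.path(out_dir, "architecture_calls.tsv"))
  write_tsv(dd$removed, file.path(out_dir, "duplicates_removed.tsv"))
  write_tsv(summary, file.path(out_dir, "taxonomy_summary.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "taxonomy_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, summary = summary, removed = dd$removed))
}

#' Run the composition stage: profiles, enrichment counts, rank table
#'
#' Composes every protein against the background table and writes the long
#' per-protein per-residue profile table, the per-residue enrichment counts
#' and the aggregated rank table for the tracked signature residues.
#'
#' @param fasta Input FASTA.
#' @param out_dir Output directory.
#' @param background_path Optional background TSV; default the packaged
#'   Swiss-Prot table.
#' @param tracked Residues for [aggregate_ranks()].
#' @return Invisibly, a list with `profiles`, `enrichment`, `ranks`.
#' @export
run_compose <- function(fasta, out_dir, background_path = NULL,
                        tracked = c("L", "E", "P", "D", "C")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_fasta(fasta)
  bg <- if (is.null(background_path)) default_background()
        else read_background(background_path)
  profiles <- compose_cohort(cohort, bg)
  long <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(protein_id = p$protein_id, residue = AA20,
               count = as.integer(p$counts),
               percentage = as.numeric(p$percentage),
               fold_change = as.numeric(p$fold_change),
               log2_fc = as.numeric(p$log2_fc),
               enriched = as.logical(p$enriched),
               rank = as.numeric(p$ranks),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  enr <- enrichment_counts(profiles)
  enr_df <- data.frame(residue = names(enr), n_enriched = as.integer(enr),
                       stringsAsFactors = FALSE)
  ranks <- aggregate_ranks(profiles, tracked)
  write_tsv(long, file.path(out_dir, "composition_profiles.tsv"))
  write_tsv(enr_df, file.path(out_dir, "enrichment_counts.tsv"))
  write_tsv(ranks, file.path(out_dir, "aggregate_ranks.tsv"))
  invisible(list(profiles = profiles, enrichment = enr, ranks = ranks))
}

#' Run the motif stage: align, extract, consensus, PFMs
#'
#' Aligns every cohort protein to the reference, extracts the annotated
#' motif windows, computes per-motif position frequencies and consensus
#' patterns, and writes the instance table, the consensus table and one
#' percentage PFM per motif.
#'
#' @param fasta Input FASTA.
#' @param out_dir Output directory.
#' @param reference Reference sequence string; default the packaged
#'   synthetic reference.
#' @param annotation Motif annotation data frame; default derived from the
#'   reference by [derive_motif_annotation()].
#' @return Invisibly, a list with `instances` and `consensus` (named list
#'   of `motif_consensus`).
#' @export
run_motifs <- function(fasta, out_dir, reference = NULL, annotation = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_fasta(fasta)
  if (is.null(reference)) reference <- synthetic_reference()$sequence
  if (is.null(annotation)) annotation <- derive_motif_annotation(reference)
  instances <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(k) {
    aln <- global_align(cohort$sequence[[k]], reference)
    extract_motifs(aln, annotation, cohort$id[[k]])
  }))
  if (is.null(instances)) {
    stop("validation error: empty cohort in run_motifs()")
  }
  consensus <- lapply(split(instances, instances$motif_id), function(sub) {
    position_frequencies(
      sub, motif_canonical_length(sub$motif_id[[1L]]))
  })
  consensus <- consensus[intersect(MOTIF_ID_ORDER, names(consensus))]
  cons_df <- do.call(rbind, lapply(consensus, function(cs) {
    data.frame(motif_id = cs$motif_id, n_counted = cs$n_counted,
               consensus = cs$consensus_pattern, stringsAsFactors = FALSE)
  }))
  rownames(cons_df) <- NULL
  write_tsv(instances, file.path(out_dir, "motif_instances.tsv"))
  write_tsv(cons_df, file.path(out_dir, "motif_consensus.tsv"))
  for (cs in consensus) {
    export_pfm(cs, file.path(out_dir, paste0("pfm_", cs$motif_id, ".tsv")))
  }
  invisible(list(instances = instances, consensus = consensus))
}

#' Run the identity stage: matrix, clustering, heatmap table, Newick
#'
#' @param fasta Input FASTA (at least two records).
#' @param out_dir Output directory.
#' @param linkage Linkage for [cluster_identity()].
#' @return Invisibly, a list with `matrix`, `hclust`, `newick`.
#' @export
run_identity <- function(fasta, out_dir, linkage = "average") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_fasta(fasta)
  im <- identity_matrix(cohort)
  hc <- cluster_identity(im, linkage)
  export_heatmap(im, hc, file.path(out_dir, "identity_heatmap.tsv"))
  nwk <- to_newick(hc, file.path(out_dir, "identity_tree.nwk"))
  summary_df <- data.frame(statistic = c("mean", "min", "max"),
                           percent_identity = as.numeric(im$summary),
                           stringsAsFactors = FALSE)
  write_tsv(summary_df, file.path(out_dir, "identity_summary.tsv"))
  invisible(list(matrix = im, hclust = hc, newick = nwk))
}
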