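#' All-vs-all percent-identity matrix
#'
#' Computes global pairwise alignments ([global_align()]) for every pair of
#' cohort sequences and assembles the symmetric percent-identity matrix
#' (diagonal 100). Identity is identical aligned columns divided by columns
#' containing at least one residue, times 100. Each unordered pair is
#' aligned once and mirrored, so the matrix is symmetric by construction.
#'
#' @param cohort Cohort data frame with at least two records.
#' @param ... Alignment parameters passed to [global_align()].
#' @return Object of class `identity_matrix`: list with `labels`, `values`
#'   (n x n numeric matrix) and `summary` (named vector `mean`, `min`,
#'   `max` over the off-diagonal upper triangle).
#' @export
identity_matrix <- function(cohort, ...) {
  n <- nrow(cohort)
  if (n < 2L) {
    stop("validation error: identity_matrix() needs at least 2 records")
  }
  if (anyDuplicated(cohort$id)) {
    stop("validation error: duplicated ids in cohort")
  }
  values <- diag(100, n)
  dimnames(values) <- list(cohort$id, cohort$id)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pid <- global_align(cohort$sequence[[i]], cohort$sequence[[j]],
                          ...)$percent_identity
      values[i, j] <- pid
      values[j, i] <- pid
    }
  }
  upper <- values[upper.tri(values)]
  structure(list(labels = cohort$id, values = values,
                 summary = c(mean = mean(upper), min = min(upper),
                             max = max(upper))),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("Percent-identity matrix over", length(x$labels), "proteins\n")
  cat(sprintf("  off-diagonal mean %.2f%%, range %.2f%%-%.2f%%\n",
              x$summary[["mean"]], x$summary[["min"]], x$summary[["max"]]))
  invisible(x)
}

#' Hierarchically cluster an identity matrix
#'
#' Computes Euclidean distances between the rows of the percent-identity
#' matrix (each protein represented by its vector of identities to all
#' proteins) and clusters them agglomeratively. Leaf order is made
#' deterministic by reordering the dendrogram with label order as the
#' weight (ties in merge height are broken by label sort).
#'
#' @param im `identity_matrix` object.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An `hclust` object (merge list, heights, leaf order, labels).
#' @export
cluster_identity <- function(im, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d <- dist(im$values, method = "euclidean")
  hc <- hclust(d, method = linkage)
  stats::as.hclust(stats::reorder(stats::as.dendrogram(hc),
                                  match(im$labels, sort(im$labels)),
                                  agglo.FUN = mean))
}

#' Export a clustered identity matrix as a heatmap table
#'
#' Writes the identity matrix reordered to the dendrogram leaf order as a
#' labelled TSV; optionally also renders a heatmap image on a blue-to-red
#' ramp anchored at 0% and 100% identity (requires the `pheatmap` package).
#'
#' @param im `identity_matrix` object.
#' @param hc `hclust` object from [cluster_identity()]; its leaf order
#'   defines the row/column order. `NULL` keeps input order.
#' @param path Output TSV path.
#' @param image Optional PNG path for the rendered heatmap.
#' @return The reordered matrix, invisibly.
#' @export
export_heatmap <- function(im, hc = NULL, path, image = NULL) {
  ord <- if (is.null(hc)) seq_along(im$labels) else hc$order
  mat <- im$values[ord, ord, drop = FALSE]
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image) && requireNamespace("pheatmap", quietly = TRUE)) {
    ramp <- grDevices::colorRampPalette(c("blue", "white", "red"))(100)
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = ramp, breaks = seq(0, 100, length.out = 101),
                       filename = image)
  }
  invisible(mat)
}

#' Read back a heatmap TSV written by [export_heatmap()]
#'
#' @param path TSV path.
#' @return Numeric matrix with row and column labels.
#' @export
read_heatmap_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$id
  mat
}

#' Convert a dendrogram to Newick text
#'
#' Converts the `hclust` merge structure to a rooted Newick tree whose
#' branch lengths are merge-height differences (leaves sit at height 0, an
#' internal node at its merge height).
#'
#' @param hc `hclust` object from [cluster_identity()].
#' @param path Optional output file; when given the Newick text is written
#'   there as well.
#' @return Newick string (with trailing `;`).
#' @export
to_newick <- function(hc, path = NULL) {
  hc2 <- hc
  hc2$height <- hc$height * 2  # ape halves hclust heights when converting
  phy <- ape::as.phylo(hc2)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) writeLines(txt, path)
  txt
}
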