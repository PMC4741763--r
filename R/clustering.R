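# Hierarchical clustering of samples over a probe subset and export of the
# dendrogram (Newick) and reordered matrix for heatmap rendering.

#' Hierarchically cluster samples
#'
#' Distance is 1 - Pearson correlation between sample beta profiles over the
#' selected probes (pairwise-complete on missing values), or Euclidean by
#' flag; agglomeration uses the stated linkage (default average). The result
#' is deterministic given the input order, with ties resolved by
#' `stats::hclust`'s lowest-index-first convention.
#'
#' @param beta Probes x samples matrix.
#' @param probes Non-empty character vector of probes to cluster on.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `cluster_result`: `hclust` (the tree),
#'   `leaf_order` (labels left to right), `cophenetic` (distance matrix),
#'   `cut2` (two-cluster labels named by sample), `distance`, `linkage`.
#' @export
cluster_samples <- function(beta, probes, distance = c("correlation", "euclidean"),
                            linkage = "average") {
  distance <- match.arg(distance)
  if (!length(probes)) stop("probes must be non-empty")
  missing_probes <- setdiff(probes, rownames(beta))
  if (length(missing_probes))
    stop("probe(s) absent from matrix: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  X <- beta[probes, , drop = FALSE]
  if (ncol(X) < 2L) stop("need >= 2 samples")
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(X, use = "pairwise.complete.obs"))
  } else {
    stats::dist(t(X))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 cophenetic = as.matrix(stats::cophenetic(hc)),
                 cut2 = stats::cutree(hc, k = 2),
                 distance = distance, linkage = linkage),
            class = "cluster_result")
}

#' Export dendrogram and heatmap matrix
#'
#' Writes the dendrogram in Newick format (branch lengths from merge heights)
#' and the probe matrix with columns reordered by the tree's leaf order, as a
#' TSV ready for heatmap rendering.
#'
#' @param result A `cluster_result` from [cluster_samples()].
#' @param beta Probes x samples matrix (same samples as the clustering).
#' @param probes Non-empty probe subset to export.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector: manifest of written files.
#' @export
export_tree_and_heatmap <- function(result, beta, probes, out_dir) {
  stopifnot(inherits(result, "cluster_result"))
  if (!length(probes)) stop("probes must be non-empty")
  if (!setequal(result$hclust$labels, colnames(beta)))
    stop("matrix samples do not match the clustering")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(out_dir, "samples_dendrogram.nwk")
  ape::write.tree(ape::as.phylo(result$hclust), file = tree_path)
  mat_path <- file.path(out_dir, "heatmap_matrix.tsv")
  write_matrix_tsv(beta[probes, result$leaf_order, drop = FALSE], mat_path)
  c(tree = tree_path, matrix = mat_path)
}
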