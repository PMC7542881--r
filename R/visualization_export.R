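# Heatmap, dendrogram and thresholded-network views of the clustered
# similarity matrix. The testable artifacts are structural (row orders,
# edge lists, merge heights); images are a rendering of those structures.

#' Build a thresholded similarity network
#'
#' Nodes are gene-sets (annotated with cluster label and highlight score);
#' edges connect every unordered off-diagonal pair whose similarity is
#' strictly above the threshold. Isolated nodes are retained so cluster
#' membership stays visible.
#'
#' @param matrix a `SimilarityMatrix` (pass the uncapped matrix to threshold
#'   raw scores).
#' @param clustering a `ClusteringResult` over the same set_ids.
#' @param threshold non-negative edge threshold (strictly greater-than).
#' @return a `NetworkSpec`: `nodes` data.frame (set_id, cluster, highlight),
#'   `edges` data.frame (source_id, target_id, score), `threshold`, `cap`.
#' @export
build_network <- function(matrix, clustering, threshold) {
  stopifnot(inherits(matrix, "SimilarityMatrix"),
            inherits(clustering, "ClusteringResult"))
  if (!identical(matrix$set_ids, clustering$set_ids)) {
    stop("matrix and clustering refer to different set_ids")
  }
  if (threshold < 0) stop("threshold must be >= 0")

  ids <- matrix$set_ids
  s <- matrix$scores
  idx <- which(upper.tri(s) & s > threshold, arr.ind = TRUE)
  edges <- data.frame(
    source_id = ids[idx[, 1]],
    target_id = ids[idx[, 2]],
    score = s[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(
    set_id = ids,
    cluster = clustering$labels,
    highlight = if (is.null(clustering$highlight_scores)) NA_real_ else
      clustering$highlight_scores,
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges,
                 threshold = threshold, cap = matrix$cap_applied),
            class = "NetworkSpec")
}

#' @export
print.NetworkSpec <- function(x, ...) {
  cat("<NetworkSpec> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (score > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Convert a network to igraph
#'
#' @param network a `NetworkSpec`.
#' @return an undirected `igraph` graph with node attributes `cluster` and
#'   `highlight` and edge attribute `score`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "NetworkSpec"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Write a network edge list (and optionally GraphML)
#'
#' @param network a `NetworkSpec`.
#' @param path output TSV path for the edge list.
#' @param graphml_path optional GraphML output path.
#' @return the edge-list path, invisibly.
#' @export
write_edge_list <- function(network, path, graphml_path = NULL) {
  write_tsv(network$edges, path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Row/column order used by the heatmap
#'
#' A pure function of the clustering: sets ordered by cluster label, then by
#' set_id within each cluster. Exposed so the rendered order can be asserted
#' without touching pixels.
#'
#' @param clustering a `ClusteringResult`.
#' @return integer permutation of the sets.
#' @export
heatmap_order <- function(clustering) {
  order(clustering$labels, clustering$set_ids)
}

#' Render the clustered similarity heatmap
#'
#' Rows and columns follow [heatmap_order()]; the colour scale is clamped at
#' `cap` (the underlying scores are not modified); cluster labels and, when
#' present, highlight scores are drawn as annotation side bars.
#'
#' @param matrix a `SimilarityMatrix`.
#' @param clustering a `ClusteringResult` over the same set_ids.
#' @param cap optional colour-scale upper limit (e.g. 70 for RR).
#' @param out_path output image path (`.png`).
#' @return the output path, invisibly, with attributes `row_order` and
#'   `scale_max` describing the rendered structure.
#' @export
render_heatmap <- function(matrix, clustering, cap = NULL, out_path) {
  stopifnot(inherits(matrix, "SimilarityMatrix"),
            inherits(clustering, "ClusteringResult"))
  if (!identical(matrix$set_ids, clustering$set_ids)) {
    stop("matrix and clustering refer to different set_ids")
  }
  ord <- heatmap_order(clustering)
  s <- matrix$scores[ord, ord, drop = FALSE]
  scale_max <- if (!is.null(cap)) cap else max(s)
  breaks <- seq(min(s, 0), scale_max, length.out = 101)

  ann <- data.frame(cluster = factor(clustering$labels[ord]),
                    row.names = matrix$set_ids[ord])
  if (!is.null(clustering$highlight_scores)) {
    ann$highlight <- clustering$highlight_scores[ord]
  }
  ph <- pheatmap::pheatmap(
    pmin(s, scale_max),
    cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = breaks,
    annotation_row = ann, annotation_col = ann["cluster"],
    silent = TRUE)
  grDevices::png(out_path, width = 1200, height = 1000, res = 120)
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  structure(invisible(out_path), row_order = ord, scale_max = scale_max)
}

#' Average-linkage dendrogram of the gene-sets
#'
#' Agglomerates the dissimilarity transform of the similarity matrix and
#' renders the tree; the merge structure is also written as newick text so
#' topology and heights are testable.
#'
#' @param matrix a `SimilarityMatrix` with at least 2 sets.
#' @param out_path output image path (`.png`), or `NULL` to skip rendering.
#' @param newick_path optional path for the newick export.
#' @param linkage agglomeration method, default `"average"`.
#' @return the `hclust` object, invisibly.
#' @export
render_dendrogram <- function(matrix, out_path = NULL, newick_path = NULL,
                              linkage = "average") {
  stopifnot(inherits(matrix, "SimilarityMatrix"))
  if (length(matrix$set_ids) < 2) stop("need at least 2 sets")
  hc <- stats::hclust(as_dissimilarity(matrix), method = linkage)
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 1200, height = 800, res = 120)
    plot(hc, main = "Gene-set dendrogram", xlab = "", sub = "")
    grDevices::dev.off()
  }
  if (!is.null(newick_path)) {
    ape::write.tree(ape::as.phylo(hc), file = newick_path)
  }
  invisible(hc)
}
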