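# Local over-representation analysis of per-cluster gene lists against a
# user-supplied annotation GMT: a one-sided hypergeometric test per
# (cluster, term) pair with Benjamini-Hochberg adjustment within each
# cluster. Fully offline and deterministic.

#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for the number of annotated genes in a random draw of
#' `query_size` genes from a universe of `universe_size` containing
#' `term_size` annotated genes. `k = 0` returns 1 (the certain event).
#'
#' @param k_hits observed overlap count.
#' @param term_size number of annotated genes in the universe.
#' @param query_size number of genes drawn.
#' @param universe_size total universe size.
#' @return probability in `[0, 1]`.
#' @export
hyper_upper_tail <- function(k_hits, term_size, query_size, universe_size) {
  stopifnot(k_hits >= 0, term_size <= universe_size, query_size <= universe_size)
  stats::phyper(k_hits - 1, term_size, universe_size - term_size, query_size,
                lower.tail = FALSE)
}

#' Over-representation analysis per cluster
#'
#' Tests each cluster's gene list against every annotation set. The query is
#' either the union of the cluster's member genes (`gene_mode = "all"`) or
#' only the genes unique to the cluster (`"unique"`); the universe is the
#' union of the collection's universe and the annotation universe (a
#' conservative default, overridable). Clusters with an empty query are
#' skipped with a warning. Results are BH-adjusted within each cluster and
#' sorted by FDR then p-value.
#'
#' @param collection the clustered `GeneSetCollection`.
#' @param clustering a `ClusteringResult` over the same set_ids.
#' @param annotations a `GeneSetCollection` of annotation terms, harmonized
#'   to the same vocabulary (e.g. from [read_gmt()]).
#' @param gene_mode `"all"` (default) or `"unique"`.
#' @param universe_size optional explicit universe size override.
#' @return a data.frame of class `OraResult` with columns `cluster`, `term`,
#'   `k_hits`, `term_size`, `query_size`, `universe_size`, `pvalue`, `fdr`.
#' @export
ora_per_cluster <- function(collection, clustering, annotations,
                            gene_mode = c("all", "unique"),
                            universe_size = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(clustering, "ClusteringResult"),
            inherits(annotations, "GeneSetCollection"))
  gene_mode <- match.arg(gene_mode)

  gpc <- genes_per_cluster(collection, clustering)
  genes <- lapply(collection$gene_sets, `[[`, "genes")
  universe <- union(gene_universe(collection), gene_universe(annotations))
  n_univ <- if (is.null(universe_size)) length(universe) else as.integer(universe_size)

  rows <- list()
  for (i in seq_len(nrow(gpc))) {
    k <- gpc$cluster[i]
    query <- if (gene_mode == "all") {
      sort(unique(unlist(genes[clustering$labels == k], use.names = FALSE)))
    } else {
      gpc$unique[[i]]
    }
    if (length(query) == 0) {
      warning("cluster ", k, " has an empty ", gene_mode, "-gene query; skipped")
      next
    }
    res <- lapply(annotations$gene_sets, function(term) {
      hits <- length(intersect(query, term$genes))
      data.frame(
        cluster = k,
        term = term$name,
        k_hits = hits,
        term_size = length(term$genes),
        query_size = length(query),
        universe_size = n_univ,
        pvalue = hyper_upper_tail(hits, length(term$genes), length(query), n_univ),
        stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, res)
    res$fdr <- stats::p.adjust(res$pvalue, method = "BH")
    rows[[length(rows) + 1]] <- res[order(res$fdr, res$pvalue, res$term), ]
  }
  if (length(rows) == 0) {
    stop("every cluster had an empty query; nothing to test")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("OraResult", "data.frame")
  out
}
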