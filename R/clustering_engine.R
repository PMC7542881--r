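# Clustering of gene-sets from the similarity matrix, selection of the
# number of clusters, highlight scoring against a user gene subset, and
# per-cluster shared/unique gene summaries.

# Features for k-means / gap: each gene-set is described by its similarity
# profile to every gene-set, i.e. the rows of the (optionally capped)
# similarity matrix.
feature_rows <- function(matrix) {
  f <- matrix$scores
  storage.mode(f) <- "double"
  f
}

# renumber labels 1..k by decreasing cluster size, ties broken by the
# lexicographically smallest member set_id, so output is platform-stable
canonicalize_labels <- function(labels, ids) {
  sizes <- table(labels)
  first_id <- vapply(names(sizes), function(l) min(ids[labels == l]), character(1))
  ord <- order(-as.integer(sizes), first_id)
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  as.integer(remap[as.character(labels)])
}

run_kmeans <- function(features, k, seed, nstart = 25L, iter_max = 100L) {
  set.seed(seed)
  for (attempt in seq_len(25L)) {
    fit <- tryCatch(
      stats::kmeans(features, centers = k, nstart = nstart,
                    iter.max = iter_max, algorithm = "Lloyd"),
      error = function(e) e, warning = function(w) {
        # empty-cluster / non-convergence warnings: retry from new seeds
        tryCatch(suppressWarnings(
          stats::kmeans(features, centers = k, nstart = nstart,
                        iter.max = iter_max, algorithm = "Lloyd")),
          error = function(e) e)
      })
    if (!inherits(fit, "error")) return(fit)
  }
  stop("k-means failed to produce ", k, " non-empty clusters after 25 restarts")
}

#' Cluster gene-sets
#'
#' Partitions the gene-sets into `k` clusters. `"kmeans"` runs Lloyd's
#' algorithm with 25 restarts on the similarity-profile rows (deterministic
#' under `seed`); `"hierarchical"` agglomerates the dissimilarity transform
#' (average linkage by default) and cuts the tree at `k`. A custom function
#' may be supplied: it receives the `SimilarityMatrix` and `k` and must
#' return one integer label per set. Labels are renumbered 1..k by
#' decreasing cluster size (ties by smallest member set_id).
#'
#' @param matrix a `SimilarityMatrix` (cap first with [cap_matrix()] if
#'   capped features are wanted).
#' @param k number of clusters, `2 <= k < n_sets`.
#' @param method `"kmeans"`, `"hierarchical"`, or a function.
#' @param seed integer seed driving the k-means restarts.
#' @param linkage hierarchical linkage: `"average"` (default), `"complete"`,
#'   `"single"` or `"ward.D2"`.
#' @return a `ClusteringResult`.
#' @export
cluster_gene_sets <- function(matrix, k, method = c("kmeans", "hierarchical"),
                              seed = 1L, linkage = "average") {
  stopifnot(inherits(matrix, "SimilarityMatrix"))
  n <- length(matrix$set_ids)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < ", n)

  if (is.function(method)) {
    labels <- method(matrix, k)
    if (length(labels) != n || length(unique(labels)) != k) {
      stop("custom clustering must return ", n, " labels covering ", k, " clusters")
    }
    method_name <- "CUSTOM"
  } else {
    method_name <- toupper(match.arg(method))
    if (method_name == "KMEANS") {
      fit <- run_kmeans(feature_rows(matrix), k, seed)
      labels <- fit$cluster
    } else {
      hc <- stats::hclust(as_dissimilarity(matrix), method = linkage)
      labels <- stats::cutree(hc, k = k)
    }
  }
  labels <- canonicalize_labels(labels, matrix$set_ids)

  structure(list(
    set_ids = matrix$set_ids,
    labels = labels,
    method = method_name,
    k = as.integer(k),
    seed = as.integer(seed),
    highlight_scores = NULL,
    cluster_summaries = NULL
  ), class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat("<ClusteringResult> ", length(x$set_ids), " gene-sets in ", x$k,
      " clusters (", x$method, ", seed ", x$seed, ")\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

# mean silhouette width of a labelling on a dissimilarity
mean_silhouette <- function(labels, diss) {
  sil <- cluster::silhouette(labels, diss)
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters
#'
#' Scans `k_range` and scores each k:
#' * `"silhouette"` — mean silhouette width of the k-means labelling on the
#'   dissimilarity transform; recommended k maximizes it.
#' * `"elbow"` — total within-cluster sum of squares of the k-means fit on
#'   the similarity-profile rows; recommended k maximizes the discrete
#'   curvature (second difference) of the curve, i.e. the sharpest bend.
#' * `"gap"` — Tibshirani gap statistic with `gap_B` uniform reference
#'   datasets drawn over the feature bounding box; recommended k is the
#'   smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`.
#'
#' The full curve is always returned so the recommendation can be overridden.
#'
#' @param matrix a `SimilarityMatrix`.
#' @param method `"silhouette"`, `"elbow"` or `"gap"`.
#' @param k_range integer vector of candidate k within `[2, n_sets - 1]`;
#'   elbow and gap need at least 2 candidates.
#' @param seed integer seed for the k-means restarts and gap references.
#' @param gap_B number of gap reference datasets (default 50).
#' @return a `KSelectionCurve` with fields `method`, `k_values`,
#'   `criterion_values`, `recommended_k` and (gap only) `gap_se`.
#' @export
optimal_k <- function(matrix, method = c("silhouette", "elbow", "gap"),
                      k_range = NULL, seed = 1L, gap_B = 50L) {
  stopifnot(inherits(matrix, "SimilarityMatrix"))
  method <- match.arg(method)
  n <- length(matrix$set_ids)
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, ", n - 1, "]")
  }
  if (method != "silhouette" && length(k_range) < 2) {
    stop(method, " needs a k_range of length >= 2")
  }

  features <- feature_rows(matrix)
  gap_se <- NULL

  if (method == "silhouette") {
    diss <- as_dissimilarity(matrix)
    crit <- vapply(k_range, function(k) {
      mean_silhouette(cluster_gene_sets(matrix, k, "kmeans", seed)$labels, diss)
    }, numeric(1))
    rec <- k_range[which.max(crit)]
  } else if (method == "elbow") {
    crit <- vapply(k_range, function(k) {
      run_kmeans(features, k, seed)$tot.withinss
    }, numeric(1))
    if (length(k_range) >= 3) {
      curv <- crit[-c(1, length(crit))]
      d2 <- crit[seq_len(length(crit) - 2)] - 2 * curv + crit[-(1:2)]
      rec <- k_range[1 + which.max(d2)]
    } else {
      rec <- k_range[which.min(crit)]
    }
  } else {
    set.seed(seed)
    gap_fit <- cluster::clusGap(
      features,
      FUNcluster = function(x, k) {
        list(cluster = suppressWarnings(
          stats::kmeans(x, k, nstart = 25, iter.max = 100,
                        algorithm = "Lloyd")$cluster))
      },
      K.max = max(k_range), B = gap_B, d.power = 2,
      spaceH0 = "original", verbose = FALSE)
    tab <- gap_fit$Tab[k_range, , drop = FALSE]
    crit <- tab[, "gap"]
    gap_se <- tab[, "SE.sim"]
    rec <- k_range[length(k_range)]
    for (i in seq_len(length(k_range) - 1)) {
      if (crit[i] >= crit[i + 1] - gap_se[i + 1]) { rec <- k_range[i]; break }
    }
  }

  structure(list(
    method = toupper(method),
    k_values = k_range,
    criterion_values = unname(crit),
    recommended_k = as.integer(rec),
    gap_se = unname(gap_se)
  ), class = "KSelectionCurve")
}

#' @export
print.KSelectionCurve <- function(x, ...) {
  cat("<KSelectionCurve> ", x$method, " over k = ",
      paste(range(x$k_values), collapse = ".."),
      " | recommended k = ", x$recommended_k, "\n", sep = "")
  invisible(x)
}

#' Highlight clusters by a user gene subset
#'
#' Scores each gene-set by the fraction of its genes found in a
#' user-supplied subset (e.g. reactive-oxygen-signalling genes), and each
#' cluster by the mean of its members' scores, so clusters enriched for a
#' biological theme stand out in heatmaps and exports.
#'
#' @param collection the `GeneSetCollection` the clustering was computed on.
#' @param clustering a `ClusteringResult`.
#' @param subset character vector of gene IDs (same vocabulary); cleaned via
#'   [clean_gene_tokens()].
#' @return the `ClusteringResult` with `highlight_scores` (per set, in
#'   `[0, 1]`) filled in.
#' @export
highlight_score <- function(collection, clustering, subset) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(clustering, "ClusteringResult"))
  if (!identical(set_ids(collection), clustering$set_ids)) {
    stop("collection and clustering refer to different set_ids")
  }
  subset <- clean_gene_tokens(subset)
  if (length(subset) == 0) stop("highlight subset is empty")
  if (length(intersect(subset, gene_universe(collection))) == 0) {
    warning("highlight subset is disjoint from the gene universe; all scores 0")
  }
  clustering$highlight_scores <- vapply(collection$gene_sets, function(s) {
    length(intersect(s$genes, subset)) / length(s$genes)
  }, numeric(1), USE.NAMES = FALSE)
  clustering
}

#' Shared and unique genes per cluster
#'
#' For each cluster: the genes present in *every* member set (shared) and the
#' genes found in this cluster's union but in no other cluster (unique).
#'
#' @param collection the `GeneSetCollection`.
#' @param clustering a `ClusteringResult` over the same set_ids.
#' @return a data.frame with columns `cluster`, `n_sets`, `mean_highlight`,
#'   `shared_genes`, `unique_genes` (gene lists joined by `;`), plus list
#'   columns `shared` and `unique` carrying the raw character vectors.
#' @export
genes_per_cluster <- function(collection, clustering) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(clustering, "ClusteringResult"))
  if (!identical(set_ids(collection), clustering$set_ids)) {
    stop("collection and clustering refer to different set_ids")
  }
  genes <- lapply(collection$gene_sets, `[[`, "genes")
  ks <- sort(unique(clustering$labels))
  unions <- lapply(ks, function(k) {
    sort(unique(unlist(genes[clustering$labels == k], use.names = FALSE)))
  })
  shared <- lapply(ks, function(k) {
    sort(Reduce(intersect, genes[clustering$labels == k]))
  })
  uniq <- lapply(seq_along(ks), function(i) {
    others <- unlist(unions[-i], use.names = FALSE)
    setdiff(unions[[i]], others)
  })
  mean_hl <- if (!is.null(clustering$highlight_scores)) {
    vapply(ks, function(k) mean(clustering$highlight_scores[clustering$labels == k]),
           numeric(1))
  } else rep(NA_real_, length(ks))

  out <- data.frame(
    cluster = ks,
    n_sets = vapply(ks, function(k) sum(clustering$labels == k), integer(1)),
    mean_highlight = mean_hl,
    shared_genes = vapply(shared, paste, character(1), collapse = ";"),
    unique_genes = vapply(uniq, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  out$shared <- shared
  out$unique <- uniq
  out
}
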