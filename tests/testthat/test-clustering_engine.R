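planted_sim <- function(seed = 7L, metric = "RR") {
  g <- make_planted(seed = seed)
  list(sim = build_similarity_matrix(g$collection, metric),
       labels = g$labels, collection = g$collection)
}

test_that("both methods recover the planted 3-group structure", {
  p <- planted_sim()
  for (method in c("kmeans", "hierarchical")) {
    cl <- cluster_gene_sets(p$sim, 3, method, seed = 1)
    expect_gte(ari(cl$labels, p$labels), 0.9)
    expect_equal(sort(unique(cl$labels)), 1:3)
  }
})

test_that("clustering is deterministic under a fixed seed", {
  p <- planted_sim()
  a <- cluster_gene_sets(p$sim, 3, "kmeans", seed = 42)
  b <- cluster_gene_sets(p$sim, 3, "kmeans", seed = 42)
  expect_identical(a$labels, b$labels)
})

test_that("k bounds are enforced and k = n-1 leaves one pair together", {
  coll <- create_collection(paste0("s", 1:5),
                            list(c("A", "B", "C"), c("A", "B", "D"),
                                 c("P", "Q"), c("R", "S"), c("T", "U")),
                            "e")
  sim <- build_similarity_matrix(coll, "JACCARD")
  expect_error(cluster_gene_sets(sim, 1), "k must")
  expect_error(cluster_gene_sets(sim, 5), "k must")
  cl <- cluster_gene_sets(sim, 4, "hierarchical")
  sizes <- table(cl$labels)
  expect_equal(sort(as.integer(sizes)), c(1, 1, 1, 2))
  # the size-2 cluster is exactly the overlapping pair
  pair <- names(which(table(cl$labels) == 2))
  members <- cl$set_ids[cl$labels == as.integer(pair)]
  expect_setequal(members, c("e::GENERIC::s1", "e::GENERIC::s2"))
})

test_that("identical gene-sets always share a cluster", {
  coll <- create_collection(c("dup1", "dup2", "x", "y"),
                            list(c("A", "B", "C"), c("A", "B", "C"),
                                 c("P", "Q", "R"), c("S", "T")),
                            "e")
  for (metric in c("RR", "JACCARD", "KAPPA")) {
    sim <- build_similarity_matrix(coll, metric)
    for (method in c("kmeans", "hierarchical")) {
      for (k in 2:3) {
        cl <- cluster_gene_sets(sim, k, method, seed = 3)
        expect_equal(cl$labels[1], cl$labels[2],
                     info = paste(metric, method, k))
      }
    }
  }
})

test_that("labels are canonical: decreasing size, ties by smallest set_id", {
  p <- planted_sim()
  cl <- cluster_gene_sets(p$sim, 3, "hierarchical")
  sizes <- as.integer(table(cl$labels))
  expect_true(all(diff(sizes) <= 0))
  # equal-size planted groups: tie broken by smallest member id
  first_ids <- vapply(1:3, function(k) min(cl$set_ids[cl$labels == k]),
                      character(1))
  expect_equal(first_ids, sort(first_ids))
})

test_that("hierarchical clustering is invariant to input row order", {
  p <- planted_sim()
  set.seed(5)
  perm <- sample(n_sets(p$collection))
  permuted <- p$collection
  permuted$gene_sets <- permuted$gene_sets[perm]
  sim_p <- build_similarity_matrix(permuted, "RR")
  a <- cluster_gene_sets(p$sim, 3, "hierarchical")
  b <- cluster_gene_sets(sim_p, 3, "hierarchical")
  expect_equal(ari(a$labels[perm], b$labels), 1)
})

test_that("custom clustering functions are validated and relabelled", {
  p <- planted_sim()
  cl <- cluster_gene_sets(p$sim, 3, method = function(m, k) {
    rep_len(1:k, length(m$set_ids))
  })
  expect_equal(cl$method, "CUSTOM")
  expect_equal(sort(unique(cl$labels)), 1:3)
  expect_error(cluster_gene_sets(p$sim, 3, method = function(m, k) rep(1, 24)),
               "custom clustering")
})

test_that("median ARI over 20 replicates is >= 0.9 for both methods", {
  aris <- sapply(1:20, function(s) {
    p <- planted_sim(seed = s)
    c(kmeans = ari(cluster_gene_sets(p$sim, 3, "kmeans", seed = s)$labels,
                   p$labels),
      hier = ari(cluster_gene_sets(p$sim, 3, "hierarchical")$labels, p$labels))
  })
  expect_gte(median(aris["kmeans", ]), 0.9)
  expect_gte(median(aris["hier", ]), 0.9)
})

test_that("silhouette, gap and elbow all recommend the planted k", {
  p <- planted_sim()
  expect_equal(optimal_k(p$sim, "silhouette", 2:6, seed = 1)$recommended_k, 3)
  expect_equal(optimal_k(p$sim, "gap", 2:6, seed = 1, gap_B = 50)$recommended_k, 3)
  expect_equal(optimal_k(p$sim, "elbow", 2:6, seed = 1)$recommended_k, 3)

  # silhouette at the planted k beats its neighbours
  curve <- optimal_k(p$sim, "silhouette", 2:4, seed = 1)
  expect_true(curve$criterion_values[2] > curve$criterion_values[1])
  expect_true(curve$criterion_values[2] > curve$criterion_values[3])
})

test_that("elbow WSS curve is non-increasing in k and k_range is validated", {
  p <- planted_sim()
  curve <- optimal_k(p$sim, "elbow", 2:8, seed = 1)
  expect_true(all(diff(curve$criterion_values) <= 1e-6))
  expect_error(optimal_k(p$sim, "elbow", k_range = 3), "length >= 2")
  expect_error(optimal_k(p$sim, "gap", k_range = 3), "length >= 2")
  expect_error(optimal_k(p$sim, "silhouette", k_range = c(1, 2)), "k_range")
})

test_that("highlight scores are per-set fractions with per-cluster means", {
  coll <- create_collection(c("a", "b", "c"),
                            list(c("A", "B", "C", "D"), c("A", "B", "X", "Y", "Z"),
                                 c("P", "Q")),
                            "e")
  sim <- build_similarity_matrix(coll, "JACCARD")
  cl <- cluster_gene_sets(sim, 2, "hierarchical")
  cl <- highlight_score(coll, cl, c("A", "B"))
  expect_equal(cl$highlight_scores,
               c(0.5, 0.4, 0)[match(set_ids(coll), cl$set_ids)])
  gpc <- genes_per_cluster(coll, cl)
  ab_cluster <- gpc$cluster[gpc$n_sets == 2]
  expect_equal(gpc$mean_highlight[gpc$cluster == ab_cluster], 0.45)

  # saturation and disjoint warnings
  sat <- highlight_score(coll, cl, gene_universe(coll))
  expect_true(all(sat$highlight_scores == 1))
  expect_warning(dis <- highlight_score(coll, cl, "ZZZ"), "disjoint")
  expect_true(all(dis$highlight_scores == 0))
})

test_that("genes_per_cluster matches brute-force set algebra", {
  coll <- create_collection(c("a", "b", "x"),
                            list(c("A", "B", "C"), c("B", "C", "D"), c("X", "Y")),
                            "e")
  cl <- structure(list(set_ids = set_ids(coll), labels = c(1L, 1L, 2L),
                       method = "CUSTOM", k = 2L, seed = 0L,
                       highlight_scores = NULL, cluster_summaries = NULL),
                  class = "ClusteringResult")
  gpc <- genes_per_cluster(coll, cl)
  expect_equal(gpc$shared[[1]], c("B", "C"))
  expect_equal(gpc$unique[[1]], c("A", "B", "C", "D"))
  expect_equal(gpc$shared[[2]], c("X", "Y"))  # singleton cluster: its own genes
  expect_equal(gpc$unique[[2]], c("X", "Y"))
})

test_that("shared/unique summaries equal brute force on random clusterings", {
  set.seed(202)
  for (rep in 1:100) {
    coll <- random_collection(n_sets = sample(4:8, 1), universe_size = 25)
    n <- n_sets(coll)
    k <- sample(2:(n - 1), 1)
    labels <- sample(rep_len(1:k, n))
    cl <- structure(list(set_ids = set_ids(coll), labels = labels,
                         method = "CUSTOM", k = k, seed = 0L,
                         highlight_scores = NULL, cluster_summaries = NULL),
                    class = "ClusteringResult")
    gpc <- genes_per_cluster(coll, cl)
    genes <- lapply(coll$gene_sets, `[[`, "genes")
    for (i in seq_len(nrow(gpc))) {
      kk <- gpc$cluster[i]
      expect_equal(gpc$shared[[i]], sort(Reduce(intersect, genes[labels == kk])))
      un <- setdiff(unlist(genes[labels == kk]), unlist(genes[labels != kk]))
      expect_setequal(gpc$unique[[i]], un)
    }
    expect_lte(sum(lengths(gpc$unique)), length(gene_universe(coll)))

    # relabelling permutation never changes the per-cluster contents
    perm <- sample(k)
    cl2 <- cl; cl2$labels <- perm[labels]
    gpc2 <- genes_per_cluster(coll, cl2)
    for (i in seq_len(nrow(gpc))) {
      j <- which(gpc2$cluster == perm[gpc$cluster[i]])
      expect_equal(gpc2$shared[[j]], gpc$shared[[i]])
      expect_equal(gpc2$unique[[j]], gpc$unique[[i]])
    }
  }
})
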