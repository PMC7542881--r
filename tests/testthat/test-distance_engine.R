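gs <- function(genes, id = paste(genes, collapse = "")) {
  new_gene_set(id, id, genes, experiment = "e")
}

test_that("overlap counts are exact and guard the universe precondition", {
  oc <- overlap_counts(gs(c("A", "B", "C")), gs(c("B", "C", "D")), 10)
  expect_equal(oc$c_ij, 2); expect_equal(oc$p_i, 3); expect_equal(oc$p_j, 3)
  expect_equal(overlap_counts(gs(c("A", "B")), gs(c("A", "B")), 5)$c_ij, 2)
  expect_equal(overlap_counts(gs("A"), gs("B"), 5)$c_ij, 0)
  expect_error(overlap_counts(gs(c("A", "B", "C")), gs("D"), 2), "universe_size")
})

test_that("the worked micro-case matches hand-derived constants", {
  # c=2, p_i=p_j=3, n=10: RR = 2*10/(3*3-2) = 20/7, J = 2/4, kappa = 11/21
  oc <- overlap_counts(gs(c("A", "B", "C")), gs(c("B", "C", "D")), 10)
  expect_equal(relative_risk(oc), 20 / 7, tolerance = 1e-12)
  expect_equal(jaccard(oc), 0.5, tolerance = 1e-12)
  expect_equal(cohens_kappa(oc), 11 / 21, tolerance = 1e-12)
})

test_that("metric degenerate cases follow the documented conventions", {
  zero <- structure(list(c_ij = 0, p_i = 4, p_j = 7, n = 20),
                    class = "OverlapCounts")
  expect_equal(relative_risk(zero), 0)
  expect_equal(jaccard(zero), 0)

  singleton <- structure(list(c_ij = 1, p_i = 1, p_j = 1, n = 10),
                         class = "OverlapCounts")
  expect_identical(relative_risk(singleton), Inf)

  ident <- overlap_counts(gs(c("A", "B", "C")), gs(c("A", "B", "C")), 10)
  expect_equal(jaccard(ident), 1)
  expect_equal(cohens_kappa(ident), 1)

  full <- structure(list(c_ij = 5, p_i = 5, p_j = 5, n = 5),
                    class = "OverlapCounts")
  expect_equal(cohens_kappa(full), 1)  # p_e = 1 convention
})

test_that("all three metrics agree with the brute-force contingency oracle", {
  set.seed(101)
  for (rep in seq_len(1000)) {
    pr <- random_set_pair()
    oc <- overlap_counts(gs(pr$i, "i"), gs(pr$j, "j"), length(pr$universe))
    truth <- oracle_metrics(pr$i, pr$j, pr$universe)
    expect_equal(relative_risk(oc), truth$rr, tolerance = 1e-9)
    expect_equal(jaccard(oc), truth$jaccard, tolerance = 1e-9)
    expect_equal(cohens_kappa(oc), truth$kappa, tolerance = 1e-9)
  }
})

test_that("metrics are non-decreasing in the overlap count", {
  for (p_i in c(2, 5, 9)) {
    for (p_j in c(3, 7)) {
      n <- 20
      vals <- lapply(0:min(p_i, p_j), function(c_ij) {
        oc <- structure(list(c_ij = c_ij, p_i = p_i, p_j = p_j, n = n),
                        class = "OverlapCounts")
        c(rr = relative_risk(oc), j = jaccard(oc), k = cohens_kappa(oc))
      })
      m <- do.call(rbind, vals)
      for (col in colnames(m)) expect_true(all(diff(m[, col]) >= -1e-12))
    }
  }
})

test_that("similarity matrices are symmetric and match the pairwise oracle", {
  set.seed(55)
  coll <- random_collection(n_sets = 10, universe_size = 40)
  n_univ <- length(gene_universe(coll))
  for (metric in c("RR", "JACCARD", "KAPPA")) {
    sim <- build_similarity_matrix(coll, metric)
    expect_true(max(abs(sim$scores - t(sim$scores))) < 1e-12)
    fun <- switch(metric, RR = relative_risk, JACCARD = jaccard,
                  KAPPA = cohens_kappa)
    for (i in 1:10) {
      for (j in 1:10) {
        oc <- overlap_counts(coll$gene_sets[[i]], coll$gene_sets[[j]], n_univ)
        v <- fun(oc)
        if (is.infinite(v)) next  # replaced at matrix level
        expect_equal(sim$scores[i, j], v, tolerance = 1e-9)
      }
    }
  }
})

test_that("the RR diagonal follows N/(P-1) and disjoint sets score zero", {
  coll <- create_collection(c("a", "b", "c"),
                            list(c("A", "B", "C"), c("D", "E"), c("F", "G")),
                            "e")
  sim <- build_similarity_matrix(coll, "RR")
  n <- length(gene_universe(coll))
  expect_equal(diag(sim$scores), c(n / 2, n / 1, n / 1),
               ignore_attr = TRUE)  # N/(P_i - 1)
  expect_true(all(sim$scores[upper.tri(sim$scores)] == 0))
})

test_that("identical singleton pairs produce the Inf sentinel and get replaced", {
  coll <- create_collection(c("s1", "s2", "big1", "big2"),
                            list("A", "A", c("B", "C", "D"), c("C", "D", "E")),
                            "e")
  sim <- build_similarity_matrix(coll, "RR")
  expect_true(sim$infinite_replaced > 0)
  expect_true(all(is.finite(sim$scores)))
  off <- sim$scores[row(sim$scores) != col(sim$scores)]
  # replaced entries equal the largest finite off-diagonal value
  expect_equal(sim$scores["e::GENERIC::s1", "e::GENERIC::s2"], max(off))
})

test_that("matrix build is order-independent up to the same permutation", {
  set.seed(9)
  coll <- random_collection(n_sets = 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  permuted <- coll
  permuted$gene_sets <- permuted$gene_sets[perm]
  s1 <- build_similarity_matrix(coll, "JACCARD")$scores
  s2 <- build_similarity_matrix(permuted, "JACCARD")$scores
  expect_equal(s2, s1[perm, perm], tolerance = 1e-12)
})

test_that("custom metrics are applied per pair and must be finite", {
  coll <- create_collection(c("a", "b"), list(c("A", "B"), c("B", "C")), "e")
  sim <- build_similarity_matrix(coll, function(oc) oc$c_ij / oc$n)
  expect_equal(sim$metric, "CUSTOM")
  expect_equal(sim$scores[1, 2], 1 / 3)
  expect_error(build_similarity_matrix(coll, function(oc) Inf), "non-finite")
})

test_that("capping clamps scores, is idempotent, and records itself", {
  coll <- create_collection(c("a", "b", "c"),
                            list(c("A", "B"), c("A", "B"), c("A", "C")), "e")
  sim <- build_similarity_matrix(coll, "RR")
  capped <- cap_matrix(sim, 1.5)
  expect_true(all(capped$scores <= 1.5))
  expect_equal(capped$cap_applied, 1.5)
  expect_equal(cap_matrix(capped, 1.5)$scores, capped$scores)
  high <- cap_matrix(sim, 1e6)
  expect_equal(high$scores, sim$scores)
  expect_error(cap_matrix(sim, -1), "positive")
  expect_error(cap_matrix(sim, 0), "positive")
})
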