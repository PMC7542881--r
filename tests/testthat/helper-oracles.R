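# Independent oracles and small generators shared across tests.

# Brute-force 2x2 gene x membership contingency oracle: enumerates every
# universe gene, tabulates joint membership, and computes each metric from
# the table. Independent of the OverlapCounts path in the package.
oracle_metrics <- function(genes_i, genes_j, universe) {
  in_i <- universe %in% genes_i
  in_j <- universe %in% genes_j
  a <- sum(in_i & in_j)        # in both
  b <- sum(in_i & !in_j)       # only i
  c2 <- sum(!in_i & in_j)      # only j
  d <- sum(!in_i & !in_j)      # in neither
  n <- length(universe)
  p_i <- a + b; p_j <- a + c2

  rr <- if (a == 0) 0 else {
    den <- p_i * p_j - a
    if (den == 0) Inf else a * n / den
  }
  jac <- a / (a + b + c2)
  p_o <- (a + d) / n
  p_e <- (p_i * p_j + (n - p_i) * (n - p_j)) / n^2
  kap <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(rr = rr, jaccard = jac, kappa = kap,
       c_ij = a, p_i = p_i, p_j = p_j, n = n)
}

# random pair of gene-sets over a shared universe
random_set_pair <- function(universe_size = NULL) {
  n <- if (is.null(universe_size)) sample(5:60, 1) else universe_size
  universe <- sprintf("G%03d", seq_len(n))
  gi <- sample(universe, sample.int(n, 1))
  gj <- sample(universe, sample.int(n, 1))
  list(i = gi, j = gj, universe = universe)
}

# random small collection for brute-force audits
random_collection <- function(n_sets = 6, universe_size = 30) {
  universe <- sprintf("G%03d", seq_len(universe_size))
  gs <- lapply(seq_len(n_sets), function(i) {
    sample(universe, sample(2:universe_size, 1))
  })
  create_collection(paste0("set", seq_len(n_sets)), gs, experiment = "rand")
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws
enum_hyper_tail <- function(k_hits, term_size, query_size, universe_size) {
  genes <- seq_len(universe_size)
  annotated <- seq_len(term_size)
  draws <- utils::combn(universe_size, query_size)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k_hits)
}

make_planted <- function(seed = 7L, ...) {
  generate_planted_collection(planted_design(seed = seed, ...))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

fixture_dir <- function() {
  d <- file.path(tempdir(), "gsclust-fixtures")
  if (!dir.exists(d)) write_fixture_files(d)
  d
}
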