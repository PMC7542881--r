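# Pairwise gene-set similarity. The default metric is the relative risk
# from comorbidity statistics,
#
#     RR_ij = C_ij * N / (P_i * P_j - C_ij)
#
# with C_ij the overlap count, P_i and P_j the set sizes and N the gene
# universe size. Jaccard (intersection over union) and Cohen's kappa
# (chance-corrected agreement of the two membership indicators over the
# universe) are alternatives, and any callable on the overlap counts can be
# plugged in.

#' Overlap counts for a pair of gene-sets
#'
#' The sufficient statistics for every pairwise metric: the intersection
#' count, the two set sizes and the universe size.
#'
#' @param set_i,set_j `GeneSet` objects (harmonized to one vocabulary).
#' @param universe_size total number of genes `N`; must be at least as large
#'   as either set.
#' @return an `OverlapCounts` object with fields `c_ij`, `p_i`, `p_j`, `n`.
#' @export
overlap_counts <- function(set_i, set_j, universe_size) {
  p_i <- length(set_i$genes); p_j <- length(set_j$genes)
  if (universe_size < max(p_i, p_j)) {
    stop("universe_size (", universe_size, ") smaller than a set (",
         max(p_i, p_j), ")")
  }
  structure(list(
    c_ij = length(intersect(set_i$genes, set_j$genes)),
    p_i = p_i, p_j = p_j, n = as.integer(universe_size)
  ), class = "OverlapCounts")
}

#' Relative risk of gene co-membership
#'
#' `RR = C*N / (P_i*P_j - C)`. Returns 0 when the overlap is 0; returns the
#' `+Inf` sentinel when the denominator vanishes (only possible for two
#' identical singleton sets, `p_i = p_j = c = 1`), to be replaced at matrix
#' level.
#'
#' @param counts an `OverlapCounts`.
#' @return non-negative numeric (possibly `Inf`).
#' @export
relative_risk <- function(counts) {
  with(counts, {
    if (c_ij == 0) return(0)
    denom <- p_i * p_j - c_ij
    if (denom == 0) return(Inf)
    c_ij * n / denom
  })
}

#' Jaccard index
#'
#' Intersection over union, in `[0, 1]`.
#'
#' @param counts an `OverlapCounts`.
#' @return numeric in `[0, 1]`.
#' @export
jaccard <- function(counts) {
  with(counts, {
    u <- p_i + p_j - c_ij
    if (u <= 0) stop("Jaccard undefined for two empty sets")
    c_ij / u
  })
}

#' Cohen's kappa of the two membership indicators
#'
#' Treats each set as a rater labelling every universe gene in/out and
#' returns the chance-corrected agreement. By convention kappa is 1 when the
#' expected agreement is already perfect (both sets equal the full universe).
#'
#' @param counts an `OverlapCounts`.
#' @return numeric in `[-1, 1]`.
#' @export
cohens_kappa <- function(counts) {
  with(counts, {
    if (n <= 0) stop("kappa needs a positive universe")
    a <- c_ij
    d <- n - p_i - p_j + c_ij
    p_o <- (a + d) / n
    p_e <- (p_i * p_j + (n - p_i) * (n - p_j)) / n^2
    if (p_e == 1) return(1)
    (p_o - p_e) / (1 - p_e)
  })
}

metric_fun <- function(metric) {
  switch(metric,
         RR = relative_risk,
         JACCARD = jaccard,
         KAPPA = cohens_kappa,
         stop("unknown metric: ", metric))
}

#' Build the pairwise similarity matrix
#'
#' Scores every pair of gene-sets (including the diagonal) under the chosen
#' metric. For the built-in metrics the overlap counts are obtained in one
#' pass from the binary membership matrix; a custom function is called per
#' pair with the `OverlapCounts` and must return a finite number.
#'
#' RR produces `Inf` for identical singleton pairs and on the diagonal of
#' singleton sets; all infinite entries are replaced by the largest finite
#' off-diagonal value of the matrix, and the number of replacements is kept
#' in `infinite_replaced`. The RR diagonal follows the same formula
#' (`N / (P_i - 1)` for sets larger than one gene).
#'
#' @param collection a harmonized `GeneSetCollection` with at least 2 sets.
#' @param metric `"RR"` (default), `"JACCARD"`, `"KAPPA"`, or a function
#'   taking an `OverlapCounts` and returning a finite numeric.
#' @param universe_size optional explicit `N`; defaults to the collection's
#'   universe size (respecting any override).
#' @return a `SimilarityMatrix`.
#' @export
build_similarity_matrix <- function(collection, metric = "RR",
                                    universe_size = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (n_sets(collection) < 2) stop("need at least 2 gene-sets")
  n_univ <- if (is.null(universe_size)) length(gene_universe(collection)) else
    as.integer(universe_size)

  ids <- set_ids(collection)
  genes <- lapply(collection$gene_sets, `[[`, "genes")
  vocab <- sort(unique(unlist(genes, use.names = FALSE)))
  M <- matrix(0L, nrow = length(ids), ncol = length(vocab),
              dimnames = list(ids, vocab))
  for (i in seq_along(genes)) M[i, genes[[i]]] <- 1L
  C <- M %*% t(M)                      # pairwise overlap counts
  p <- vapply(genes, length, integer(1))

  custom <- is.function(metric)
  if (custom) {
    S <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)) {
      for (j in i:length(ids)) {
        oc <- structure(list(c_ij = C[i, j], p_i = p[i], p_j = p[j], n = n_univ),
                        class = "OverlapCounts")
        v <- metric(oc)
        if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
          stop("custom metric returned a non-finite value for pair (",
               ids[i], ", ", ids[j], ")")
        }
        S[i, j] <- S[j, i] <- v
      }
    }
    metric_name <- "CUSTOM"
    n_inf <- 0L
  } else {
    metric_name <- match.arg(toupper(metric), c("RR", "JACCARD", "KAPPA"))
    PiPj <- outer(p, p)
    if (metric_name == "RR") {
      S <- C * n_univ / (PiPj - C)
      S[C == 0] <- 0                   # zero overlap dominates 0/0
    } else if (metric_name == "JACCARD") {
      S <- C / (outer(p, p, `+`) - C)
    } else {
      d <- n_univ - outer(p, p, `+`) + C
      p_o <- (C + d) / n_univ
      p_e <- (PiPj + outer(n_univ - p, n_univ - p)) / n_univ^2
      S <- ifelse(p_e == 1, 1, (p_o - p_e) / (1 - p_e))
    }
    dimnames(S) <- list(ids, ids)
    inf_mask <- is.infinite(S)
    n_inf <- sum(inf_mask)
    if (n_inf > 0) {
      off <- S[row(S) != col(S)]
      max_finite <- suppressWarnings(max(off[is.finite(off)]))
      if (!is.finite(max_finite)) max_finite <- 0
      S[inf_mask] <- max_finite
    }
  }

  structure(list(
    set_ids = ids,
    scores = S,
    metric = metric_name,
    cap_applied = NULL,
    infinite_replaced = as.integer(n_inf),
    universe_size = n_univ
  ), class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat("<SimilarityMatrix> ", length(x$set_ids), " x ", length(x$set_ids),
      " | metric: ", x$metric,
      if (!is.null(x$cap_applied)) paste0(" | cap: ", x$cap_applied) else "",
      " | Inf replaced: ", x$infinite_replaced, "\n", sep = "")
  invisible(x)
}

#' Cap similarity scores at an upper limit
#'
#' Clamps every score to `min(score, cap)`. Used for the heatmap colour scale
#' (large RR values otherwise swamp the palette) and optionally as the
#' clustering feature matrix. Idempotent.
#'
#' @param matrix a `SimilarityMatrix`.
#' @param cap positive upper limit.
#' @return a new `SimilarityMatrix` with `cap_applied` recorded.
#' @export
cap_matrix <- function(matrix, cap) {
  stopifnot(inherits(matrix, "SimilarityMatrix"))
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive")
  matrix$scores <- pmin(matrix$scores, cap)
  matrix$cap_applied <- cap
  matrix
}

#' Dissimilarity transform of a similarity matrix
#'
#' Monotone, bounded conversions used for hierarchical clustering and
#' silhouette widths: Jaccard `1 - s`; kappa `(1 - s)/2`; RR (and custom
#' metrics) `1 - s / max(s)` after replacing infinities. The diagonal is
#' forced to zero.
#'
#' @param matrix a `SimilarityMatrix`.
#' @return a base-R `dist` object.
#' @export
as_dissimilarity <- function(matrix) {
  stopifnot(inherits(matrix, "SimilarityMatrix"))
  s <- matrix$scores
  d <- switch(matrix$metric,
              JACCARD = 1 - s,
              KAPPA = (1 - s) / 2,
              { mx <- max(s[is.finite(s)]); if (mx <= 0) mx <- 1; 1 - s / mx })
  d[d < 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}
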