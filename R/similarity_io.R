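# Rebuild a SimilarityMatrix object from an exported TSV, so pipeline stages
# can be chained through files (the CLI's only intermediate format).

#' Reconstruct a SimilarityMatrix from its TSV export
#'
#' @param path matrix TSV written by [write_outputs()].
#' @param metric metric tag the matrix was computed under.
#' @param universe_size the universe size `N` used at computation time
#'   (stored nowhere in the TSV; needed only if scores will be recomputed).
#' @return a `SimilarityMatrix`.
#' @export
similarity_from_tsv <- function(path, metric = "RR", universe_size = NA_integer_) {
  m <- read_similarity_tsv(path)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("matrix TSV is not square with matching set_id headers: ", path)
  }
  structure(list(
    set_ids = rownames(m),
    scores = m,
    metric = toupper(metric),
    cap_applied = NULL,
    infinite_replaced = 0L,
    universe_size = universe_size
  ), class = "SimilarityMatrix")
}
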