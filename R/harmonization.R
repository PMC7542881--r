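# Identifier harmonization: user-supplied mapping tables translate gene
# tokens from any namespace/species into one target symbol vocabulary, so
# collections from different tools and organisms become comparable.

#' Load a gene-ID mapping table
#'
#' Four tab-separated columns: `source_id`, `source_namespace` (e.g.
#' `"SYMBOL"`, `"ENSEMBL"`), `species`, `target_symbol`. A
#' (source_id, namespace, species) key mapping to several targets is a
#' legitimate one-to-many record; the same key repeated with *conflicting*
#' duplicated rows is collapsed, and exact duplicate rows are dropped.
#'
#' @param path path to the TSV.
#' @param provenance free-text description of where the table came from.
#' @return a `MappingTable` (data.frame with a provenance attribute).
#' @export
read_mapping_table <- function(path, provenance = path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("source_id", "source_namespace", "species", "target_symbol")
  if (!all(req %in% colnames(df))) {
    stop("mapping table must have columns: ", paste(req, collapse = ", "))
  }
  mapping_table(df, provenance)
}

#' Construct a mapping table from a data.frame
#'
#' @param df data.frame with columns `source_id`, `source_namespace`,
#'   `species`, `target_symbol`.
#' @param provenance free-text origin description.
#' @return a `MappingTable`.
#' @export
mapping_table <- function(df, provenance = "in-memory") {
  df$target_symbol <- toupper(trimws(df$target_symbol))
  if (any(!nzchar(df$target_symbol))) stop("empty target_symbol in mapping table")
  df <- unique(df)
  structure(df, class = c("MappingTable", "data.frame"), provenance = provenance)
}

#' Harmonize a collection's gene identifiers
#'
#' Replaces each gene token with its mapped target symbol(s). Lookup is
#' case-insensitive on the source ID and keyed by each set's species tag.
#' Many-to-one mappings collapse to one token (set semantics); one-to-many
#' mappings expand to all targets, with the expansion noted in the report.
#' Unmapped tokens are kept verbatim (default) or dropped, per
#' `unmapped_policy`; sets emptied by dropping are removed with a warning.
#'
#' @param collection a `GeneSetCollection`.
#' @param mapping a `MappingTable`.
#' @param source_namespace namespace the collection's tokens live in.
#' @param unmapped_policy `"keep"` (default) or `"drop"`.
#' @return `list(collection, report)` where `report` is a per-set data.frame
#'   of mapped/unmapped/collapsed counts with a `flagged` attribute set when
#'   more than half of all tokens failed to map.
#' @export
harmonize <- function(collection, mapping, source_namespace,
                      unmapped_policy = c("keep", "drop")) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(mapping, "MappingTable"))
  unmapped_policy <- match.arg(unmapped_policy)

  tab <- mapping[norm_header(mapping$source_namespace) == norm_header(source_namespace), ,
                 drop = FALSE]
  if (nrow(tab) == 0) {
    stop("namespace '", source_namespace, "' absent from mapping table")
  }
  key <- function(id, sp) paste(toupper(id), tolower(trimws(sp)), sep = "\r")
  lut <- split(tab$target_symbol, key(tab$source_id, tab$species))

  rows <- vector("list", n_sets(collection))
  keep_sets <- rep(TRUE, n_sets(collection))
  new_sets <- collection$gene_sets
  for (i in seq_len(n_sets(collection))) {
    s <- new_sets[[i]]
    hits <- lut[key(s$genes, s$species)]
    found <- !vapply(hits, is.null, logical(1))
    expanded <- sum(vapply(hits[found], length, integer(1)) > 1)
    # rebuild in the original token order so harmonization is idempotent
    out_genes <- unlist(lapply(seq_along(s$genes), function(t) {
      if (found[t]) hits[[t]]
      else if (unmapped_policy == "keep") s$genes[t]
      else character(0)
    }), use.names = FALSE)
    n_before_dedup <- length(out_genes)
    out_genes <- unique(out_genes)
    rows[[i]] <- data.frame(
      set_id = s$set_id,
      n_tokens = length(s$genes),
      mapped = sum(found),
      unmapped = sum(!found),
      one_to_many = expanded,
      collapsed = n_before_dedup - length(out_genes),
      stringsAsFactors = FALSE
    )
    if (length(out_genes) == 0) {
      warning("set '", s$set_id, "' emptied by harmonization; removed")
      keep_sets[i] <- FALSE
    } else {
      s$genes <- out_genes
      new_sets[[i]] <- s
    }
  }
  report <- do.call(rbind, rows)
  frac_unmapped <- sum(report$unmapped) / max(1, sum(report$n_tokens))
  attr(report, "flagged") <- frac_unmapped > 0.5
  if (frac_unmapped > 0.5) {
    warning(sprintf("%.0f%% of gene tokens unmapped; check namespace/species",
                    100 * frac_unmapped))
  }

  out <- new_collection(new_sets[keep_sets],
                        universe_override = collection$universe_override,
                        log = collection$log)
  out <- append_log(out, "harmonize",
                    params = list(namespace = source_namespace,
                                  unmapped_policy = unmapped_policy),
                    counts = list(mapped = sum(report$mapped),
                                  unmapped = sum(report$unmapped),
                                  sets_removed = sum(!keep_sets)))
  list(collection = out, report = report)
}

#' Collapse duplicate gene-sets within an experiment
#'
#' Gene-sets with identical gene content *and* identical
#' (experiment, source_tool) provenance are collapsed to a single set carrying
#' the lexicographically smallest name; the other names are recorded as
#' aliases. Identical content from *different* experiments is deliberately
#' kept — that cross-experiment redundancy is exactly what downstream
#' clustering should reveal. The collection's universe is unchanged.
#'
#' @param collection a harmonized `GeneSetCollection`.
#' @return `list(collection, aliases)` where `aliases` is a data.frame of
#'   (kept_set_id, alias_name, alias_set_id) records (zero rows if none).
#' @export
reduce_redundancy <- function(collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  sig <- vapply(collection$gene_sets, function(s) {
    paste(s$experiment, s$source_tool,
          paste(sort(s$genes), collapse = ","), sep = "\r")
  }, character(1))

  keep <- logical(n_sets(collection))
  alias_rows <- list()
  for (g in split(seq_len(n_sets(collection)), sig)) {
    if (length(g) == 1) { keep[g] <- TRUE; next }
    nms <- vapply(collection$gene_sets[g], `[[`, character(1), "name")
    winner <- g[order(nms, vapply(collection$gene_sets[g], `[[`,
                                  character(1), "set_id"))[1]]
    keep[winner] <- TRUE
    for (j in setdiff(g, winner)) {
      alias_rows[[length(alias_rows) + 1]] <- data.frame(
        kept_set_id = collection$gene_sets[[winner]]$set_id,
        alias_name = collection$gene_sets[[j]]$name,
        alias_set_id = collection$gene_sets[[j]]$set_id,
        stringsAsFactors = FALSE
      )
    }
  }
  aliases <- if (length(alias_rows)) do.call(rbind, alias_rows) else
    data.frame(kept_set_id = character(0), alias_name = character(0),
               alias_set_id = character(0), stringsAsFactors = FALSE)

  out <- new_collection(collection$gene_sets[sort(which(keep))],
                        universe_override = collection$universe_override,
                        log = collection$log)
  out <- append_log(out, "reduce_redundancy",
                    counts = list(sets_in = n_sets(collection),
                                  sets_out = n_sets(out),
                                  duplicates_merged = nrow(aliases)))
  list(collection = out, aliases = aliases)
}
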