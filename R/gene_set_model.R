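#' @keywords internal
"_PACKAGE"

# ---- gene token hygiene -----------------------------------------------------

#' Normalize raw gene tokens
#'
#' Trims surrounding whitespace, uppercases, drops empty strings and collapses
#' duplicates while preserving first-occurrence order. All ingest paths
#' (readers, the object creator) funnel through this so that collections from
#' different tools share one vocabulary before any comparison is made.
#'
#' @param tokens character vector of raw gene tokens.
#' @return character vector of unique, uppercase, non-empty gene IDs.
#' @export
clean_gene_tokens <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  x <- toupper(trimws(as.character(tokens)))
  x <- x[!is.na(x) & nzchar(x)]
  unique(x)
}

# ---- GeneSet ----------------------------------------------------------------

#' Construct a single gene-set
#'
#' A `GeneSet` is one named set of harmonized gene IDs together with its
#' provenance: the tool it came from, the experiment label, the species tag,
#' an optional ontology category and an optional p-value.
#'
#' @param set_id unique string key within a collection.
#' @param name display label (pathway/term name).
#' @param genes character vector of gene tokens; cleaned via
#'   [clean_gene_tokens()].
#' @param source_tool one of `"IPA"`, `"GREAT"`, `"GMT"`, `"GENERIC"`.
#' @param experiment free-text experiment label.
#' @param species free-text species tag (e.g. `"Homo sapiens"`).
#' @param category optional ontology/category label.
#' @param pvalue optional p-value in `[0, 1]`, or `NA`.
#' @param raw_genes original tokens before cleaning (kept for auditability).
#' @return an object of class `GeneSet`.
#' @export
new_gene_set <- function(set_id, name, genes, source_tool = "GENERIC",
                         experiment = "", species = "", category = NA_character_,
                         pvalue = NA_real_, raw_genes = genes) {
  source_tool <- match.arg(toupper(source_tool), c("IPA", "GREAT", "GMT", "GENERIC"))
  genes <- clean_gene_tokens(genes)
  if (length(genes) < 1) stop("GeneSet '", name, "' has no genes after cleaning")
  if (!is.na(pvalue) && (pvalue < 0 || pvalue > 1)) {
    stop("pvalue for '", name, "' outside [0, 1]: ", pvalue)
  }
  structure(list(
    set_id = as.character(set_id),
    name = as.character(name),
    genes = genes,
    source_tool = source_tool,
    experiment = as.character(experiment),
    species = as.character(species),
    category = as.character(category),
    pvalue = as.numeric(pvalue),
    raw_genes = as.character(raw_genes)
  ), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("<GeneSet> ", x$set_id, "\n  name: ", x$name,
      "\n  genes: ", length(x$genes),
      " | tool: ", x$source_tool,
      " | experiment: ", x$experiment, "\n", sep = "")
  invisible(x)
}

# ---- GeneSetCollection ------------------------------------------------------

new_collection <- function(gene_sets, universe_override = NULL, log = list()) {
  ids <- vapply(gene_sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate set_id within collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(gene_sets) <- ids
  structure(list(
    gene_sets = gene_sets,
    universe = sort(unique(unlist(lapply(gene_sets, `[[`, "genes"), use.names = FALSE))),
    universe_override = universe_override,
    log = log
  ), class = "GeneSetCollection")
}

append_log <- function(collection, operation, params = list(), counts = list()) {
  collection$log <- c(collection$log,
                      list(list(operation = operation, params = params, counts = counts)))
  collection
}

#' Number of gene-sets in a collection
#' @param collection a `GeneSetCollection`.
#' @return integer count.
#' @export
n_sets <- function(collection) length(collection$gene_sets)

#' Ordered set_ids of a collection
#' @param collection a `GeneSetCollection`.
#' @return character vector.
#' @export
set_ids <- function(collection) {
  vapply(collection$gene_sets, function(s) s$set_id, character(1), USE.NAMES = FALSE)
}

#' Gene universe of a collection
#'
#' The universe is the denominator population `N` for the overlap statistics.
#' By default it is the union of all member gene sets; an explicit
#' `universe_override` (for example all measured genes in the experiment)
#' takes precedence when present.
#'
#' @param collection a `GeneSetCollection`.
#' @return character vector of unique gene IDs.
#' @export
gene_universe <- function(collection) {
  if (!is.null(collection$universe_override)) return(collection$universe_override)
  collection$universe
}

#' Set an explicit gene universe
#'
#' @param collection a `GeneSetCollection`.
#' @param universe character vector of gene IDs (cleaned); must contain every
#'   gene appearing in the member sets.
#' @return the updated collection.
#' @export
set_universe_override <- function(collection, universe) {
  universe <- clean_gene_tokens(universe)
  missing <- setdiff(collection$universe, universe)
  if (length(missing) > 0) {
    stop("universe_override is missing ", length(missing),
         " gene(s) present in the collection, e.g. ", missing[1])
  }
  collection$universe_override <- sort(universe)
  append_log(collection, "set_universe_override",
             counts = list(universe_size = length(universe)))
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("<GeneSetCollection> ", n_sets(x), " gene-sets, universe of ",
      length(gene_universe(x)), " genes",
      if (!is.null(x$universe_override)) " (override)" else "",
      "\n", sep = "")
  exps <- unique(vapply(x$gene_sets, `[[`, character(1), "experiment"))
  cat("  experiments: ", paste(exps, collapse = ", "), "\n", sep = "")
  cat("  log entries: ", length(x$log), "\n", sep = "")
  invisible(x)
}

# ---- creation ---------------------------------------------------------------

#' Create a collection from arbitrary GSA results
#'
#' The object-creator entry point: turns any tool's output — a vector of
#' set names and a parallel list of gene vectors — into a
#' `GeneSetCollection`. Records with zero usable genes are dropped with a
#' warning rather than failing, since real exports contain annotation-only
#' rows.
#'
#' `set_id`s are assigned as `"<experiment>::<source_tool>::<name>"`; when the
#' same triple occurs more than once every occurrence gets a numeric suffix
#' (`::1`, `::2`, ...), so duplicates stay distinct and traceable.
#'
#' @param names character vector of gene-set names.
#' @param genes list of character vectors (one per name) of gene tokens.
#' @param experiment experiment label applied to all records.
#' @param source_tool provenance tag, default `"GENERIC"`.
#' @param species species tag applied to all records.
#' @param pvalue optional numeric vector of p-values (recycled `NA` if absent).
#' @param category optional character vector of category labels.
#' @return a `GeneSetCollection`.
#' @export
create_collection <- function(names, genes, experiment,
                              source_tool = "GENERIC", species = "",
                              pvalue = NULL, category = NULL) {
  if (length(names) == 0) stop("empty input: no gene-set records supplied")
  if (!is.list(genes) || length(genes) != length(names)) {
    stop("'genes' must be a list parallel to 'names'")
  }
  if (any(!nzchar(trimws(names)))) stop("every record needs a non-empty name")
  if (is.null(pvalue)) pvalue <- rep(NA_real_, length(names))
  if (is.null(category)) category <- rep(NA_character_, length(names))

  cleaned <- lapply(genes, clean_gene_tokens)
  empty <- vapply(cleaned, length, integer(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " record(s) with zero genes dropped: ",
            paste(names[empty], collapse = ", "))
  }
  keep <- which(!empty)
  if (length(keep) == 0) stop("empty input: all records had zero genes")

  base_ids <- paste(experiment, toupper(source_tool), names[keep], sep = "::")
  ids <- base_ids
  dup_bases <- unique(base_ids[duplicated(base_ids)])
  for (b in dup_bases) {
    idx <- which(base_ids == b)
    ids[idx] <- paste0(b, "::", seq_along(idx))
  }

  sets <- lapply(seq_along(keep), function(i) {
    j <- keep[i]
    new_gene_set(ids[i], names[j], cleaned[[j]], source_tool = source_tool,
                 experiment = experiment, species = species,
                 category = category[j], pvalue = pvalue[j],
                 raw_genes = genes[[j]])
  })
  out <- new_collection(sets)
  append_log(out, "create_collection",
             params = list(experiment = experiment, source_tool = source_tool),
             counts = list(records_in = length(names),
                           sets_created = length(sets),
                           records_dropped = sum(empty)))
}

# ---- merging ----------------------------------------------------------------

#' Merge several collections into one
#'
#' Concatenates gene-sets preserving their order and provenance. When the same
#' `set_id` appears in more than one input collection, every occurrence is
#' prefixed with its collection's positional index (`"c<i>::"`) — a collision
#' is never silently overwritten. Universes are recomputed as the union; an
#' explicit override survives only if every input carries the same one.
#'
#' @param ... two or more `GeneSetCollection` objects (or a single list of them).
#' @return the merged `GeneSetCollection`.
#' @export
merge_collections <- function(...) {
  colls <- list(...)
  if (length(colls) == 1 && !inherits(colls[[1]], "GeneSetCollection")) {
    colls <- colls[[1]]
  }
  if (length(colls) < 2) stop("merge_collections needs at least 2 collections")
  stopifnot(all(vapply(colls, inherits, logical(1), "GeneSetCollection")))

  all_ids <- unlist(lapply(colls, set_ids), use.names = FALSE)
  clashing <- unique(all_ids[duplicated(all_ids)])

  sets <- list()
  for (i in seq_along(colls)) {
    for (s in colls[[i]]$gene_sets) {
      if (s$set_id %in% clashing) s$set_id <- paste0("c", i, "::", s$set_id)
      sets[[length(sets) + 1]] <- s
    }
  }

  overrides <- lapply(colls, `[[`, "universe_override")
  has_override <- !vapply(overrides, is.null, logical(1))
  override <- NULL
  if (all(has_override)) {
    merged_override <- sort(unique(unlist(overrides)))
    override <- merged_override
  }

  out <- new_collection(sets, universe_override = override,
                        log = do.call(c, lapply(colls, `[[`, "log")))
  append_log(out, "merge_collections",
             counts = list(n_collections = length(colls),
                           sets_total = length(sets),
                           set_id_collisions = length(clashing)))
}

# ---- filtering --------------------------------------------------------------

#' Filter gene-sets by category and size
#'
#' Reduces a collection to the sets whose category passes a keep/drop rule and
#' whose size lies in `[min_size, max_size]`. Useful to tame very large
#' multi-ontology loads before the quadratic distance step. The input
#' collection is never mutated.
#'
#' @param collection a `GeneSetCollection`.
#' @param keep_categories optional character vector: keep only these categories.
#' @param drop_categories optional character vector: drop these categories.
#'   At most one of keep/drop may be given.
#' @param min_size,max_size inclusive size bounds on `|genes|`.
#' @return a new, filtered `GeneSetCollection`.
#' @export
manage_gene_sets <- function(collection, keep_categories = NULL,
                             drop_categories = NULL,
                             min_size = 1L, max_size = Inf) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (!is.null(keep_categories) && !is.null(drop_categories)) {
    stop("supply at most one of keep_categories/drop_categories")
  }
  if (!is.null(keep_categories) && length(keep_categories) == 0) {
    stop("keep_categories is empty: refusing to produce an empty collection")
  }
  if (min_size < 1 || min_size > max_size) {
    stop("need 1 <= min_size <= max_size")
  }

  cats <- vapply(collection$gene_sets, `[[`, character(1), "category")
  sizes <- vapply(collection$gene_sets, function(s) length(s$genes), integer(1))

  keep <- rep(TRUE, n_sets(collection))
  rule <- "none"
  if (!is.null(keep_categories)) {
    keep <- keep & (cats %in% keep_categories)
    rule <- "keep_categories"
  } else if (!is.null(drop_categories)) {
    keep <- keep & !(cats %in% drop_categories)
    rule <- "drop_categories"
  }
  size_ok <- sizes >= min_size & sizes <= max_size
  removed_by_cat <- sum(!keep)
  removed_by_size <- sum(keep & !size_ok)
  keep <- keep & size_ok

  if (!any(keep)) {
    responsible <- if (removed_by_cat >= removed_by_size) rule else "size filter"
    stop("empty collection after filtering (rule responsible: ", responsible, ")")
  }

  out <- new_collection(collection$gene_sets[keep],
                        universe_override = collection$universe_override,
                        log = collection$log)
  append_log(out, "manage_gene_sets",
             params = list(rule = rule, min_size = min_size, max_size = max_size),
             counts = list(removed_by_category = removed_by_cat,
                           removed_by_size = removed_by_size,
                           sets_remaining = sum(keep)))
}
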