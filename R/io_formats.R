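# Readers for GMT / IPA / GREAT / generic dialects and writers for all
# pipeline outputs. Every reader returns list(collection, report) where the
# report reconciles rows_read = sets_created + rows_skipped.

new_parse_report <- function(file_path, dialect, rows_read, sets_created,
                             skip_reasons = character(0)) {
  rep <- structure(list(
    file_path = file_path,
    dialect = dialect,
    rows_read = as.integer(rows_read),
    sets_created = as.integer(sets_created),
    rows_skipped = length(skip_reasons),
    skip_reasons = skip_reasons
  ), class = "ParseReport")
  if (rep$rows_read != rep$sets_created + rep$rows_skipped) {
    stop("ParseReport reconciliation failed for ", file_path,
         ": ", rep$rows_read, " != ", rep$sets_created, " + ", rep$rows_skipped)
  }
  rep
}

#' @export
print.ParseReport <- function(x, ...) {
  cat("<ParseReport> ", x$dialect, " ", x$file_path, "\n  rows read: ",
      x$rows_read, " | sets created: ", x$sets_created,
      " | skipped: ", x$rows_skipped, "\n", sep = "")
  invisible(x)
}

# normalize a header token for case/punctuation-insensitive matching
norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

match_column <- function(headers, wanted, file_path, required = TRUE) {
  idx <- which(norm_header(headers) == norm_header(wanted))
  if (length(idx) == 0) {
    if (required) stop("missing mandatory column '", wanted, "' in ", file_path)
    return(NA_integer_)
  }
  idx[1]
}

# split IPA molecule tokens: comma-separated list, complexes joined by '/'
split_molecules <- function(cell) {
  toks <- unlist(strsplit(cell, ",", fixed = TRUE), use.names = FALSE)
  unlist(strsplit(toks, "/", fixed = TRUE), use.names = FALSE)
}

# ---- GMT --------------------------------------------------------------------

#' Read a GMT gene-set file
#'
#' One gene-set per line: name, description, then member genes, all
#' tab-separated. The description is stored as the set's category when
#' non-empty. Lines with fewer than three fields are skipped with a reason.
#'
#' @param path path to the GMT file.
#' @param experiment experiment label attached to every set.
#' @param species optional species tag.
#' @param source_tool provenance tag, default `"GMT"`.
#' @return `list(collection = GeneSetCollection, report = ParseReport)`.
#' @export
read_gmt <- function(path, experiment, species = "", source_tool = "GMT") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no parsable lines in ", path)

  skip <- character(0)
  nm <- character(0); gs <- list(); cat_ <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      skip <- c(skip, paste0("line ", i, ": fewer than 3 fields"))
      next
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(toupper(trimws(genes)))) {
      message("read_gmt: duplicate gene tokens collapsed in set '", fields[1], "'")
    }
    nm <- c(nm, fields[1]); gs <- c(gs, list(genes))
    cat_ <- c(cat_, if (nzchar(fields[2])) fields[2] else NA_character_)
  }
  if (length(nm) == 0) stop("no parsable lines in ", path)

  coll <- create_collection(nm, gs, experiment = experiment,
                            source_tool = source_tool, species = species,
                            category = cat_)
  list(collection = coll,
       report = new_parse_report(path, "GMT", length(lines), n_sets(coll), skip))
}

#' Write a collection as GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$gene_sets, function(s) {
    desc <- if (is.na(s$category)) "" else s$category
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- IPA --------------------------------------------------------------------

#' Read an IPA canonical-pathways export
#'
#' Tab-delimited export with a header row containing (matched
#' case-insensitively after stripping punctuation) an
#' "Ingenuity Canonical Pathways" column, a "-log(p-value)" column, and a
#' "Molecules" column of comma-separated gene tokens. Banner lines before the
#' header are tolerated and counted as skipped. Complex notation `A/B` in the
#' molecules column is split into member genes. `pvalue` is recovered as
#' `10^-(-log10 p)`; an unparsable cell leaves the p-value absent but keeps
#' the row.
#'
#' @param path path to the export.
#' @param experiment experiment label.
#' @param species optional species tag.
#' @param column_map optional named list overriding the expected header names,
#'   with entries `name`, `neglogp`, `molecules`.
#' @return `list(collection, report)`.
#' @export
read_ipa <- function(path, experiment, species = "",
                     column_map = list(name = "Ingenuity Canonical Pathways",
                                       neglogp = "-log(p-value)",
                                       molecules = "Molecules")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header_idx <- which(vapply(lines, function(l) {
    norm_header(column_map$name) %in% norm_header(strsplit(l, "\t", fixed = TRUE)[[1]])
  }, logical(1)))[1]
  if (is.na(header_idx)) {
    stop("missing mandatory column '", column_map$name, "' in ", path)
  }
  headers <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  i_name <- match_column(headers, column_map$name, path)
  i_p <- match_column(headers, column_map$neglogp, path)
  i_mol <- match_column(headers, column_map$molecules, path)

  skip <- if (header_idx > 1) {
    paste0("line ", seq_len(header_idx - 1), ": banner before header")
  } else character(0)

  data_lines <- lines[-seq_len(header_idx)]
  nm <- character(0); gs <- list(); pv <- numeric(0)
  n_rows <- 0L
  for (i in seq_along(data_lines)) {
    n_rows <- n_rows + 1L
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < max(i_name, i_mol)) {
      skip <- c(skip, paste0("data row ", i, ": too few fields"))
      next
    }
    neglogp <- suppressWarnings(as.numeric(fields[i_p]))
    p <- if (is.na(neglogp)) NA_real_ else 10^(-neglogp)
    nm <- c(nm, fields[i_name])
    gs <- c(gs, list(split_molecules(fields[i_mol])))
    pv <- c(pv, p)
  }
  if (length(nm) == 0) stop("no parsable data rows in ", path)

  coll <- create_collection(nm, gs, experiment = experiment,
                            source_tool = "IPA", species = species,
                            pvalue = pv)
  # records dropped inside create_collection (zero genes) must stay reconciled
  dropped <- length(nm) - n_sets(coll)
  if (dropped > 0) skip <- c(skip, rep("row with zero genes", dropped))
  # the header row itself is neither a data row nor a skip
  list(collection = coll,
       report = new_parse_report(path, "IPA", header_idx - 1L + n_rows,
                                 n_sets(coll), skip))
}

# ---- GREAT ------------------------------------------------------------------

#' Read a GREAT all-ontologies export
#'
#' Tab-delimited table with an ontology column, a term-name column, a
#' hypergeometric FDR column and a comma-separated gene-list column.
#' `#`-prefixed comment lines are skipped and excluded from the row
#' reconciliation. The ontology becomes the set's category; an optional
#' `categories` argument filters immediately (delegating to
#' [manage_gene_sets()]).
#'
#' @param path path to the export.
#' @param experiment experiment label.
#' @param categories optional character vector of ontologies to keep.
#' @param species optional species tag.
#' @param column_map optional named list with entries `ontology`, `term`,
#'   `fdr`, `genes` overriding expected header names.
#' @return `list(collection, report)`.
#' @export
read_great <- function(path, experiment, categories = NULL, species = "",
                       column_map = list(ontology = "Ontology",
                                         term = "TermName",
                                         fdr = "HyperFdrQ",
                                         genes = "Genes")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]       # comments never enter rows_read
  if (length(lines) == 0) stop("no parsable lines in ", path)

  headers <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  i_ont <- match_column(headers, column_map$ontology, path)
  i_term <- match_column(headers, column_map$term, path)
  i_fdr <- match_column(headers, column_map$fdr, path)
  i_genes <- match_column(headers, column_map$genes, path)

  skip <- character(0)
  nm <- character(0); gs <- list(); pv <- numeric(0); cats <- character(0)
  for (i in seq_along(lines)[-1]) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < max(i_ont, i_term, i_genes)) {
      skip <- c(skip, paste0("line ", i, ": too few fields"))
      next
    }
    fdr <- suppressWarnings(as.numeric(fields[i_fdr]))
    nm <- c(nm, fields[i_term])
    gs <- c(gs, list(strsplit(fields[i_genes], ",", fixed = TRUE)[[1]]))
    pv <- c(pv, if (is.na(fdr)) NA_real_ else fdr)
    cats <- c(cats, fields[i_ont])
  }
  if (length(nm) == 0) stop("no parsable data rows in ", path)

  coll <- create_collection(nm, gs, experiment = experiment,
                            source_tool = "GREAT", species = species,
                            pvalue = pv, category = cats)
  dropped <- length(nm) - n_sets(coll)
  if (dropped > 0) skip <- c(skip, rep("row with zero genes", dropped))
  report <- new_parse_report(path, "GREAT", length(lines) - 1L, n_sets(coll), skip)
  if (!is.null(categories)) {
    coll <- manage_gene_sets(coll, keep_categories = categories)
  }
  list(collection = coll, report = report)
}

# ---- generic table ----------------------------------------------------------

#' Read a generic "name + gene list (+ p-value)" TSV
#'
#' Minimal dialect for any GSA tool without a dedicated reader: a header row,
#' a name column, a gene-list column (separator configurable, default `;`),
#' and an optional p-value column.
#'
#' @param path path to the TSV.
#' @param experiment experiment label.
#' @param name_col,genes_col,pvalue_col column names (pvalue optional).
#' @param gene_sep separator inside the gene-list cell.
#' @param species optional species tag.
#' @return `list(collection, report)`.
#' @export
read_generic <- function(path, experiment, name_col = "name",
                         genes_col = "genes", pvalue_col = NULL,
                         gene_sep = ";", species = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  i_name <- match_column(colnames(df), name_col, path)
  i_genes <- match_column(colnames(df), genes_col, path)
  pv <- if (!is.null(pvalue_col)) {
    as.numeric(df[[match_column(colnames(df), pvalue_col, path)]])
  } else NULL
  gs <- strsplit(as.character(df[[i_genes]]), gene_sep, fixed = TRUE)
  coll <- create_collection(as.character(df[[i_name]]), gs,
                            experiment = experiment, source_tool = "GENERIC",
                            species = species, pvalue = pv)
  dropped <- nrow(df) - n_sets(coll)
  skip <- if (dropped > 0) rep("row with zero genes", dropped) else character(0)
  list(collection = coll,
       report = new_parse_report(path, "GENERIC", nrow(df), n_sets(coll), skip))
}

# ---- writers ----------------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", na = "")
  path
}

#' Read back a similarity-matrix TSV
#'
#' @param path path written by [write_outputs()].
#' @return numeric matrix with set_id dimnames.
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Export the pipeline's tabular artifacts
#'
#' Writes (1) a gene-sets TSV with provenance, cluster label, highlight score
#' and the harmonized genes joined by `;`; (2) the square similarity matrix
#' with set_id headers; (3) a per-cluster summary (size, shared genes, unique
#' genes, mean highlight); (4) the harmonized collection as GMT. All TSVs are
#' UTF-8, tab-separated, `.` decimal, no row-index column. The three inputs
#' must refer to the same set_ids in the same order — a mismatch is an error,
#' never a silent realignment. `similarity` and `clustering` may each be
#' `NULL` for a partial-pipeline export.
#'
#' @param collection a `GeneSetCollection`.
#' @param similarity optional `SimilarityMatrix`.
#' @param clustering optional `ClusteringResult`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_outputs <- function(collection, similarity = NULL, clustering = NULL,
                          out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- set_ids(collection)
  if (!is.null(similarity) && !identical(similarity$set_ids, ids)) {
    stop("set_id order mismatch between collection and similarity matrix")
  }
  if (!is.null(clustering) && !identical(clustering$set_ids, ids)) {
    stop("set_id order mismatch between collection and clustering")
  }

  paths <- character(0)

  labels <- if (!is.null(clustering)) clustering$labels else rep(NA_integer_, length(ids))
  hl <- if (!is.null(clustering) && !is.null(clustering$highlight_scores)) {
    clustering$highlight_scores
  } else rep(NA_real_, length(ids))
  gs_df <- data.frame(
    set_id = ids,
    name = vapply(collection$gene_sets, `[[`, character(1), "name"),
    experiment = vapply(collection$gene_sets, `[[`, character(1), "experiment"),
    source_tool = vapply(collection$gene_sets, `[[`, character(1), "source_tool"),
    category = vapply(collection$gene_sets, `[[`, character(1), "category"),
    pvalue = vapply(collection$gene_sets, `[[`, numeric(1), "pvalue"),
    n_genes = vapply(collection$gene_sets, function(s) length(s$genes), integer(1)),
    cluster = labels,
    highlight_score = hl,
    genes = vapply(collection$gene_sets, function(s) paste(s$genes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  paths["gene_sets"] <- write_tsv(gs_df, file.path(out_dir, "gene_sets.tsv"))
  paths["gmt"] <- write_gmt(collection, file.path(out_dir, "gene_sets.gmt"))

  if (!is.null(similarity)) {
    m <- as.data.frame(similarity$scores)
    out <- cbind(set_id = ids, m)
    paths["similarity"] <- write_tsv(out, file.path(out_dir, "similarity_matrix.tsv"))
  } else {
    warning("no similarity matrix supplied; matrix TSV skipped")
  }

  if (!is.null(clustering)) {
    gpc <- genes_per_cluster(collection, clustering)
    summ <- data.frame(
      cluster = gpc$cluster,
      n_sets = gpc$n_sets,
      mean_highlight = gpc$mean_highlight,
      shared_genes = gpc$shared_genes,
      unique_genes = gpc$unique_genes,
      stringsAsFactors = FALSE
    )
    paths["cluster_summary"] <- write_tsv(summ, file.path(out_dir, "cluster_summary.tsv"))
  } else {
    warning("no clustering supplied; cluster summary skipped")
  }

  paths
}
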