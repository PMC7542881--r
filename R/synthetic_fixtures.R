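# Deterministic synthetic data: gene-set collections with planted cluster
# structure (for clustering/k-selection benchmarks) and small reference
# files in each supported input dialect (for the parsers).

#' Describe a planted-cluster design
#'
#' Each of `n_groups` groups owns a disjoint pool of `pool_size` genes; every
#' gene-set draws `round(within_overlap * set_size)` genes from its own pool
#' and the remainder from a shared background pool, all without replacement
#' within a set. High `within_overlap` with disjoint pools yields
#' well-separated groups.
#'
#' Defaults (3 groups of 8 sets, pools of 40, sets of 20 genes, 90% drawn
#' from the own pool, background of 200) give a compact benchmark whose
#' groups are clearly recoverable yet non-trivial: between-group overlap can
#' only arise through the shared background.
#'
#' @param n_groups number of planted groups.
#' @param sets_per_group gene-sets per group.
#' @param pool_size genes in each group-specific pool.
#' @param set_size genes drawn per set.
#' @param within_overlap expected fraction drawn from the own pool, in (0,1].
#' @param background_size genes in the shared background pool.
#' @param seed integer seed; one stream drives all draws.
#' @return a `PlantedDesign`.
#' @export
planted_design <- function(n_groups = 3L, sets_per_group = 8L, pool_size = 40L,
                           set_size = 20L, within_overlap = 0.9,
                           background_size = 200L, seed = 7L) {
  if (within_overlap <= 0 || within_overlap > 1) {
    stop("within_overlap must be in (0, 1]")
  }
  n_within <- round(within_overlap * set_size)
  if (n_within > pool_size) stop("own-pool draw exceeds pool_size")
  if (set_size - n_within > background_size) stop("background draw exceeds background_size")
  structure(list(
    n_groups = as.integer(n_groups),
    sets_per_group = as.integer(sets_per_group),
    pool_size = as.integer(pool_size),
    set_size = as.integer(set_size),
    within_overlap = within_overlap,
    background_size = as.integer(background_size),
    seed = as.integer(seed)
  ), class = "PlantedDesign")
}

#' Generate a collection with planted cluster structure
#'
#' @param design a `PlantedDesign`.
#' @return `list(collection = GeneSetCollection, labels = integer ground-truth
#'   group per set)`.
#' @export
generate_planted_collection <- function(design) {
  stopifnot(inherits(design, "PlantedDesign"))
  set.seed(design$seed)
  pools <- lapply(seq_len(design$n_groups), function(g) {
    sprintf("GRP%02d_GENE%03d", g, seq_len(design$pool_size))
  })
  background <- sprintf("BKG_GENE%03d", seq_len(design$background_size))
  n_within <- round(design$within_overlap * design$set_size)
  n_noise <- design$set_size - n_within

  nm <- character(0); gs <- list(); labels <- integer(0)
  for (g in seq_len(design$n_groups)) {
    for (i in seq_len(design$sets_per_group)) {
      own <- sample(pools[[g]], n_within)
      noise <- if (n_noise > 0) sample(background, n_noise) else character(0)
      nm <- c(nm, sprintf("group%d_set%02d", g, i))
      gs <- c(gs, list(c(own, noise)))
      labels <- c(labels, g)
    }
  }
  coll <- create_collection(nm, gs, experiment = "planted",
                            source_tool = "GENERIC", species = "synthetic")
  list(collection = coll, labels = labels)
}

# small fixed symbol vocabulary used by all file fixtures; mouse symbols map
# onto their human orthologs so the mapping fixture covers the GMT fixture
fixture_symbol_pairs <- function() {
  data.frame(
    source_id = c("Trp53", "Myc", "Egfr", "Cdkn1a", "Bax", "Casp3", "Sod1",
                  "Sod2", "Cat", "Gpx1", "Nfe2l2", "Il6", "Tnf", "Stat3"),
    source_namespace = "SYMBOL",
    species = "Mus musculus",
    target_symbol = c("TP53", "MYC", "EGFR", "CDKN1A", "BAX", "CASP3", "SOD1",
                      "SOD2", "CAT", "GPX1", "NFE2L2", "IL6", "TNF", "STAT3"),
    stringsAsFactors = FALSE
  )
}

#' Write reference input fixtures in every supported dialect
#'
#' Creates, under `out_dir`: `ipa_export.tsv` (banner line, header, 6 data
#' rows with complex notation), `great_export.tsv` (comment lines, 2
#' ontologies), `sets_mouse.gmt` (mouse symbols), `mapping_mouse_human.tsv`
#' (14 symbol pairs covering the GMT fixture), and `highlight_ros.txt` (one
#' gene per line). These synthetic files define the reference dialects the
#' readers are tested against.
#'
#' @param out_dir writable directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_fixture_files <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  ipa <- c(
    "© 2000-2020 Example export banner",
    paste("Ingenuity Canonical Pathways", "-log(p-value)", "Ratio", "z-score",
          "Molecules", sep = "\t"),
    paste("p53 Signaling", "4.2", "0.12", "1.5", "TP53,CDKN1A,BAX,MDM2", sep = "\t"),
    paste("Apoptosis Signaling", "3.1", "0.10", "-0.4", "BAX,CASP3,CASP9,BCL2", sep = "\t"),
    paste("Oxidative Stress Response", "2.0", "0.08", "NaN", "SOD1,SOD2,CAT,GPX1,NFE2L2", sep = "\t"),
    paste("IL-6 Signaling", "1.7", "0.05", "0.2", "IL6,STAT3,JAK1/JAK2,SOCS3", sep = "\t"),
    paste("Myc Mediated Apoptosis", "1.5", "0.06", "0.0", "MYC,TP53,BAX", sep = "\t"),
    paste("EGF Signaling", "1.3", "0.04", "0.9", "EGFR,STAT3,MAPK1", sep = "\t")
  )
  paths["ipa"] <- file.path(out_dir, "ipa_export.tsv")
  writeLines(ipa, paths["ipa"])

  great <- c(
    "# GREAT version 4.0.4",
    "# species assembly: hg38",
    paste("Ontology", "TermName", "HyperFdrQ", "Genes", sep = "\t"),
    paste("GO Biological Process", "apoptotic process", "0.0001",
          "TP53,BAX,CASP3,CASP9", sep = "\t"),
    paste("GO Biological Process", "response to oxidative stress", "0.002",
          "SOD1,SOD2,CAT,NFE2L2", sep = "\t"),
    paste("MSigDB Pathway", "p53 pathway", "0.01",
          "TP53,CDKN1A,MDM2", sep = "\t")
  )
  paths["great"] <- file.path(out_dir, "great_export.tsv")
  writeLines(great, paths["great"])

  gmt <- c(
    paste(c("mouse_p53_targets", "GO Biological Process",
            "Trp53", "Cdkn1a", "Bax", "Myc"), collapse = "\t"),
    paste(c("mouse_ros_defense", "GO Biological Process",
            "Sod1", "Sod2", "Cat", "Gpx1", "Nfe2l2"), collapse = "\t"),
    paste(c("mouse_inflammation", "GO Biological Process",
            "Il6", "Tnf", "Stat3"), collapse = "\t")
  )
  paths["gmt"] <- file.path(out_dir, "sets_mouse.gmt")
  writeLines(gmt, paths["gmt"])

  paths["mapping"] <- file.path(out_dir, "mapping_mouse_human.tsv")
  write_tsv(fixture_symbol_pairs(), paths["mapping"])

  paths["highlight"] <- file.path(out_dir, "highlight_ros.txt")
  writeLines(c("SOD1", "SOD2", "CAT", "GPX1", "NFE2L2"), paths["highlight"])

  paths
}
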