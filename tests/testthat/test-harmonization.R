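mouse_coll <- function() {
  create_collection(c("p53ish", "rosish"),
                    list(c("Trp53", "Myc", "Notagene"),
                         c("Sod1", "Sod2", "Cat")),
                    experiment = "m1", species = "Mus musculus")
}

mouse_map <- function() {
  mapping_table(fixture_symbol_pairs_for_tests())
}

# local copy of the bundled fixture pairs via the package generator
fixture_symbol_pairs_for_tests <- function() {
  d <- fixture_dir()
  read.delim(file.path(d, "mapping_mouse_human.tsv"), stringsAsFactors = FALSE)
}

test_that("harmonize maps symbols, keeps or drops unmapped tokens, and reports", {
  coll <- mouse_coll()
  res <- harmonize(coll, mouse_map(), "SYMBOL", unmapped_policy = "keep")
  g1 <- res$collection$gene_sets[[1]]$genes
  expect_setequal(g1, c("TP53", "MYC", "NOTAGENE"))
  expect_equal(res$report$mapped, c(2, 3))
  expect_equal(res$report$unmapped, c(1, 0))

  dropped <- harmonize(coll, mouse_map(), "SYMBOL", unmapped_policy = "drop")
  expect_setequal(dropped$collection$gene_sets[[1]]$genes, c("TP53", "MYC"))
  expect_equal(length(dropped$collection$gene_sets[[1]]$genes), 2)

  expect_error(harmonize(coll, mouse_map(), "ENSEMBL"), "absent")
})

test_that("many-to-one mappings collapse and one-to-many expand, with accounting", {
  tab <- mapping_table(data.frame(
    source_id = c("ENSG1", "ENSG2", "ENSG3", "ENSG3"),
    source_namespace = "ENSEMBL",
    species = "Homo sapiens",
    target_symbol = c("A", "A", "B1", "B2"),
    stringsAsFactors = FALSE))

  coll <- create_collection("s", list(c("ENSG1", "ENSG2")), "e",
                            species = "Homo sapiens")
  res <- harmonize(coll, tab, "ENSEMBL")
  expect_equal(res$collection$gene_sets[[1]]$genes, "A")
  expect_equal(res$report$collapsed, 1)

  coll2 <- create_collection("s", list("ENSG3"), "e", species = "Homo sapiens")
  res2 <- harmonize(coll2, tab, "ENSEMBL")
  expect_setequal(res2$collection$gene_sets[[1]]$genes, c("B1", "B2"))
  expect_equal(res2$report$one_to_many, 1)
})

test_that("harmonize is idempotent and audits total token counts", {
  coll <- mouse_coll()
  once <- harmonize(coll, mouse_map(), "SYMBOL")$collection
  twice <- harmonize(once, mouse_map(), "SYMBOL")$collection
  expect_equal(lapply(twice$gene_sets, `[[`, "genes"),
               lapply(once$gene_sets, `[[`, "genes"))

  # mapped + unmapped = original token count, per set
  rep <- harmonize(coll, mouse_map(), "SYMBOL")$report
  expect_equal(rep$mapped + rep$unmapped, rep$n_tokens)
})

test_that("mostly-unmapped input raises the prominent report flag", {
  coll <- create_collection("s", list(c("AAA", "BBB", "CCC", "Trp53")), "e",
                            species = "Mus musculus")
  expect_warning(res <- harmonize(coll, mouse_map(), "SYMBOL"), "unmapped")
  expect_true(attr(res$report, "flagged"))
})

test_that("sets emptied by drop-policy harmonization are removed with warning", {
  coll <- create_collection(c("gone", "stays"),
                            list(c("NOPE1", "NOPE2"), c("Trp53", "Myc")),
                            "e", species = "Mus musculus")
  expect_warning(res <- harmonize(coll, mouse_map(), "SYMBOL", "drop"),
                 "emptied")
  expect_equal(n_sets(res$collection), 1)
})

test_that("reduce_redundancy collapses same-experiment duplicates only", {
  coll <- create_collection(c("Y", "X", "other"),
                            list(c("A", "B"), c("B", "A"), c("C", "D")),
                            experiment = "e1")
  res <- reduce_redundancy(coll)
  expect_equal(n_sets(res$collection), 2)
  kept_names <- vapply(res$collection$gene_sets, `[[`, character(1), "name")
  expect_true("X" %in% kept_names)       # lexicographically smallest name wins
  expect_false("Y" %in% kept_names)
  expect_equal(res$aliases$alias_name, "Y")
  expect_equal(gene_universe(res$collection), gene_universe(coll))

  # identical content across experiments is preserved
  e1 <- create_collection("same", list(c("A", "B")), "e1")
  e2 <- create_collection("same", list(c("A", "B")), "e2")
  both <- merge_collections(e1, e2)
  res2 <- reduce_redundancy(both)
  expect_equal(n_sets(res2$collection), 2)

  # no duplicates: identity
  res3 <- reduce_redundancy(create_collection(c("a", "b"),
                                              list("A", "B"), "e1"))
  expect_equal(n_sets(res3$collection), 2)
  expect_equal(nrow(res3$aliases), 0)
})
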