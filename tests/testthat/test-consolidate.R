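write_taxonomy_yaml <- function(types, categories, rules = list()) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(types = types, categories = categories, rules = rules),
                   path)
  path
}

minimal_53 <- function() {
  tax <- default_taxonomy()
  lapply(seq_len(53), function(i) {
    list(name = tax$categories$category[i], type = tax$categories$type[i])
  })
}

test_that("the shipped taxonomy declares exactly 7 types and 53 categories", {
  tax <- default_taxonomy()
  expect_length(tax$types, 7)
  expect_equal(nrow(tax$categories), 53)
  expect_true(all(tax$categories$type %in% tax$types))
  ## every category has exactly one parent type
  expect_equal(anyDuplicated(tax$categories$category), 0)
})

test_that("taxonomy validation rejects wrong cardinalities and bad rules", {
  tax <- default_taxonomy()
  expect_error(read_taxonomy(write_taxonomy_yaml(tax$types[1:6], minimal_53())),
               "7", class = "pathmosaic_validation_error")
  expect_error(read_taxonomy(write_taxonomy_yaml(tax$types, minimal_53()[1:40])),
               "53", class = "pathmosaic_validation_error")
  ## rule assigning a category to the wrong parent type
  bad_rule <- list(list(kind = "regex", pattern = "x",
                        type = "Disease", category = "Carbohydrate metabolism"))
  expect_error(read_taxonomy(write_taxonomy_yaml(tax$types, minimal_53(), bad_rule)),
               "belongs to type", class = "pathmosaic_validation_error")
  ## regex that does not compile
  bad_regex <- list(list(kind = "regex", pattern = "([unclosed",
                         type = "Metabolism", category = "Carbohydrate metabolism"))
  expect_error(read_taxonomy(write_taxonomy_yaml(tax$types, minimal_53(), bad_regex)),
               "compile", class = "pathmosaic_validation_error")
})

test_that("assignment precedence is manual > ontology > regex with a flagged fallback", {
  tax <- default_taxonomy()
  ## add a manual rule that contradicts an obvious regex match
  cfg <- yaml::read_yaml(system.file("extdata", "taxonomy.yaml",
                                     package = "pathmosaic"))
  cfg$rules <- c(list(list(kind = "manual", pathway_id = "P1",
                           type = "Disease", category = "Immune diseases")),
                 cfg$rules)
  path <- tempfile(fileext = ".yaml"); yaml::write_yaml(cfg, path)
  tax2 <- read_taxonomy(path)

  coll <- make_collection(list(P1 = c("G1", "G2"), P2 = c("G1", "G3"),
                               P3 = c("G2", "G3")))
  coll$pathways$name <- c("Glycolysis core", "Glycolysis variant", "zzz opaque")
  assigned <- assign_categories(coll, tax2)
  got <- setNames(assigned$pathways$category, assigned$pathways$pathway_id)
  expect_equal(got[["P1"]], "Immune diseases")            # manual wins over regex
  expect_equal(got[["P2"]], "Carbohydrate metabolism")    # regex fallback
  expect_equal(got[["P3"]], "Unclassified")               # no rule matches
  expect_equal(assigned$assignment_report$n_unclassified, 1)
  expect_equal(assigned$assignment_report$unclassified_ids, "P3")
  ## determinism: same inputs, same output
  again <- assign_categories(coll, tax2)
  expect_equal(again$pathways$category, assigned$pathways$category)
})

test_that("ontology assignment maps descendants of a term to the term's category", {
  coll <- make_collection(list(P1 = c("G1", "G2")))
  coll$pathways$name <- "zzz opaque"  # make sure no regex rule can match
  ## ancestors are ordered root -> parent; the carbohydrate term is mapped to
  ## the carbohydrate category, so its descendant pathway inherits it
  ont <- list(P1 = c("Metabolism", "Metabolism of carbohydrates"))
  assigned <- assign_categories(coll, ontology = ont)
  expect_equal(assigned$pathways$category, "Carbohydrate metabolism")

  ## the deepest matching ancestor wins over a shallower one
  ont2 <- list(P1 = c("Disease", "Metabolism of carbohydrates"))
  cfg <- yaml::read_yaml(system.file("extdata", "taxonomy.yaml",
                                     package = "pathmosaic"))
  cfg$rules <- c(list(list(kind = "ontology_term", term = "Disease",
                           type = "Disease", category = "Other diseases")),
                 cfg$rules)
  path <- tempfile(fileext = ".yaml"); yaml::write_yaml(cfg, path)
  assigned2 <- assign_categories(coll, read_taxonomy(path), ontology = ont2)
  expect_equal(assigned2$pathways$category, "Carbohydrate metabolism")
})

test_that("the consolidated view keeps one minimal-p representative per category", {
  rows <- tibble::tibble(
    pathway_id = sprintf("P%d", 1:5),
    name = sprintf("pw%d", 1:5),
    source = "SRCA",
    pathway_type = "Metabolism",
    category = c("Carbohydrate metabolism", "Carbohydrate metabolism",
                 "Lipid metabolism", "Lipid metabolism", "Unclassified"),
    p = c(0.001, 0.01, 0.05, 0.002, 0.0001),
    q_bh = c(0.005, 0.02, 0.08, 0.006, 0.001),
    q_bonferroni = c(0.005, 0.05, 0.25, 0.01, 0.0005),
    N_S = 30L, N_U = 10L, N_Pw = 8L,
    N_u = c(7L, 3L, 2L, 5L, 6L), ratio = 0.5,
    overlap_members = replicate(5, character(0), simplify = FALSE))
  view <- consolidated_view(rows, taxonomy = default_taxonomy())
  expect_equal(nrow(view), 2)
  expect_setequal(view$pathway_id, c("P1", "P4"))
  expect_equal(view$category_pathway_count[view$pathway_id == "P1"], 2L)
  expect_equal(view$category_min_q[view$pathway_id == "P4"], 0.006)
  ## representatives carry the smallest p of their category
  for (cat in view$category) {
    expect_equal(min(rows$p[rows$category == cat]),
                 view$p[view$category == cat])
  }
  ## unclassified rows are reported separately, never as a category row
  expect_equal(attr(view, "unclassified")$pathway_id, "P5")

  ## ties on p break toward the larger overlap
  tied <- rows[1:2, ]
  tied$p <- 0.01; tied$N_u <- c(2L, 9L)
  expect_equal(consolidated_view(tied)$pathway_id, "P2")

  ## empty input and missing categories
  expect_equal(nrow(consolidated_view(rows[0, ])), 0)
  rows_na <- rows; rows_na$category[1] <- NA
  expect_error(consolidated_view(rows_na), class = "pathmosaic_contract_error")
  expect_error(consolidated_view(rows[, setdiff(names(rows), "category")]),
               class = "pathmosaic_contract_error")
})
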