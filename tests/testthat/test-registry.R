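test_that("gene-set loading excludes undersized pathways and deduplicates members", {
  gmt <- write_fixture_lines(c(
    "P1\tsingleton\tG1",
    "P2\tpair\tG1\tG2",
    "P3\tfive\tG1\tG2\tG3\tG4\tG5"
  ))
  meta <- write_fixture_tsv(standard_meta(c("P1", "P2", "P3")))
  coll <- read_gene_sets(gmt, meta, min_core_members = 2)
  expect_equal(n_pathways(coll), 2)
  expect_equal(coll$load_report$excluded_count, 1)
  expect_equal(coll$load_report$excluded_ids, "P1")
  expect_setequal(coll$pathways$pathway_id, c("SRCA:P2", "SRCA:P3"))

  ## duplicate member within one line counts once, before the size filter
  gmt2 <- write_fixture_lines("PD\tdup\tG1\tG1\tG2")
  coll2 <- read_gene_sets(gmt2, write_fixture_tsv(standard_meta("PD")))
  expect_equal(sort(coll2$members$member_id), c("G1", "G2"))

  ## empty file: empty collection, nothing excluded
  coll3 <- read_gene_sets(write_fixture_lines(character(0)),
                          write_fixture_tsv(standard_meta(character(0))))
  expect_equal(n_pathways(coll3), 0)
  expect_equal(coll3$load_report$excluded_count, 0)
})

test_that("malformed GMT lines and missing sidecar entries fail loudly", {
  gmt <- write_fixture_lines(c("P1\tok\tG1\tG2", "justonefield"))
  meta <- write_fixture_tsv(standard_meta("P1"))
  expect_error(read_gene_sets(gmt, meta), "line 2",
               class = "pathmosaic_parse_error")

  gmt2 <- write_fixture_lines("P9\tdesc\tG1\tG2")
  expect_error(read_gene_sets(gmt2, meta), "P9",
               class = "pathmosaic_validation_error")

  ## a '*' sidecar row supplies defaults for uncovered pathways
  meta_default <- write_fixture_tsv(standard_meta(c("P1", "*")))
  coll <- read_gene_sets(gmt2, meta_default)
  expect_equal(coll$pathways$pathway_id, "SRCA:P9")
})

test_that("write/read round-trip preserves the pathway and member multiset", {
  coll <- make_collection(list("SRCA:P1" = c("G1", "G2", "G3"),
                               "SRCB:P2" = c("G3", "G4")),
                          source = c("SRCA", "SRCB"))
  gmt <- tempfile(fileext = ".gmt"); meta <- tempfile(fileext = ".tsv")
  write_gene_sets(coll, gmt, meta)
  back <- read_gene_sets(gmt, meta)
  expect_setequal(back$pathways$pathway_id, coll$pathways$pathway_id)
  key <- function(x) sort(paste(x$members$pathway_id, x$members$member_id,
                                x$members$member_kind))
  expect_equal(key(back), key(coll))
})

test_that("raising the core size threshold never increases the pathway count", {
  gmt <- write_fixture_lines(vapply(1:6, function(i) {
    paste(c(sprintf("P%d", i), "d", sprintf("G%d", seq_len(i))), collapse = "\t")
  }, character(1)))
  meta <- write_fixture_tsv(standard_meta(sprintf("P%d", 1:6)))
  counts <- vapply(1:7, function(th) n_pathways(read_gene_sets(gmt, meta, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts, c(6, 5, 4, 3, 2, 1, 0))
})

test_that("member index matches a rebuild from the membership table", {
  set.seed(11)
  for (rep in 1:5) {
    members <- lapply(setNames(1:6, sprintf("P%d", 1:6)), function(i) {
      sample(sprintf("G%02d", 1:30), sample(3:10, 1))
    })
    coll <- make_collection(members)
    idx <- member_index(coll)
    rebuilt <- split(coll$members$pathway_id, coll$members$member_id)
    expect_equal(idx[order(names(idx))], rebuilt[order(names(rebuilt))])
    for (g in names(idx)) {
      expect_setequal(idx[[g]],
                      coll$members$pathway_id[coll$members$member_id == g])
    }
  }
})

test_that("member kind is fixed per identifier across a collection", {
  pw <- make_collection(list(P1 = "G1", P2 = "G1"))$pathways
  mem <- tibble::tibble(pathway_id = c("P1", "P2"), member_id = "G1",
                        member_kind = c("gene", "metabolite"),
                        provenance = "curated")
  expect_error(pathway_collection(pw, mem), "conflicting kinds",
               class = "pathmosaic_validation_error")
})

test_that("identifier resolution follows namespace precedence and reports ambiguity", {
  idmap <- read_id_map(write_fixture_tsv(tibble::tibble(
    primary_id = c("P04637", "Q00001", "Q00002"),
    alternate_ids = c("7157", "11", "12"),
    symbol = c("TP53", "ALPHA", "BETA"),
    synonyms = c("p53|LFS1", "DUP", "DUP")
  )))

  empty <- map_identifiers(character(0), idmap)
  expect_equal(empty$mapped, character(0))
  expect_equal(empty$unmapped, character(0))
  expect_equal(empty$ambiguous, character(0))

  ## case-insensitive symbol match
  expect_equal(map_identifiers("tp53", idmap)$mapped, "P04637")
  ## exact alternate match
  expect_equal(map_identifiers("7157", idmap)$mapped, "P04637")
  ## synonym shared by two records is ambiguous, never assigned
  amb <- map_identifiers("DUP", idmap)
  expect_equal(amb$ambiguous, "DUP")
  expect_equal(amb$mapped, character(0))

  ## partition is exhaustive and disjoint; mapped keeps input order
  res <- map_identifiers(c("Q00002", "tp53", "nope", "DUP", "tp53"), idmap)
  expect_equal(res$mapped, c("Q00002", "P04637"))
  expect_equal(res$unmapped, "nope")
  expect_equal(res$ambiguous, "DUP")
  expect_equal(sort(c(res$table$input)),
               sort(unique(c("Q00002", "tp53", "nope", "DUP"))))
})

test_that("primary ids in an id map must be unique", {
  bad <- write_fixture_tsv(tibble::tibble(
    primary_id = c("A", "A"), alternate_ids = "", symbol = c("S1", "S2"),
    synonyms = ""))
  expect_error(read_id_map(bad), "unique",
               class = "pathmosaic_validation_error")
})

test_that("subset selection filters by type/source and restricts member kind", {
  coll <- make_collection(
    setNames(lapply(1:7, function(i) sprintf("G%d_%d", i, 1:3)), sprintf("P%d", 1:7)),
    pathway_type = c(rep("Metabolism", 3), rep("Disease", 4))
  )
  expect_equal(n_pathways(select_subset(coll, types = "Metabolism")), 3)
  ## identity selection
  ident <- select_subset(coll, sources = "SRCA",
                         types = c("Metabolism", "Disease"))
  expect_setequal(ident$pathways$pathway_id, coll$pathways$pathway_id)
  expect_error(select_subset(coll, sources = character(0)),
               class = "pathmosaic_config_error")
  expect_error(select_subset(coll, sources = "NOPE"),
               class = "pathmosaic_config_error")

  mixed <- pathway_collection(
    make_collection(list(PM = c("G1", "ATP")))$pathways,
    tibble::tibble(pathway_id = "PM", member_id = c("G1", "ATP"),
                   member_kind = c("gene", "metabolite"), provenance = "curated")
  )
  genes_only <- select_subset(mixed, member_kind = "gene")
  expect_equal(genes_only$members$member_id, "G1")
  ## a pathway emptied by the member-kind restriction disappears
  gene_pw <- make_collection(list(PG = c("G1", "G2")))
  expect_equal(n_pathways(select_subset(gene_pw, member_kind = "metabolite")), 0)
})
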