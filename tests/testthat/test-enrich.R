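test_that("the background is the union of selected pathway members", {
  coll <- make_collection(list(P1 = c("A", "B", "C"), P2 = c("C", "D")))
  bg <- build_background(coll)
  expect_setequal(bg$background, c("A", "B", "C", "D"))
  one <- build_background(coll, enrichment_options(types = NULL))
  expect_equal(length(one$background), 4)
  single <- select_subset(coll, set_kinds = "core")
  expect_setequal(build_background(make_collection(list(P1 = c("A", "B"))))$background,
                  c("A", "B"))
  expect_error(enrichment_options(sources = character(0)),
               class = "pathmosaic_config_error")
})

test_that("enrichment rows match the enumeration oracle and hand Bonferroni", {
  coll <- enrich_fixture()
  g <- sprintf("G%02d", 1:30)
  query <- c(g[1:7], g[21:23])   # 7 of pathway P's 8 members, 10 in background
  res <- run_enrichment(query, coll, enrichment_options(sources = "SRCA"))
  expect_equal(nrow(res), 2)
  rowP <- res[res$pathway_id == "P", ]
  expect_equal(rowP$N_S, 30)
  expect_equal(rowP$N_U, 10)
  expect_equal(rowP$N_Pw, 8)
  expect_equal(rowP$N_u, 7)
  ## exact-integer oracle for Pr(overlap >= 7 | N_S=30, N_Pw=8, N_U=10)
  C <- pascal_binom(30)
  expect_equal(rowP$p, exact_tail(7, 30, 8, 10, C), tolerance = 1e-10)
  expect_equal(rowP$q_bonferroni, min(1, rowP$p * 2))
  expect_equal(rowP$ratio, 7 / 8)
  expect_setequal(rowP$overlap_members[[1]], g[1:7])
  ## sorted ascending by p
  expect_true(!is.unsorted(res$p))
})

test_that("per-source q-values never exceed combined q-values on a shared background", {
  coll <- enrich_fixture()
  g <- sprintf("G%02d", 1:30)
  query <- c(g[1:7], g[21:23])
  combined <- run_enrichment(query, coll, enrichment_options(mode = "combined"))
  per <- run_enrichment(query, coll, enrichment_options(mode = "per_source"))
  expect_equal(sum(attr(per, "family_sizes")), attr(combined, "family_sizes")[["combined"]])
  joined <- dplyr::inner_join(
    tibble::as_tibble(combined)[, c("pathway_id", "p", "q_bh", "q_bonferroni")],
    tibble::as_tibble(per)[, c("pathway_id", "p", "q_bh", "q_bonferroni")],
    by = "pathway_id", suffix = c("_comb", "_per"))
  expect_equal(joined$p_per, joined$p_comb, tolerance = 1e-12)
  expect_true(all(joined$q_bh_per <= joined$q_bh_comb + 1e-12))
  expect_true(all(joined$q_bonferroni_per <= joined$q_bonferroni_comb + 1e-12))
})

test_that("a query disjoint from the background gives p = 1 everywhere and filters empty", {
  coll <- enrich_fixture()
  res <- run_enrichment(c("X1", "X2"), coll, enrichment_options())
  expect_true(all(res$p == 1))
  expect_equal(attr(res, "coverage")$absent_from_background, c("X1", "X2"))
  filtered <- run_enrichment(c("X1", "X2"), coll,
                             enrichment_options(filter_threshold = 0.05))
  expect_equal(nrow(filtered), 0)
})

test_that("adjusted-p filter tiers and the filter column behave as configured", {
  coll <- enrich_fixture()
  g <- sprintf("G%02d", 1:30)
  query <- c(g[1:7], g[21:23])
  all_rows <- run_enrichment(query, coll, enrichment_options())
  expect_equal(nrow(all_rows), 4)   # threshold "none" returns every tested pathway
  strict <- run_enrichment(query, coll,
                           enrichment_options(filter_threshold = 0.01))
  expect_true(all(strict$q_bh < 0.01))
  bonf <- run_enrichment(query, coll,
                         enrichment_options(filter_threshold = 0.05,
                                            filter_column = "q_bonferroni"))
  expect_true(all(bonf$q_bonferroni < 0.05))
  expect_error(enrichment_options(filter_threshold = 0.2),
               class = "pathmosaic_config_error")
})

test_that("q-value ordering invariants hold on random queries", {
  set.seed(41)
  coll <- enrich_fixture()
  g <- sprintf("G%02d", 1:30)
  for (rep in 1:10) {
    res <- run_enrichment(sample(g, 8), coll, enrichment_options())
    expect_true(all(res$q_bonferroni >= res$q_bh - 1e-12))
    expect_true(all(res$q_bh >= res$p - 1e-12))
    expect_true(all(res$q_bonferroni <= 1))
    expect_true(all(res$ratio == res$N_u / res$N_Pw))
  }
})

test_that("coverage report accounts for query ids outside the background", {
  coll <- enrich_fixture()
  res <- run_enrichment(c("G01", "G02", "NOPE"), coll, enrichment_options())
  expect_equal(res$N_U[1], 2)
  expect_equal(attr(res, "coverage")$absent_from_background, "NOPE")
  cov <- attr(res, "coverage")$by_source_set
  expect_true(all(c("source", "set", "n_annotated") %in% names(cov)))
})

test_that("metabolite mode tests metabolite membership only", {
  pw <- make_collection(list(PM = c("g1", "g2"), PX = c("g1", "g3")))$pathways
  mem <- tibble::tibble(
    pathway_id = c("PM", "PM", "PM", "PX", "PX"),
    member_id = c("g1", "ATP", "NAD", "g1", "g3"),
    member_kind = c("gene", "metabolite", "metabolite", "gene", "gene"),
    provenance = "curated")
  coll <- pathway_collection(pw, mem)
  res <- run_enrichment(c("ATP", "g1"), coll,
                        enrichment_options(member_kind = "metabolite"))
  expect_equal(res$pathway_id, "PM")
  expect_equal(res$N_S, 2)       # metabolite background is {ATP, NAD}
  expect_equal(res$N_u, 1)
})

test_that("miRNA enrichment combines target sets by intersection or union", {
  coll <- enrich_fixture()
  g <- sprintf("G%02d", 1:30)
  targets <- tibble::tibble(
    mirna = c(rep("miR-X", 3), rep("miR-Y", 3)),
    target = c(g[1], g[2], g[3], g[2], g[3], g[4]))

  ## single miRNA behaves exactly like run_enrichment on its targets
  one <- mirna_enrichment("miR-X", targets, coll, enrichment_options())
  direct <- run_enrichment(g[1:3], coll, enrichment_options())
  expect_equal(tidy(one), tidy(direct), ignore_attr = TRUE)

  ## targeted-by-all (intersection) is the default
  both <- mirna_enrichment(c("miR-X", "miR-Y"), targets, coll,
                           enrichment_options())
  expect_equal(attr(both, "mirna_report")$query_size, 2)   # {G02, G03}
  expect_equal(both$N_U[1], 2)

  uni <- mirna_enrichment(c("miR-X", "miR-Y"), targets, coll,
                          enrichment_options(mirna_mode = "union"))
  expect_equal(attr(uni, "mirna_report")$query_size, 4)

  ## unknown miRNA only: empty result, reported
  none <- mirna_enrichment("miR-Z", targets, coll, enrichment_options())
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "mirna_report")$missing, "miR-Z")
})
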