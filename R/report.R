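#' Top pathways per source (chart-ready table)
#'
#' Selects, per source, the `k` most enriched rows (smallest `p`, ties by
#' larger `N_u` then name) — the table behind a per-source top-pathways
#' bar chart.
#'
#' @param rows Enrichment rows carrying `source`, `p`, `N_u`, `name`, `q_bh`.
#' @param k Rows kept per source (default 7).
#' @return Tibble sorted by source then rank.
#' @export
top_pathways_per_source <- function(rows, k = 7) {
  rows <- tibble::as_tibble(rows)
  if (!nrow(rows)) return(rows)
  rows |>
    dplyr::arrange(.data$p, dplyr::desc(.data$N_u), .data$name) |>
    dplyr::mutate(rank = dplyr::row_number(), .by = "source") |>
    dplyr::filter(.data$rank <= k) |>
    dplyr::arrange(.data$source, .data$rank)
}

#' Gene-by-pathway membership matrix
#'
#' Binary matrix of query genes against retained pathways, the table behind
#' a heatmap-style overlap chart. Every query gene keeps a row even when it
#' overlaps no pathway (an all-zero row makes an unannotated gene visible).
#' Rows follow query order; pathway columns follow the enrichment order
#' (increasing `p`); each pathway's source is attached as the
#' `pathway_sources` attribute.
#'
#' @param rows Enrichment rows with list-column `overlap_members`.
#' @param query Character vector of query genes.
#' @return Tibble with a `gene` column plus one 0/1 column per pathway.
#' @export
gene_pathway_matrix <- function(rows, query) {
  rows <- tibble::as_tibble(rows)
  query <- unique(as.character(query))
  out <- tibble::tibble(gene = query)
  for (i in seq_len(nrow(rows))) {
    out[[rows$pathway_id[i]]] <- as.integer(query %in% rows$overlap_members[[i]])
  }
  attr(out, "pathway_sources") <- setNames(rows$source, rows$pathway_id)
  out
}

#' Query coverage per source and set
#'
#' Counts, for every (source, set) cell, how many distinct query genes carry
#' an annotation there, where the set is the membership provenance:
#' literature-curated or network-predicted. A gene curated in one source and
#' predicted in another counts in both cells. The global annotated/orphan
#' split — query genes with no annotation anywhere in the collection — is
#' attached as the `global` attribute; this is the table behind per-source
#' coverage pie charts.
#'
#' @param query Character vector of query identifiers.
#' @param collection A `pathway_collection`.
#' @return Tibble with columns `source`, `set`, `n_annotated` (complete over
#'   all source/set combinations present in the collection). Empty query
#'   gives an empty table.
#' @export
coverage_summary <- function(query, collection) {
  query <- unique(as.character(query))
  empty <- tibble::tibble(source = character(0), set = character(0),
                          n_annotated = integer(0))
  if (!length(query)) {
    attr(empty, "global") <- list(n_query = 0L, n_annotated = 0L,
                                  n_orphan = 0L, orphan_ids = character(0))
    return(empty)
  }
  mem <- dplyr::inner_join(collection$members,
                           collection$pathways[, c("pathway_id", "source")],
                           by = "pathway_id")
  cells <- dplyr::distinct(mem, .data$source, set = .data$provenance)
  hits <- mem[mem$member_id %in% query, ]
  counts <- hits |>
    dplyr::distinct(.data$source, set = .data$provenance, .data$member_id) |>
    dplyr::count(.data$source, .data$set, name = "n_annotated")
  out <- dplyr::left_join(cells, counts, by = c("source", "set")) |>
    dplyr::mutate(n_annotated = dplyr::coalesce(.data$n_annotated, 0L)) |>
    dplyr::arrange(.data$source, .data$set)
  annotated <- intersect(query, mem$member_id)
  attr(out, "global") <- list(
    n_query = length(query),
    n_annotated = length(annotated),
    n_orphan = length(query) - length(annotated),
    orphan_ids = setdiff(query, annotated)
  )
  out
}

#' Plot query coverage per source and set
#'
#' @param coverage Output of [coverage_summary()].
#' @return A ggplot bar chart.
#' @export
plot_coverage_summary <- function(coverage) {
  ggplot2::ggplot(coverage, ggplot2::aes(x = .data$source, y = .data$n_annotated,
                                         fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Query genes annotated", fill = "Set",
                  title = "Query coverage by source and set") +
    ggplot2::theme_minimal()
}

#' Plot the gene-by-pathway membership matrix as a heatmap
#'
#' @param matrix_tbl Output of [gene_pathway_matrix()].
#' @return A ggplot tile chart, colour-coded by pathway source.
#' @export
plot_gene_pathway_matrix <- function(matrix_tbl) {
  sources <- attr(matrix_tbl, "pathway_sources")
  long <- tidyr::pivot_longer(matrix_tbl, -"gene", names_to = "pathway_id",
                              values_to = "member")
  long$source <- unname(sources[long$pathway_id])
  long$pathway_id <- factor(long$pathway_id, levels = names(sources))
  long$gene <- factor(long$gene, levels = rev(matrix_tbl$gene))
  ggplot2::ggplot(long[long$member == 1, ],
                  ggplot2::aes(x = .data$pathway_id, y = .data$gene,
                               fill = .data$source)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Source",
                  title = "Gene/pathway membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
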