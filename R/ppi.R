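#' Construct a protein-protein interaction network
#'
#' Builds the undirected, evidence-labelled interaction network used for
#' connectivity-based pathway extension. Self-loops are dropped (with a
#' count), reversed duplicates of the same unordered pair are merged, and a
#' pair reported with conflicting evidence is kept as `experimental` —
#' experimental detection subsumes a computational prediction of the same
#' physical contact.
#'
#' @param edges Tibble/data frame with columns `protein_a`, `protein_b`,
#'   `evidence` (each `"experimental"` or `"predicted"`).
#' @param species Species code (e.g. `"Hs"`).
#' @return Object of class `ppi_network` with elements `species`, `edges`
#'   (canonicalised tibble), `graph` (igraph), and `n_self_loops`.
#' @export
ppi_network <- function(edges, species) {
  if (!species %in% SPECIES_CODES) abort_validation(paste0("unknown species code: ", species))
  edges <- tibble::as_tibble(edges)
  need <- c("protein_a", "protein_b", "evidence")
  if (!all(need %in% names(edges))) {
    abort_validation(paste0("edge table missing columns: ",
                            paste(setdiff(need, names(edges)), collapse = ", ")))
  }
  bad <- setdiff(unique(edges$evidence), EVIDENCE_CLASSES)
  if (length(bad)) {
    abort_validation(paste0("unknown evidence label(s): ", paste(bad, collapse = ", ")))
  }
  loops <- edges$protein_a == edges$protein_b
  n_loops <- sum(loops)
  if (n_loops) {
    warn(sprintf("dropped %d self-loop(s)", n_loops))
    edges <- edges[!loops, ]
  }
  if (nrow(edges)) {
    edges <- edges |>
      dplyr::mutate(a = pmin(.data$protein_a, .data$protein_b),
                    b = pmax(.data$protein_a, .data$protein_b)) |>
      dplyr::summarise(
        evidence = if (any(.data$evidence == "experimental")) "experimental" else "predicted",
        .by = c("a", "b")
      ) |>
      dplyr::rename(protein_a = "a", protein_b = "b") |>
      dplyr::arrange(.data$protein_a, .data$protein_b)
  } else {
    edges <- tibble::tibble(protein_a = character(0), protein_b = character(0),
                            evidence = character(0))
  }
  graph <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE
  )
  structure(list(species = species, edges = edges, graph = graph,
                 n_self_loops = n_loops),
            class = "ppi_network")
}

#' Read a PPI network from an edge-list TSV
#'
#' @param path TSV with header `protein_a, protein_b, evidence`.
#' @param species Species code.
#' @return A `ppi_network`; see [ppi_network()] for the merge rules applied.
#' @export
read_ppi_network <- function(path, species) {
  edges <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  ppi_network(edges, species)
}

#' Restrict a network to an evidence class
#'
#' `"experimental_only"` keeps experimentally detected edges;
#' `"full"` is the identity. Proteins left without any retained edge are
#' removed from the node set, so the network size `N` used by the prediction
#' test always counts proteins incident to at least one retained interaction.
#'
#' @param network A `ppi_network`.
#' @param which `"full"` or `"experimental_only"`.
#' @return A `ppi_network`.
#' @export
evidence_subset <- function(network, which = c("full", "experimental_only")) {
  which <- match.arg(which)
  if (which == "full") return(network)
  ppi_network(network$edges[network$edges$evidence == "experimental", ],
              network$species)
}

#' Proteins in a network
#' @param network A `ppi_network`.
#' @return Character vector of protein ids with at least one edge.
#' @export
ppi_proteins <- function(network) {
  as.character(igraph::V(network$graph)$name)
}

#' Network size N (proteins with at least one edge)
#' @param network A `ppi_network`.
#' @return Integer.
#' @export
ppi_size <- function(network) igraph::vcount(network$graph)

#' Interaction partners of a protein
#' @param network A `ppi_network`.
#' @param protein Protein id; must be present in the network.
#' @return Character vector of neighbours.
#' @export
ppi_neighbors <- function(network, protein) {
  if (!protein %in% ppi_proteins(network)) {
    abort_lookup(paste0("protein not in network: ", protein))
  }
  as.character(igraph::neighbors(network$graph, protein)$name)
}

#' Degrees of network proteins
#' @param network A `ppi_network`.
#' @param proteins Optional subset of proteins (default all).
#' @return Named integer vector of degrees.
#' @export
ppi_degree <- function(network, proteins = NULL) {
  d <- igraph::degree(network$graph)
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, names(d))
    if (length(missing)) abort_lookup(paste0("protein not in network: ",
                                             paste(missing, collapse = ", ")))
    d <- d[proteins]
  }
  d
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> species %s: %d proteins, %d edges (%d experimental, %d predicted)\n",
              x$species, ppi_size(x), nrow(x$edges),
              sum(x$edges$evidence == "experimental"),
              sum(x$edges$evidence == "predicted")))
  invisible(x)
}

#' @export
tidy.ppi_network <- function(x, ...) x$edges
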