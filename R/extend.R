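#' Predict protein-pathway associations from network connectivity
#'
#' Guilt-by-association annotation: a protein is predicted to belong to a
#' pathway when a significantly large share of its interaction partners are
#' curated members of that pathway. For each protein the candidate family is
#' every pathway containing at least one partner and not already containing
#' the protein; the raw probability is the upper-tail hypergeometric
#' [hypergeom_tail()] on (`k = m`, `N`, `M`, `n`) where `N` is the network
#' size, `M` the network proteins in the pathway, `n` the partner count and
#' `m` the partners inside the pathway. Probabilities are
#' Benjamini-Hochberg-adjusted within each protein's candidate family
#' (`scope = "global"` adjusts across all tests instead) and predictions with
#' adjusted probability strictly below `alpha` are retained.
#'
#' @param network A `ppi_network` (apply [evidence_subset()] first to choose
#'   the evidence class).
#' @param collection The curated `pathway_collection` supplying memberships.
#' @param proteins Proteins to test; default all network proteins. A protein
#'   absent from the network is an error.
#' @param alpha Retention threshold on the adjusted probability (default
#'   0.01, strict inequality).
#' @param scope Multiple-testing family: `"per_protein"` (default) or
#'   `"global"`.
#' @param keep_all Return non-retained candidates too (with a `retained`
#'   column) instead of retained rows only.
#' @return Tibble of class `membership_predictions` with columns `protein`,
#'   `pathway_id`, `source`, `p_raw`, `p_adjusted`, `N`, `M`, `n`, `m`
#'   (plus `retained` when `keep_all = TRUE`).
#' @export
predict_pathway_membership <- function(network, collection, proteins = NULL,
                                       alpha = 0.01,
                                       scope = c("per_protein", "global"),
                                       keep_all = FALSE) {
  scope <- match.arg(scope)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort_domain("alpha must be a probability")
  }
  nodes <- ppi_proteins(network)
  if (is.null(proteins)) {
    proteins <- nodes
  } else {
    missing <- setdiff(proteins, nodes)
    if (length(missing)) {
      abort_lookup(paste0("protein(s) not in network: ",
                          paste(missing, collapse = ", ")))
    }
  }
  N <- length(nodes)
  ## M and partner lookups use only members that are network proteins;
  ## full membership (network or not) governs candidate exclusion.
  mem_net <- collection$members[collection$members$member_id %in% nodes, ]
  M_tab <- dplyr::count(mem_net, .data$pathway_id, name = "M")
  M_of <- setNames(M_tab$M, M_tab$pathway_id)
  pw_members_net <- split(mem_net$member_id, mem_net$pathway_id)
  member_pathways <- split(mem_net$pathway_id, mem_net$member_id)
  full_membership <- split(collection$members$pathway_id, collection$members$member_id)

  rows <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    prot <- proteins[i]
    partners <- ppi_neighbors(network, prot)
    n <- length(partners)
    cand <- unique(unlist(member_pathways[partners], use.names = FALSE))
    cand <- setdiff(cand, full_membership[[prot]])
    if (!length(cand)) next
    m <- vapply(cand, function(pw) sum(partners %in% pw_members_net[[pw]]),
                integer(1))
    p <- hypergeom_tail(m, N, M_of[cand], n)
    rows[[i]] <- tibble::tibble(protein = prot, pathway_id = cand,
                                p_raw = p, N = N, M = unname(M_of[cand]),
                                n = n, m = unname(m))
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(protein = character(0), pathway_id = character(0),
                          p_raw = numeric(0), N = integer(0), M = integer(0),
                          n = integer(0), m = integer(0))
  }
  out <- if (scope == "per_protein") {
    dplyr::mutate(out, p_adjusted = bh_adjust(.data$p_raw), .by = "protein")
  } else {
    dplyr::mutate(out, p_adjusted = bh_adjust(.data$p_raw))
  }
  out$retained <- out$p_adjusted < alpha
  out <- dplyr::left_join(out,
                          collection$pathways[, c("pathway_id", "source")],
                          by = "pathway_id") |>
    dplyr::select("protein", "pathway_id", "source", "p_raw", "p_adjusted",
                  "N", "M", "n", "m", "retained") |>
    dplyr::arrange(.data$protein, .data$p_adjusted, .data$p_raw, .data$pathway_id)
  if (!keep_all) {
    out <- out[out$retained, setdiff(names(out), "retained")]
  }
  structure(out, alpha = alpha, scope = scope,
            class = c("membership_predictions", class(out)))
}

#' @export
tidy.membership_predictions <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "membership_predictions")
  out
}

#' @export
glance.membership_predictions <- function(x, ...) {
  tibble::tibble(
    n_predictions = if ("retained" %in% names(x)) sum(x$retained) else nrow(x),
    n_proteins = length(unique(x$protein)),
    n_pathways = length(unique(x$pathway_id)),
    alpha = attr(x, "alpha"),
    scope = attr(x, "scope")
  )
}

#' Extend a pathway collection with network-predicted members
#'
#' Runs [predict_pathway_membership()] for every protein in the chosen
#' evidence subset of the network and adds retained predictions as new
#' `provenance = "predicted"` members. Curated membership is never removed,
#' so each core pathway is a subset of its extended counterpart. The
#' resulting collection's `set_kind` records which evidence class fed the
#' prediction, and the full prediction table is attached as `$predictions`.
#'
#' @param core Curated `pathway_collection`.
#' @param network A `ppi_network` of the same species.
#' @param evidence `"experimental_only"` or `"full"`.
#' @param alpha Retention threshold on the adjusted probability.
#' @param scope Multiple-testing family, as in [predict_pathway_membership()].
#' @return A `pathway_collection` with `set_kind` `"extended_experimental"`
#'   or `"extended_full"` and a `$predictions` provenance table.
#' @export
extend_pathways <- function(core, network, evidence = c("experimental_only", "full"),
                            alpha = 0.01, scope = "per_protein") {
  evidence <- match.arg(evidence)
  if (!is.na(core$species) && core$species != network$species) {
    abort_validation(sprintf("species mismatch: collection is %s, network is %s",
                             core$species, network$species))
  }
  net <- evidence_subset(network,
                         which = if (evidence == "experimental_only") "experimental_only" else "full")
  preds <- predict_pathway_membership(net, core, alpha = alpha, scope = scope)
  kind <- if (evidence == "experimental_only") "extended_experimental" else "extended_full"
  new_members <- tibble::tibble(
    pathway_id = preds$pathway_id,
    member_id = preds$protein,
    member_kind = "gene",
    provenance = "predicted"
  )
  pw <- dplyr::mutate(core$pathways, set_kind = kind)
  out <- pathway_collection(pw, dplyr::bind_rows(core$members, new_members),
                            load_report = core$load_report)
  out$predictions <- preds
  out
}

#' Write a prediction table as TSV
#'
#' @param predictions A `membership_predictions` tibble.
#' @param path Output path.
#' @param evidence_set Label recorded in the `evidence_set` column.
#' @return Invisibly, the predictions.
#' @export
write_predictions <- function(predictions, path, evidence_set = "full") {
  out <- tidy(predictions)
  out$p_raw <- format_num(out$p_raw)
  out$p_adjusted <- format_num(out$p_adjusted)
  out$evidence_set <- evidence_set
  readr::write_tsv(out, path, progress = FALSE)
  invisible(predictions)
}
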