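#' Read a one-to-one ortholog table
#'
#' Within each ordered species pair the mapping must be one-to-one: any
#' `id_from` or `id_to` appearing more than once invalidates every record it
#' touches. Violating records are rejected (not loaded) and listed in the
#' rejection report attached to the result.
#'
#' @param path TSV with header `species_from, id_from, species_to, id_to`.
#' @return Tibble of class `ortholog_map` with attribute `rejected` (tibble
#'   of dropped records with a `reason` column).
#' @export
read_ortholog_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("species_from", "id_from", "species_to", "id_to")
  if (!all(need %in% names(raw))) {
    abort_validation(paste0("ortholog table missing columns: ",
                            paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  raw <- dplyr::distinct(raw)
  raw <- raw |>
    dplyr::mutate(
      dup_from = duplicated(.data$id_from) | duplicated(.data$id_from, fromLast = TRUE),
      dup_to = duplicated(.data$id_to) | duplicated(.data$id_to, fromLast = TRUE),
      .by = c("species_from", "species_to")
    )
  bad <- raw$dup_from | raw$dup_to
  rejected <- raw[bad, need]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(raw$dup_from[bad], "one_to_many", "many_to_one")
  } else {
    rejected$reason <- character(0)
  }
  out <- raw[!bad, need]
  structure(out, rejected = rejected,
            class = c("ortholog_map", class(out)))
}

#' Project pathways onto another species through one-to-one orthologs
#'
#' Each pathway's gene members are replaced by their orthologs in the target
#' species; members without a one-to-one ortholog are dropped, as are
#' metabolite members (orthology is a gene-level relation). Pathways left
#' with fewer than `min_members` orthologs are removed — a single gene or a
#' single interacting pair does not constitute a pathway, hence the default
#' of 3, which is intentionally stricter than the size-2 floor applied to
#' curated pathways.
#'
#' @param core Source-species `pathway_collection`.
#' @param map An `ortholog_map` from [read_ortholog_map()].
#' @param target_species Species code to project onto.
#' @param min_members Minimum surviving ortholog members (default 3).
#' @return A `pathway_collection` with `set_kind = "ortholog"` and
#'   `species = target_species`; its load report counts dropped pathways.
#' @export
project_pathways <- function(core, map, target_species, min_members = 3) {
  if (!inherits(map, "ortholog_map")) abort_validation("map must come from read_ortholog_map()")
  if (!target_species %in% SPECIES_CODES) {
    abort_config(paste0("unknown target species: ", target_species))
  }
  if (nrow(map) && !target_species %in% map$species_to) {
    abort_config(paste0("target species absent from ortholog map: ", target_species))
  }
  pair <- map[map$species_from == core$species & map$species_to == target_species, ]
  lookup <- setNames(pair$id_to, pair$id_from)
  genes <- core$members[core$members$member_kind == "gene", ]
  genes$ortholog <- unname(lookup[genes$member_id])
  genes <- genes[!is.na(genes$ortholog), ]
  surviving <- dplyr::count(genes, .data$pathway_id)
  keep_ids <- surviving$pathway_id[surviving$n >= min_members]
  dropped <- setdiff(core$pathways$pathway_id, keep_ids)
  members <- genes[genes$pathway_id %in% keep_ids, ] |>
    dplyr::transmute(pathway_id = .data$pathway_id, member_id = .data$ortholog,
                     member_kind = "gene", provenance = .data$provenance)
  pathways <- core$pathways[core$pathways$pathway_id %in% keep_ids, ] |>
    dplyr::mutate(species = target_species, set_kind = "ortholog")
  pathway_collection(pathways, members,
                     load_report = list(excluded_count = length(dropped),
                                        excluded_ids = dropped,
                                        min_core_members = min_members,
                                        n_loaded = nrow(pathways)))
}
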