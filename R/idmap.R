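#' Read an identifier mapping table
#'
#' The map records, per primary identifier, its alternate identifiers in other
#' namespaces, a display symbol, and free-form synonyms. Primary ids must be
#' unique; the map refuses to load otherwise.
#'
#' @param path TSV with header `primary_id, alternate_ids, symbol, synonyms`;
#'   `alternate_ids` and `synonyms` are `|`-separated.
#' @return A tibble of class `id_map` with list-columns `alternate_ids` and
#'   `synonyms`.
#' @export
read_id_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("primary_id", "alternate_ids", "symbol", "synonyms")
  if (!all(need %in% names(raw))) {
    abort_validation(paste0("id map missing columns: ",
                            paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  if (anyDuplicated(raw$primary_id)) {
    abort_validation("id map primary_id values must be unique")
  }
  out <- tibble::tibble(
    primary_id = raw$primary_id,
    alternate_ids = split_bar(raw$alternate_ids),
    symbol = dplyr::coalesce(raw$symbol, ""),
    synonyms = split_bar(raw$synonyms)
  )
  class(out) <- c("id_map", class(out))
  out
}

#' Resolve raw identifiers to primary identifiers
#'
#' Resolution walks a fixed namespace precedence: exact primary id, then exact
#' alternate id, then case-insensitive symbol, then case-insensitive synonym.
#' An alias matching more than one record *at its winning tier* is reported as
#' ambiguous, never silently assigned. The three output groups partition the
#' (deduplicated) input.
#'
#' @param raw_ids Character vector of query identifiers.
#' @param idmap An `id_map` from [read_id_map()].
#' @return A list with `mapped` (primary ids, input order, duplicates
#'   collapsed), `unmapped`, `ambiguous`, and `table` — a tibble with one row
#'   per distinct input id (`input`, `status`, `primary_id`).
#' @export
map_identifiers <- function(raw_ids, idmap) {
  if (!inherits(idmap, "id_map")) abort_validation("idmap must come from read_id_map()")
  ids <- unique(as.character(raw_ids))
  if (!length(ids)) {
    return(list(mapped = character(0), unmapped = character(0),
                ambiguous = character(0),
                table = tibble::tibble(input = character(0), status = character(0),
                                       primary_id = character(0))))
  }
  sym_lc <- tolower(idmap$symbol)
  syn_lc <- lapply(idmap$synonyms, tolower)
  resolve_one <- function(id) {
    hits <- which(idmap$primary_id == id)
    if (!length(hits)) hits <- which(vapply(idmap$alternate_ids, function(a) id %in% a, logical(1)))
    if (!length(hits)) hits <- which(sym_lc == tolower(id) & nzchar(sym_lc))
    if (!length(hits)) hits <- which(vapply(syn_lc, function(s) tolower(id) %in% s, logical(1)))
    if (length(hits) == 0) return(c("unmapped", NA_character_))
    if (length(hits) > 1) return(c("ambiguous", NA_character_))
    c("mapped", idmap$primary_id[hits])
  }
  res <- vapply(ids, resolve_one, character(2))
  table <- tibble::tibble(input = ids, status = res[1, ], primary_id = res[2, ])
  list(
    mapped = unique(table$primary_id[table$status == "mapped"]),
    unmapped = table$input[table$status == "unmapped"],
    ambiguous = table$input[table$status == "ambiguous"],
    table = table
  )
}
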