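#' Construct a pathway collection
#'
#' A pathway collection is the canonical container consumed by every analysis
#' function in pathmosaic. It pairs a pathway-level tibble with a long (tidy)
#' membership tibble, so pathway metadata and membership can each be
#' manipulated with ordinary dplyr verbs.
#'
#' @param pathways Tibble with columns `pathway_id`, `name`, `description`,
#'   `source`, `species`, `set_kind`, `pathway_type`, `category`.
#' @param members Tibble with columns `pathway_id`, `member_id`,
#'   `member_kind` (`"gene"` or `"metabolite"`) and `provenance`
#'   (`"curated"` or `"predicted"`).
#' @param load_report Optional list describing filtering applied at load time.
#'
#' @return An object of class `pathway_collection`: a list with elements
#'   `pathways` and `members` (both tibbles) plus a `species` string.
#' @export
pathway_collection <- function(pathways, members, load_report = NULL) {
  pathways <- tibble::as_tibble(pathways)
  members <- tibble::as_tibble(members)
  obj <- structure(
    list(
      pathways = pathways,
      members = members,
      species = if (nrow(pathways)) unique(pathways$species)[1] else NA_character_,
      load_report = load_report
    ),
    class = "pathway_collection"
  )
  validate_pathway_collection(obj)
}

validate_pathway_collection <- function(x) {
  pw_cols <- c("pathway_id", "name", "description", "source", "species",
               "set_kind", "pathway_type", "category")
  mem_cols <- c("pathway_id", "member_id", "member_kind", "provenance")
  if (!all(pw_cols %in% names(x$pathways))) {
    abort_validation(paste0("pathway table missing columns: ",
                            paste(setdiff(pw_cols, names(x$pathways)), collapse = ", ")))
  }
  if (!all(mem_cols %in% names(x$members))) {
    abort_validation(paste0("member table missing columns: ",
                            paste(setdiff(mem_cols, names(x$members)), collapse = ", ")))
  }
  if (anyDuplicated(x$pathways$pathway_id)) {
    abort_validation("duplicate pathway_id in collection")
  }
  if (nrow(x$pathways) && length(unique(x$pathways$species)) > 1) {
    abort_validation("all pathways in a collection must share one species")
  }
  if (nrow(x$pathways) && !all(x$pathways$species %in% SPECIES_CODES)) {
    abort_validation(paste0("unknown species code: ",
                            paste(setdiff(x$pathways$species, SPECIES_CODES), collapse = ", ")))
  }
  if (!all(x$pathways$set_kind %in% SET_KINDS)) {
    abort_validation("set_kind must be one of core, ortholog, extended_experimental, extended_full")
  }
  if (nrow(x$members)) {
    if (!all(x$members$member_kind %in% MEMBER_KINDS)) {
      abort_validation("member_kind must be gene or metabolite")
    }
    if (!all(nzchar(x$members$member_id))) {
      abort_validation("empty member_id in collection")
    }
    if (anyDuplicated(x$members[, c("pathway_id", "member_id")])) {
      abort_validation("duplicate member within a pathway")
    }
    ## a member's kind is fixed across the whole collection
    kinds <- dplyr::distinct(x$members, .data$member_id, .data$member_kind)
    if (anyDuplicated(kinds$member_id)) {
      bad <- kinds$member_id[duplicated(kinds$member_id)]
      abort_validation(paste0("member declared with conflicting kinds: ",
                              paste(unique(bad), collapse = ", ")))
    }
    orphan_rows <- setdiff(x$members$pathway_id, x$pathways$pathway_id)
    if (length(orphan_rows)) {
      abort_validation("membership rows reference unknown pathway_id")
    }
  }
  empty <- setdiff(x$pathways$pathway_id, x$members$pathway_id)
  if (length(empty)) {
    abort_validation(paste0("pathways with no members after filtering: ",
                            paste(head(empty, 5), collapse = ", ")))
  }
  x
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d membership records, species %s\n",
              nrow(x$pathways), nrow(x$members), x$species))
  if (nrow(x$pathways)) {
    cat("  sources:  ", paste(sort(unique(x$pathways$source)), collapse = ", "), "\n")
    cat("  set kinds:", paste(sort(unique(x$pathways$set_kind)), collapse = ", "), "\n")
  }
  if (!is.null(x$load_report)) {
    cat(sprintf("  load report: %d pathway(s) excluded below the size threshold\n",
                x$load_report$excluded_count))
  }
  invisible(x)
}

#' @export
tidy.pathway_collection <- function(x, ...) {
  sizes <- dplyr::count(x$members, .data$pathway_id, name = "n_members")
  dplyr::left_join(x$pathways, sizes, by = "pathway_id") |>
    dplyr::mutate(n_members = dplyr::coalesce(.data$n_members, 0L))
}

#' @export
glance.pathway_collection <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$pathways),
    n_members = length(unique(x$members$member_id)),
    n_sources = length(unique(x$pathways$source)),
    species = x$species
  )
}

#' Number of pathways in a collection
#' @param collection A `pathway_collection`.
#' @return Integer count.
#' @export
n_pathways <- function(collection) nrow(collection$pathways)

#' Member-to-pathway index
#'
#' Rebuilds the inverted index from the membership table. The index is always
#' derived, so it can never drift out of sync with the pathways it summarises.
#'
#' @param collection A `pathway_collection`.
#' @return A named list mapping each member id to the character vector of
#'   pathway ids containing it.
#' @export
member_index <- function(collection) {
  if (!nrow(collection$members)) return(structure(list(), names = character(0)))
  split(collection$members$pathway_id, collection$members$member_id)
}

## -- GMT + sidecar I/O -------------------------------------------------------

parse_member_kinds <- function(spec, member_ids) {
  if (is.na(spec) || !nzchar(spec) || identical(spec, "gene")) {
    return(rep("gene", length(member_ids)))
  }
  if (identical(spec, "metabolite")) {
    return(rep("metabolite", length(member_ids)))
  }
  pairs <- split_bar(spec)[[1]]
  kinds <- rep("gene", length(member_ids))
  for (p in pairs) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !kv[2] %in% MEMBER_KINDS) {
      abort_validation(paste0("malformed member_kinds entry: '", p, "'"))
    }
    kinds[member_ids == kv[1]] <- kv[2]
  }
  kinds
}

#' Read pathway gene sets from a GMT file with a metadata sidecar
#'
#' Reads the standard GMT format (`id TAB description TAB member...`) together
#' with a TSV sidecar carrying per-pathway metadata that GMT cannot hold
#' (source, species, pathway type, category, member kinds). Pathways smaller
#' than `min_core_members` after within-line deduplication are excluded and
#' counted in the load report; the default of 2 drops single-member pathways,
#' which carry no set-level information.
#'
#' @param gmt_path Path to a GMT file.
#' @param meta_path Path to the sidecar TSV with header
#'   `pathway_id, source, species, pathway_type, category, member_kinds`.
#'   A row with `pathway_id = "*"` supplies defaults for pathways absent from
#'   the sidecar. `member_kinds` may be empty (all gene), `"metabolite"`
#'   (all metabolite) or `|`-separated `id=kind` overrides.
#' @param min_core_members Minimum pathway size retained (default 2).
#' @param set_kind Set kind recorded on loaded pathways (default `"core"`).
#'
#' @return A [pathway_collection()] whose `load_report` records
#'   `excluded_count` and `excluded_ids`. Pathway ids are namespaced as
#'   `source:id` so identical ids from different sources never collide.
#' @export
read_gene_sets <- function(gmt_path, meta_path, min_core_members = 2,
                           set_kind = "core") {
  if (!is_count(min_core_members) || min_core_members < 1) {
    abort_config("min_core_members must be a positive integer")
  }
  lines <- readr::read_lines(gmt_path)
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  need <- c("pathway_id", "source", "species", "pathway_type", "category", "member_kinds")
  if (!all(need %in% names(meta))) {
    abort_validation(paste0("metadata sidecar missing columns: ",
                            paste(setdiff(need, names(meta)), collapse = ", ")))
  }
  default_row <- meta[meta$pathway_id == "*", , drop = FALSE]
  meta <- meta[meta$pathway_id != "*", , drop = FALSE]

  pw_rows <- list(); mem_rows <- list()
  excluded <- character(0)
  keep <- which(nzchar(trimws(lines)))
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      abort_parse(sprintf("malformed GMT line %d: expected at least 2 tab-separated fields", i))
    }
    raw_id <- fields[1]
    desc <- fields[2]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    m <- meta[meta$pathway_id == raw_id, , drop = FALSE]
    if (!nrow(m)) {
      if (!nrow(default_row)) {
        abort_validation(sprintf(
          "pathway '%s' (GMT line %d) missing from metadata sidecar and no '*' default supplied",
          raw_id, i))
      }
      m <- default_row
    }
    m <- m[1, ]
    if (length(members) < min_core_members) {
      excluded <- c(excluded, raw_id)
      next
    }
    src <- m$source
    pid <- if (startsWith(raw_id, paste0(src, ":"))) raw_id else paste0(src, ":", raw_id)
    kinds <- parse_member_kinds(m$member_kinds, members)
    pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
      pathway_id = pid,
      name = if (nzchar(desc)) desc else raw_id,
      description = desc,
      source = src,
      species = m$species,
      set_kind = set_kind,
      pathway_type = dplyr::coalesce(m$pathway_type, "unassigned"),
      category = dplyr::coalesce(m$category, "unassigned")
    )
    mem_rows[[length(mem_rows) + 1]] <- tibble::tibble(
      pathway_id = pid, member_id = members,
      member_kind = kinds, provenance = "curated"
    )
  }
  pathways <- if (length(pw_rows)) dplyr::bind_rows(pw_rows) else empty_pathway_table()
  members <- if (length(mem_rows)) dplyr::bind_rows(mem_rows) else empty_member_table()
  pathway_collection(pathways, members,
                     load_report = list(excluded_count = length(excluded),
                                        excluded_ids = excluded,
                                        min_core_members = min_core_members,
                                        n_loaded = nrow(pathways)))
}

empty_pathway_table <- function() {
  tibble::tibble(pathway_id = character(0), name = character(0),
                 description = character(0), source = character(0),
                 species = character(0), set_kind = character(0),
                 pathway_type = character(0), category = character(0))
}

empty_member_table <- function() {
  tibble::tibble(pathway_id = character(0), member_id = character(0),
                 member_kind = character(0), provenance = character(0))
}

#' Write a pathway collection as GMT plus metadata sidecar
#'
#' Inverse of [read_gene_sets()]: reading the written pair back yields the
#' same pathway/member multiset.
#'
#' @param collection A `pathway_collection`.
#' @param gmt_path,meta_path Output paths.
#' @return Invisibly, the collection.
#' @export
write_gene_sets <- function(collection, gmt_path, meta_path) {
  mem <- split(collection$members$member_id, collection$members$pathway_id)
  pw <- collection$pathways
  lines <- vapply(seq_len(nrow(pw)), function(i) {
    paste(c(pw$pathway_id[i], pw$description[i], mem[[pw$pathway_id[i]]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, gmt_path)
  kinds <- vapply(seq_len(nrow(pw)), function(i) {
    rows <- collection$members[collection$members$pathway_id == pw$pathway_id[i], ]
    if (all(rows$member_kind == "gene")) return("gene")
    if (all(rows$member_kind == "metabolite")) return("metabolite")
    nm <- rows[rows$member_kind != "gene", ]
    paste(paste0(nm$member_id, "=", nm$member_kind), collapse = "|")
  }, character(1))
  meta <- tibble::tibble(
    pathway_id = pw$pathway_id, source = pw$source, species = pw$species,
    pathway_type = pw$pathway_type, category = pw$category, member_kinds = kinds
  )
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(collection)
}

#' Restrict a collection by source, type, set kind and member kind
#'
#' @param collection A `pathway_collection`.
#' @param sources,types,set_kinds Character vectors of values to keep;
#'   `NULL` keeps everything. An explicitly empty `sources` selection is a
#'   configuration error because it would leave the enrichment background
#'   undefined.
#' @param member_kind Optional single member kind (`"gene"` or
#'   `"metabolite"`); members of the other kind are dropped and pathways
#'   left empty are removed.
#' @return A filtered `pathway_collection` (possibly with zero pathways).
#' @export
select_subset <- function(collection, sources = NULL, types = NULL,
                          set_kinds = NULL, member_kind = NULL) {
  if (!is.null(sources) && !length(sources)) {
    abort_config("empty sources selection: the background would be undefined")
  }
  check_known <- function(req, have, what) {
    unknown <- setdiff(req, have)
    if (length(unknown)) {
      abort_config(paste0("unknown ", what, " in selection: ",
                          paste(unknown, collapse = ", ")))
    }
  }
  pw <- collection$pathways
  if (!is.null(sources)) {
    check_known(sources, unique(pw$source), "source(s)")
    pw <- pw[pw$source %in% sources, ]
  }
  if (!is.null(types)) {
    check_known(types, unique(collection$pathways$pathway_type), "pathway type(s)")
    pw <- pw[pw$pathway_type %in% types, ]
  }
  if (!is.null(set_kinds)) {
    if (!all(set_kinds %in% SET_KINDS)) {
      abort_config(paste0("unknown set kind: ",
                          paste(setdiff(set_kinds, SET_KINDS), collapse = ", ")))
    }
    pw <- pw[pw$set_kind %in% set_kinds, ]
  }
  mem <- collection$members[collection$members$pathway_id %in% pw$pathway_id, ]
  if (!is.null(member_kind)) {
    if (!member_kind %in% MEMBER_KINDS) {
      abort_config("member_kind must be 'gene' or 'metabolite'")
    }
    mem <- mem[mem$member_kind == member_kind, ]
    pw <- pw[pw$pathway_id %in% mem$pathway_id, ]
  }
  pathway_collection(pw, mem, load_report = collection$load_report)
}
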