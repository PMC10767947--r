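#' Load a pathway taxonomy configuration
#'
#' A taxonomy declares exactly 7 pathway types (broad topics selectable
#' before enrichment) and exactly 53 categories (finer functional groups
#' used to consolidate results), each category belonging to one type, plus
#' an ordered rule list mapping pathways to categories. Three rule kinds are
#' supported, applied in fixed precedence: `manual` (curated pathway-id
#' assignments), `ontology_term` (a term whose descendant pathways inherit
#' its category, matched against supplied ancestor closures), and `regex`
#' (case-insensitive pattern on the pathway name).
#'
#' @param path YAML file with top-level keys `types` (7 labels),
#'   `categories` (list of `name`/`type` pairs, 53 entries) and `rules`
#'   (ordered list; each entry has `kind`, a matcher — `pathway_id`, `term`
#'   or `pattern` — and the assigned `type` and `category`).
#' @return A list of class `pathway_taxonomy` with elements `types`,
#'   `categories` (tibble `category`, `type`) and `rules` (tibble).
#' @export
read_taxonomy <- function(path) {
  cfg <- yaml::read_yaml(path)
  types <- as.character(cfg$types)
  if (length(types) != 7 || anyDuplicated(types)) {
    abort_validation(sprintf("taxonomy must declare exactly 7 distinct types (got %d)",
                             length(unique(types))))
  }
  cats <- dplyr::bind_rows(lapply(cfg$categories, function(x) {
    tibble::tibble(category = as.character(x$name), type = as.character(x$type))
  }))
  if (nrow(cats) != 53 || anyDuplicated(cats$category)) {
    abort_validation(sprintf("taxonomy must declare exactly 53 distinct categories (got %d)",
                             length(unique(cats$category))))
  }
  bad_parent <- setdiff(cats$type, types)
  if (length(bad_parent)) {
    abort_validation(paste0("category with unknown parent type: ",
                            paste(bad_parent, collapse = ", ")))
  }
  rules <- dplyr::bind_rows(lapply(seq_along(cfg$rules), function(i) {
    r <- cfg$rules[[i]]
    tibble::tibble(
      rule_id = i,
      kind = as.character(r$kind),
      match = as.character(r$pathway_id %||% r$term %||% r$pattern %||% NA_character_),
      type = as.character(r$type),
      category = as.character(r$category)
    )
  }))
  if (is.null(rules) || !nrow(rules)) {
    rules <- tibble::tibble(rule_id = integer(0), kind = character(0),
                            match = character(0), type = character(0),
                            category = character(0))
  }
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (!r$kind %in% c("manual", "ontology_term", "regex")) {
      abort_validation(sprintf("rule %d: unknown kind '%s'", i, r$kind))
    }
    if (is.na(r$match) || !nzchar(r$match)) {
      abort_validation(sprintf("rule %d: missing matcher", i))
    }
    row <- cats[cats$category == r$category, ]
    if (!nrow(row)) {
      abort_validation(sprintf("rule %d: unknown category '%s'", i, r$category))
    }
    if (row$type != r$type) {
      abort_validation(sprintf("rule %d: category '%s' belongs to type '%s', not '%s'",
                               i, r$category, row$type, r$type))
    }
    if (r$kind == "regex") {
      ok <- tryCatch({
        suppressWarnings(grepl(r$match, "x", ignore.case = TRUE, perl = TRUE))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) abort_validation(sprintf("rule %d: regex does not compile: %s", i, r$match))
    }
  }
  structure(list(types = types, categories = cats, rules = rules),
            class = "pathway_taxonomy")
}

#' The taxonomy shipped with the package
#'
#' Seven types following the top-level classes of the KEGG pathway ontology
#' and 53 categories reconstructed from KEGG sub-classes plus additional
#' categories (e.g. "Cellular response to stimuli", "Muscular and bone
#' system") covering pathways KEGG does not organise. The configuration is a
#' plain YAML file; users can replace it wholesale via [read_taxonomy()].
#'
#' @return A `pathway_taxonomy`.
#' @export
default_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "taxonomy.yaml", package = "pathmosaic",
                            mustWork = TRUE))
}

#' Read pathway ontology ancestor closures
#'
#' @param path TSV with header `pathway_id, ancestor_term_ids`; ancestors are
#'   `|`-separated and ordered from root to immediate parent, so the last
#'   matching term is the most specific.
#' @return Named list mapping pathway_id to its ordered ancestor vector.
#' @export
read_ontology_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("pathway_id", "ancestor_term_ids") %in% names(raw))) {
    abort_validation("ontology annotation table must have columns pathway_id, ancestor_term_ids")
  }
  setNames(split_bar(raw$ancestor_term_ids), raw$pathway_id)
}

## First matching rule wins, in precedence manual > ontology_term > regex.
## Among ontology rules the deepest (closest to the pathway) matching
## ancestor wins; ties go to the earlier rule.
assign_one <- function(pathway_id, name, taxonomy, ancestors = character(0)) {
  rules <- taxonomy$rules
  man <- rules[rules$kind == "manual" & rules$match == pathway_id, ]
  if (nrow(man)) return(c(man$type[1], man$category[1]))
  if (length(ancestors)) {
    ont <- rules[rules$kind == "ontology_term" & rules$match %in% ancestors, ]
    if (nrow(ont)) {
      depth <- match(ont$match, ancestors)
      best <- order(-depth, ont$rule_id)[1]
      return(c(ont$type[best], ont$category[best]))
    }
  }
  rex <- rules[rules$kind == "regex", ]
  for (i in seq_len(nrow(rex))) {
    if (grepl(rex$match[i], name, ignore.case = TRUE, perl = TRUE)) {
      return(c(rex$type[i], rex$category[i]))
    }
  }
  c("Unclassified", "Unclassified")
}

#' Assign pathway types and categories
#'
#' Applies the taxonomy's ordered rules to every pathway in a collection.
#' Assignment is total: pathways matching no rule receive the flagged
#' fallback `"Unclassified"` (outside the 53 categories) and are counted in
#' the assignment report.
#'
#' @param collection A `pathway_collection`.
#' @param taxonomy A `pathway_taxonomy`; defaults to [default_taxonomy()].
#' @param ontology Optional ancestor closures from
#'   [read_ontology_annotations()] (named list pathway_id -> ordered terms).
#' @return The collection with `pathway_type` and `category` filled in and an
#'   `assignment_report` element (`n_assigned`, `n_unclassified`,
#'   `unclassified_ids`).
#' @export
assign_categories <- function(collection, taxonomy = default_taxonomy(),
                              ontology = NULL) {
  pw <- collection$pathways
  res <- vapply(seq_len(nrow(pw)), function(i) {
    assign_one(pw$pathway_id[i], pw$name[i], taxonomy,
               ancestors = ontology[[pw$pathway_id[i]]] %||% character(0))
  }, character(2))
  if (nrow(pw)) {
    pw$pathway_type <- res[1, ]
    pw$category <- res[2, ]
  }
  out <- pathway_collection(pw, collection$members,
                            load_report = collection$load_report)
  uncl <- pw$pathway_id[pw$category == "Unclassified"]
  out$assignment_report <- list(n_assigned = nrow(pw) - length(uncl),
                                n_unclassified = length(uncl),
                                unclassified_ids = uncl)
  out$predictions <- collection$predictions
  out
}

#' Consolidated enrichment view: one representative pathway per category
#'
#' Collapses an enrichment result to at most 53 rows by keeping, per
#' category, the most enriched pathway — the row with minimal raw `p`
#' (ties broken by larger overlap `N_u`, then lexicographic name). Raw `p`
#' rather than an adjusted column is used because q-values are
#' family-dependent and not comparable across per-source runs; this is
#' configurable via `by`. Each representative carries the number of pathways
#' in its category and the smallest `q_bh` observed there, the quantities a
#' category-level summary chart plots. Unclassified rows never form a
#' category; they are returned separately in the `unclassified` attribute.
#'
#' @param rows A `pathway_enrichment` result (rows must carry `category`).
#' @param taxonomy Optional `pathway_taxonomy`; when supplied, categories in
#'   `rows` must belong to it.
#' @param by Column ranking "most enriched" (default `"p"`).
#' @return Tibble with one row per category present, sorted by `p`, with
#'   added columns `category_pathway_count` and `category_min_q`.
#' @export
consolidated_view <- function(rows, taxonomy = NULL, by = "p") {
  rows <- tibble::as_tibble(rows)
  if (!"category" %in% names(rows)) {
    abort_contract("enrichment rows carry no category column")
  }
  if (anyNA(rows$category)) {
    abort_contract("enrichment rows with missing category")
  }
  if (!by %in% names(rows)) abort_contract(paste0("no such ranking column: ", by))
  uncl_mask <- rows$category %in% c("Unclassified", "unassigned")
  uncl <- rows[uncl_mask, ]
  rows <- rows[!uncl_mask, ]
  if (!is.null(taxonomy)) {
    bad <- setdiff(unique(rows$category), taxonomy$categories$category)
    if (length(bad)) {
      abort_contract(paste0("categories outside the taxonomy: ",
                            paste(bad, collapse = ", ")))
    }
  }
  if (!nrow(rows)) {
    out <- dplyr::mutate(rows, category_pathway_count = integer(0),
                         category_min_q = numeric(0))
    return(structure(out, unclassified = uncl,
                     class = c("consolidated_view", class(out))))
  }
  out <- rows |>
    dplyr::mutate(category_pathway_count = dplyr::n(),
                  category_min_q = min(.data$q_bh),
                  .by = "category") |>
    dplyr::arrange(.data[[by]], dplyr::desc(.data$N_u), .data$name) |>
    dplyr::distinct(.data$category, .keep_all = TRUE) |>
    dplyr::arrange(.data$p, dplyr::desc(.data$N_u), .data$name)
  structure(out, unclassified = uncl, class = c("consolidated_view", class(out)))
}
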