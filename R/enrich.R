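#' Options controlling over-representation analysis
#'
#' @param sources Sources to include (`NULL` = all in the collection).
#' @param types Pathway types to include (`NULL` = all).
#' @param set_kind Which pathway set to test: `"core"`, `"ortholog"`,
#'   `"extended_experimental"` or `"extended_full"`.
#' @param mode `"combined"` (one background and one correction family over
#'   all selected sources) or `"per_source"` (the full procedure repeated
#'   independently per source: own background, own family size, own
#'   corrections).
#' @param filter_threshold Adjusted-p filter tier: 0.01, 0.05, 0.1 or
#'   `"none"` (return all rows).
#' @param filter_column Which adjusted column the filter applies to:
#'   `"q_bh"` (default) or `"q_bonferroni"`.
#' @param member_kind Run against gene or metabolite membership.
#' @param mirna_mode For [mirna_enrichment()]: `"intersection"` (genes
#'   targeted by all query miRNAs, the default) or `"union"`.
#' @return A list of class `enrichment_options`.
#' @export
enrichment_options <- function(sources = NULL, types = NULL, set_kind = "core",
                               mode = c("combined", "per_source"),
                               filter_threshold = "none",
                               filter_column = c("q_bh", "q_bonferroni"),
                               member_kind = c("gene", "metabolite"),
                               mirna_mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  filter_column <- match.arg(filter_column)
  member_kind <- match.arg(member_kind)
  mirna_mode <- match.arg(mirna_mode)
  if (!identical(filter_threshold, "none")) {
    if (!is.numeric(filter_threshold) ||
        !isTRUE(all.equal(min(abs(filter_threshold - c(0.01, 0.05, 0.1))), 0))) {
      abort_config("filter_threshold must be 0.01, 0.05, 0.1 or \"none\"")
    }
  }
  if (!is.null(sources) && !length(sources)) {
    abort_config("empty sources selection: the background would be undefined")
  }
  if (!set_kind %in% SET_KINDS) abort_config("unknown set_kind")
  structure(list(sources = sources, types = types, set_kind = set_kind,
                 mode = mode, filter_threshold = filter_threshold,
                 filter_column = filter_column, member_kind = member_kind,
                 mirna_mode = mirna_mode),
            class = "enrichment_options")
}

#' Build the enrichment background
#'
#' The background (universe) is the union of members of the requested kind
#' across all pathways surviving the source/type/set-kind selection; its size
#' is the `N_S` denominator of the over-representation test.
#'
#' @param collection A `pathway_collection`.
#' @param options An [enrichment_options()] object.
#' @return List with `background` (character vector of distinct members) and
#'   `pathways` (the selected `pathway_collection`).
#' @export
build_background <- function(collection, options = enrichment_options()) {
  sel <- select_subset(collection, sources = options$sources,
                       types = options$types, set_kinds = options$set_kind,
                       member_kind = options$member_kind)
  if (!nrow(sel$pathways)) {
    abort_config("selection matches no pathways: the background would be empty")
  }
  list(background = unique(sel$members$member_id), pathways = sel)
}

empty_enrichment_table <- function() {
  tibble::tibble(pathway_id = character(0), name = character(0),
                 source = character(0), pathway_type = character(0),
                 category = character(0), p = numeric(0), q_bh = numeric(0),
                 q_bonferroni = numeric(0), N_S = integer(0), N_U = integer(0),
                 N_Pw = integer(0), N_u = integer(0), ratio = numeric(0),
                 overlap_members = list())
}

run_enrichment_one <- function(query, collection, options, sources) {
  opts <- options
  opts$sources <- sources
  bg <- build_background(collection, opts)
  sel <- bg$pathways
  background <- bg$background
  q_in <- intersect(query, background)
  N_S <- length(background)
  N_U <- length(q_in)
  mem <- split(sel$members$member_id, sel$members$pathway_id)
  pw <- sel$pathways
  overlap <- lapply(pw$pathway_id, function(id) sort(intersect(mem[[id]], q_in)))
  N_Pw <- vapply(pw$pathway_id, function(id) length(mem[[id]]), integer(1))
  N_u <- lengths(overlap)
  p <- enrichment_p(N_S, N_Pw, N_U, N_u)
  family <- nrow(pw)
  rows <- tibble::tibble(
    pathway_id = pw$pathway_id, name = pw$name, source = pw$source,
    pathway_type = pw$pathway_type, category = pw$category,
    p = p, q_bh = bh_adjust(p), q_bonferroni = pmin(1, p * family),
    N_S = N_S, N_U = N_U, N_Pw = unname(N_Pw), N_u = unname(N_u),
    ratio = unname(N_u / N_Pw), overlap_members = overlap
  )
  rows <- dplyr::arrange(rows, .data$p, dplyr::desc(.data$N_u), .data$name)
  list(rows = rows, family = family, background_size = N_S,
       selection = sel, absent = setdiff(query, background))
}

#' Over-representation analysis of a query list
#'
#' Tests every selected pathway for over-representation of the query with
#' the one-sided Fisher exact (upper-tail hypergeometric) test
#' [enrichment_p()], against the background defined by the active selection.
#' Two corrections are reported per row: Benjamini-Hochberg (`q_bh`) and
#' Bonferroni (`q_bonferroni`), both over the family of pathways actually
#' tested in the active mode. In `per_source` mode the whole procedure —
#' background, tests, corrections — runs independently for each source,
#' which yields smaller families and hence q-values no larger than the
#' combined run for the same pathway.
#'
#' Query identifiers must already be in the collection's primary namespace
#' (see [map_identifiers()]). Query ids absent from the background do not
#' count toward `N_U`; they are listed in the coverage report rather than
#' silently dropped.
#'
#' @param query Character vector of primary identifiers.
#' @param collection A `pathway_collection`.
#' @param options An [enrichment_options()] object.
#' @return Tibble of class `pathway_enrichment`, one row per tested pathway
#'   surviving the adjusted-p filter, sorted by increasing `p` (ties: larger
#'   `N_u`, then name). Attributes: `options`, `coverage` (list with
#'   `absent_from_background` and per-source/set counts), `family_sizes` and
#'   `background_sizes` (named per source in `per_source` mode).
#' @export
run_enrichment <- function(query, collection, options = enrichment_options()) {
  query <- unique(as.character(query))
  if (options$mode == "combined") {
    res <- run_enrichment_one(query, collection, options, options$sources)
    rows <- res$rows
    family_sizes <- c(combined = res$family)
    background_sizes <- c(combined = res$background_size)
    absent <- res$absent
    coverage_tbl <- coverage_summary(query, res$selection)
  } else {
    sel_all <- select_subset(collection, sources = options$sources,
                             types = options$types, set_kinds = options$set_kind,
                             member_kind = options$member_kind)
    srcs <- sort(unique(sel_all$pathways$source))
    if (!length(srcs)) abort_config("selection matches no pathways")
    per <- lapply(srcs, function(s) run_enrichment_one(query, collection, options, s))
    rows <- dplyr::bind_rows(lapply(per, `[[`, "rows"))
    family_sizes <- setNames(vapply(per, `[[`, numeric(1), "family"), srcs)
    background_sizes <- setNames(vapply(per, `[[`, numeric(1), "background_size"), srcs)
    absent <- Reduce(intersect, lapply(per, `[[`, "absent"))
    coverage_tbl <- coverage_summary(query, sel_all)
  }
  if (!identical(options$filter_threshold, "none")) {
    rows <- rows[rows[[options$filter_column]] < options$filter_threshold, ]
  }
  structure(rows,
            options = options,
            coverage = list(absent_from_background = absent,
                            by_source_set = coverage_tbl),
            family_sizes = family_sizes,
            background_sizes = background_sizes,
            n_query = length(query),
            class = c("pathway_enrichment", class(rows)))
}

#' miRNA-level over-representation analysis
#'
#' Resolves each query miRNA to its target gene set, combines the sets —
#' by default the intersection, i.e. genes targeted by *all* query miRNAs;
#' optionally the union — and runs [run_enrichment()] on the combined list.
#' miRNAs absent from the target table are skipped and reported.
#'
#' @param mirnas Character vector of miRNA identifiers.
#' @param targets Tibble with columns `mirna`, `target`, or a path to a TSV
#'   with that header.
#' @param collection A `pathway_collection`.
#' @param options An [enrichment_options()] object; `options$mirna_mode`
#'   selects intersection vs union.
#' @return A `pathway_enrichment` tibble with an extra `mirna_report`
#'   attribute (`used`, `missing`, `query_size`). If no miRNA resolves, an
#'   empty result with the report.
#' @export
mirna_enrichment <- function(mirnas, targets, collection,
                             options = enrichment_options()) {
  if (is.character(targets) && length(targets) == 1) {
    targets <- readr::read_tsv(targets, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  }
  targets <- tibble::as_tibble(targets)
  if (!all(c("mirna", "target") %in% names(targets))) {
    abort_validation("target table must have columns mirna, target")
  }
  mirnas <- unique(as.character(mirnas))
  missing <- setdiff(mirnas, targets$mirna)
  used <- setdiff(mirnas, missing)
  report <- list(used = used, missing = missing)
  if (!length(used)) {
    out <- structure(empty_enrichment_table(),
                     options = options,
                     coverage = list(absent_from_background = character(0),
                                     by_source_set = NULL),
                     family_sizes = numeric(0), background_sizes = numeric(0),
                     n_query = 0L,
                     class = c("pathway_enrichment", class(empty_enrichment_table())))
    report$query_size <- 0L
    attr(out, "mirna_report") <- report
    return(out)
  }
  sets <- lapply(used, function(m) unique(targets$target[targets$mirna == m]))
  combine <- if (options$mirna_mode == "union") union else intersect
  query <- Reduce(combine, sets)
  out <- run_enrichment(query, collection, options)
  report$query_size <- length(query)
  attr(out, "mirna_report") <- report
  out
}

#' @export
tidy.pathway_enrichment <- function(x, ...) {
  out <- tibble::as_tibble(x)
  if ("overlap_members" %in% names(out)) {
    out$overlap_members <- join_bar(out$overlap_members)
  }
  out
}

#' @export
glance.pathway_enrichment <- function(x, ...) {
  opts <- attr(x, "options")
  tibble::tibble(
    n_rows = nrow(x),
    n_significant_bh_05 = sum(x$q_bh < 0.05),
    n_tested = sum(attr(x, "family_sizes")),
    n_query = attr(x, "n_query"),
    n_query_in_background = attr(x, "n_query") -
      length(attr(x, "coverage")$absent_from_background),
    mode = opts$mode,
    set_kind = opts$set_kind
  )
}

#' Plot the most enriched pathways
#'
#' Horizontal bar chart of `-log10(q)` for the top pathways, faceted by
#' source when the result came from a per-source run.
#'
#' @param object A `pathway_enrichment` result.
#' @param n_top Pathways shown (per source in per-source mode).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_enrichment <- function(object, n_top = 7, ...) {
  opts <- attr(object, "options")
  df <- top_pathways_per_source(tibble::as_tibble(object), k = n_top)
  df$neg_log_q <- -log10(pmax(df$q_bh, .Machine$double.xmin))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neg_log_q,
    y = stats::reorder(paste(.data$source, .data$name, sep = ": "), .data$neg_log_q)
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = expression(-log[10](q[BH])), y = NULL,
                  title = "Most enriched pathways") +
    ggplot2::theme_minimal()
  if (!is.null(opts) && opts$mode == "per_source") {
    p <- p + ggplot2::facet_wrap(~source, scales = "free_y")
  }
  p
}

#' Write enrichment results as TSV
#'
#' Probabilities are formatted to 6 significant digits and overlap members
#' joined with `|`, so repeated runs on the same inputs are byte-identical.
#'
#' @param rows A `pathway_enrichment` result (or compatible tibble).
#' @param path Output path.
#' @return Invisibly, `rows`.
#' @export
write_enrichment <- function(rows, path) {
  out <- tidy.pathway_enrichment(rows)
  for (col in intersect(c("p", "q_bh", "q_bonferroni", "ratio"), names(out))) {
    out[[col]] <- format_num(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(rows)
}
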