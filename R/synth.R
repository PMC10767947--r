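#' Configuration for the synthetic input generator
#'
#' Describes a complete synthetic study: a gene universe, multi-source
#' pathway sets with type/category labels, a planted-partition interaction
#' network (within-pathway edge probability `p_in`, background probability
#' `p_out`), pathway orphans wired preferentially into one pathway so that
#' connectivity-based extension can rediscover them, degree-matched random
#' probe proteins as negative controls, an identifier map, a one-to-one
#' ortholog table, miRNA target sets, and a query list enriched for one
#' signal pathway.
#'
#' Defaults encode the benchmark conditions used throughout the package's
#' tests: a 100-gene network, a 10-member planted pathway, and an orphan
#' with 10 partners of which 8 lie inside the pathway.
#'
#' @param seed Integer seed; every emitted file is a deterministic function
#'   of it (per-file derived substreams, so adding an output never perturbs
#'   earlier files).
#' @param n_genes Genes in the universe.
#' @param n_pathways Pathways generated.
#' @param pathway_size_range Inclusive size range for sampled pathways; the
#'   planted signal pathway is fixed at `planted_size`.
#' @param planted_size Size of the planted/signal pathway (default 10).
#' @param n_sources Number of source databases emulated.
#' @param type_weights Named sampling weights over the 7 default types
#'   (default uniform).
#' @param p_in,p_out Within-pathway and background edge probabilities.
#' @param predicted_fraction Fraction of edges labelled `predicted`.
#' @param n_orphans Pathway orphans planted (absent from every gene set).
#' @param orphan_partners Partner count per orphan (and per random probe).
#' @param orphan_in_fraction Fraction of orphan partners drawn from the
#'   planted pathway.
#' @param n_random_probes Degree-matched, uniformly wired negative-control
#'   proteins.
#' @param query_size,signal_fraction Query list size and the fraction of it
#'   drawn from the signal pathway.
#' @param ortholog_fraction Fraction of genes given a one-to-one ortholog.
#' @param target_species Species code for the ortholog table.
#' @param n_mirnas,targets_per_mirna,shared_targets miRNA target table shape:
#'   each miRNA receives `shared_targets` common genes plus its own draws up
#'   to `targets_per_mirna`.
#' @param species Species code of the bundle.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_genes = 100, n_pathways = 12,
                         pathway_size_range = c(5, 15), planted_size = 10,
                         n_sources = 2, type_weights = NULL,
                         p_in = 0.3, p_out = 0.05, predicted_fraction = 0.3,
                         n_orphans = 1, orphan_partners = 10,
                         orphan_in_fraction = 0.8, n_random_probes = 1,
                         query_size = 10, signal_fraction = 0.7,
                         ortholog_fraction = 0.7, target_species = "Mm",
                         n_mirnas = 3, targets_per_mirna = 12,
                         shared_targets = 4, species = "Hs") {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              planted_size = planted_size, n_sources = n_sources,
              type_weights = type_weights, p_in = p_in, p_out = p_out,
              predicted_fraction = predicted_fraction, n_orphans = n_orphans,
              orphan_partners = orphan_partners,
              orphan_in_fraction = orphan_in_fraction,
              n_random_probes = n_random_probes, query_size = query_size,
              signal_fraction = signal_fraction,
              ortholog_fraction = ortholog_fraction,
              target_species = target_species, n_mirnas = n_mirnas,
              targets_per_mirna = targets_per_mirna,
              shared_targets = shared_targets, species = species)
  probs <- c(p_in, p_out, predicted_fraction, orphan_in_fraction,
             signal_fraction, ortholog_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    abort_config("all probabilities must lie in [0, 1]")
  }
  if (max(pathway_size_range) > n_genes || planted_size > n_genes) {
    abort_config("pathway size exceeds the gene universe")
  }
  if (orphan_partners > n_genes) abort_config("orphan_partners exceeds the gene universe")
  if (query_size > n_genes) abort_config("query_size exceeds the gene universe")
  if (!species %in% SPECIES_CODES || !target_species %in% SPECIES_CODES) {
    abort_config("unknown species code")
  }
  structure(cfg, class = "synth_config")
}

## Per-section substream so each output file is independently reproducible
derive_seed <- function(seed, section) {
  as.integer((as.double(seed) * 1009 + section * 7919) %% .Machine$integer.max)
}

sample_pairs <- function(ids, prob) {
  if (length(ids) < 2 || prob <= 0) {
    return(tibble::tibble(protein_a = character(0), protein_b = character(0)))
  }
  pairs <- utils::combn(sort(ids), 2)
  keep <- stats::runif(ncol(pairs)) < prob
  tibble::tibble(protein_a = pairs[1, keep], protein_b = pairs[2, keep])
}

#' Generate a complete synthetic input bundle
#'
#' Writes every file format the analysis functions consume — gene sets
#' (GMT + metadata sidecar), PPI edge list, identifier map, ortholog table,
#' miRNA target table, query list — plus a JSON manifest recording the
#' planted truths (orphan wiring, signal pathway, category assignments) so
#' tests can score recovery against ground truth. Byte-identical across runs
#' with the same configuration.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list (with a `files` element of
#'   absolute paths).
#' @export
generate_bundle <- function(config, dir) {
  if (!inherits(config, "synth_config")) abort_config("config must come from synth_config()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  taxa <- default_taxonomy()

  ## pathways ----------------------------------------------------------------
  set.seed(derive_seed(config$seed, 1))
  n_pw <- config$n_pathways
  pw_ids <- sprintf("P%02d", seq_len(n_pw))
  sources <- paste0("SRC", LETTERS[seq_len(config$n_sources)])
  pw_source <- sources[((seq_len(n_pw) - 1) %% config$n_sources) + 1]
  weights <- config$type_weights %||% setNames(rep(1, 7), taxa$types)
  pw_type <- sample(taxa$types, n_pw, replace = TRUE, prob = weights[taxa$types])
  pw_cat <- vapply(pw_type, function(tp) {
    sample(taxa$categories$category[taxa$categories$type == tp], 1)
  }, character(1))
  sizes <- sample(seq(config$pathway_size_range[1], config$pathway_size_range[2]),
                  n_pw, replace = TRUE)
  sizes[1] <- config$planted_size    # pathway 1 is the planted/signal pathway
  pw_members <- lapply(sizes, function(s) sort(sample(genes, s)))
  names(pw_members) <- pw_ids

  gmt_lines <- vapply(seq_len(n_pw), function(i) {
    paste(c(pw_ids[i], sprintf("Synthetic pathway %s", pw_ids[i]), pw_members[[i]]),
          collapse = "\t")
  }, character(1))
  meta <- tibble::tibble(pathway_id = pw_ids, source = pw_source,
                         species = config$species, pathway_type = pw_type,
                         category = pw_cat, member_kinds = "gene")

  ## ppi ---------------------------------------------------------------------
  set.seed(derive_seed(config$seed, 2))
  within <- dplyr::bind_rows(lapply(pw_members, sample_pairs, prob = config$p_in))
  background <- sample_pairs(genes, config$p_out)
  edges <- dplyr::distinct(dplyr::bind_rows(within, background))
  edges$evidence <- ifelse(stats::runif(nrow(edges)) < config$predicted_fraction,
                           "predicted", "experimental")
  planted_pw <- pw_ids[1]
  planted_members <- pw_members[[planted_pw]]
  n_in <- round(config$orphan_partners * config$orphan_in_fraction)
  orphans <- list()
  for (i in seq_len(config$n_orphans)) {
    prot <- sprintf("ORPH%02d", i)
    ins <- sample(planted_members, min(n_in, length(planted_members)))
    outs <- sample(setdiff(genes, planted_members),
                   config$orphan_partners - length(ins))
    partners <- c(ins, outs)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      protein_a = prot, protein_b = partners, evidence = "experimental"))
    orphans[[i]] <- list(protein = prot, pathway = planted_pw,
                         partners = as.list(sort(partners)))
  }
  probes <- list()
  for (i in seq_len(config$n_random_probes)) {
    prot <- sprintf("RAND%02d", i)
    partners <- sample(genes, config$orphan_partners)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      protein_a = prot, protein_b = partners, evidence = "experimental"))
    probes[[i]] <- list(protein = prot, partners = as.list(sort(partners)))
  }

  ## id map ------------------------------------------------------------------
  set.seed(derive_seed(config$seed, 3))
  idmap <- tibble::tibble(
    primary_id = genes,
    alternate_ids = sprintf("ALT%04d", seq_along(genes)),
    symbol = paste0("SYM_", genes),
    synonyms = tolower(paste0("sy_", genes))
  )

  ## orthologs ---------------------------------------------------------------
  set.seed(derive_seed(config$seed, 4))
  with_orth <- sort(sample(genes, round(config$ortholog_fraction * length(genes))))
  ortho <- tibble::tibble(species_from = config$species, id_from = with_orth,
                          species_to = config$target_species,
                          id_to = paste0(config$target_species, "_", with_orth))

  ## mirna targets -----------------------------------------------------------
  set.seed(derive_seed(config$seed, 5))
  shared <- sample(planted_members, min(config$shared_targets, length(planted_members)))
  mirnas <- sprintf("miR-%02d", seq_len(config$n_mirnas))
  mirna_tbl <- dplyr::bind_rows(lapply(mirnas, function(m) {
    own <- sample(setdiff(genes, shared),
                  max(0, config$targets_per_mirna - length(shared)))
    tibble::tibble(mirna = m, target = sort(unique(c(shared, own))))
  }))

  ## query -------------------------------------------------------------------
  set.seed(derive_seed(config$seed, 6))
  n_sig <- round(config$query_size * config$signal_fraction)
  sig <- sample(planted_members, min(n_sig, length(planted_members)))
  noise <- sample(setdiff(genes, planted_members), config$query_size - length(sig))
  query <- c(sig, noise)

  ## write -------------------------------------------------------------------
  paths <- list(
    gmt = file.path(dir, "gene_sets.gmt"),
    meta = file.path(dir, "gene_sets_meta.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    idmap = file.path(dir, "idmap.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    query = file.path(dir, "query.txt"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_lines(gmt_lines, paths$gmt)
  readr::write_tsv(meta, paths$meta, progress = FALSE)
  edges <- dplyr::arrange(edges, .data$protein_a, .data$protein_b)
  readr::write_tsv(edges, paths$ppi, progress = FALSE)
  readr::write_tsv(idmap, paths$idmap, progress = FALSE)
  readr::write_tsv(ortho, paths$orthologs, progress = FALSE)
  readr::write_tsv(mirna_tbl, paths$mirna_targets, progress = FALSE)
  readr::write_lines(query, paths$query)

  src1 <- pw_source[1]
  manifest <- list(
    seed = config$seed,
    species = config$species,
    n_genes = config$n_genes,
    signal_pathway = list(raw_id = planted_pw,
                          pathway_id = paste0(src1, ":", planted_pw),
                          members = as.list(planted_members)),
    planted_orphans = orphans,
    random_probes = probes,
    categories = as.list(setNames(pw_cat, paste0(pw_source, ":", pw_ids))),
    query = as.list(query),
    files = lapply(paths[setdiff(names(paths), "manifest")], basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest$files <- paths
  invisible(manifest)
}
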