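## Fixture builders and independent oracles shared across the suite.

make_collection <- function(members, source = "SRCA", species = "Hs",
                            set_kind = "core", pathway_type = "unassigned",
                            category = "unassigned", member_kind = "gene") {
  n <- length(members)
  pw <- tibble::tibble(
    pathway_id = names(members),
    name = names(members),
    description = names(members),
    source = rep_len(source, n),
    species = species,
    set_kind = rep_len(set_kind, n),
    pathway_type = rep_len(pathway_type, n),
    category = rep_len(category, n)
  )
  mem <- dplyr::bind_rows(lapply(names(members), function(id) {
    tibble::tibble(pathway_id = id, member_id = members[[id]],
                   member_kind = rep_len(member_kind, length(members[[id]])),
                   provenance = "curated")
  }))
  pathway_collection(pw, mem)
}

write_fixture_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

write_fixture_lines <- function(lines, ext = ".gmt") {
  path <- tempfile(fileext = ext)
  readr::write_lines(lines, path)
  path
}

standard_meta <- function(ids, source = "SRCA", species = "Hs",
                          pathway_type = "unassigned", category = "unassigned",
                          member_kinds = "gene") {
  tibble::tibble(pathway_id = ids, source = source, species = species,
                 pathway_type = pathway_type, category = category,
                 member_kinds = member_kinds)
}

## Brute-force oracle: enumerate every n-subset of an N-element universe with
## the first M elements marked; tail probability is the fraction of subsets
## with at least k marked elements.
enum_tail <- function(k, N, M, n) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subs <- utils::combn(N, n)
  if (is.null(dim(subs))) subs <- matrix(subs, nrow = n)
  mean(colSums(subs <= M) >= k)
}

## Exact-arithmetic oracle: binomial coefficients from the Pascal recurrence
## (integer additions only; exact in doubles for N <= 25), summed directly.
pascal_binom <- function(N) {
  C <- matrix(0, N + 1, N + 1)
  C[, 1] <- 1
  for (i in seq_len(N)) {
    for (j in seq_len(i)) C[i + 1, j + 1] <- C[i, j] + C[i, j + 1]
  }
  C
}

exact_tail <- function(k, N, M, n, C = pascal_binom(N)) {
  if (k == 0) return(1)
  hi <- min(n, M)
  if (k > hi) return(0)
  num <- sum(vapply(k:hi, function(m) C[M + 1, m + 1] * C[N - M + 1, n - m + 1],
                    numeric(1)))
  num / C[N + 1, n + 1]
}

## Step-up FDR adjustment written straight from its definition.
bh_stepup <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

## 30-gene background split over two sources whose unions coincide, so
## per-source and combined runs share the same background and differ only in
## family size.
enrich_fixture <- function() {
  g <- sprintf("G%02d", 1:30)
  make_collection(
    list(P = g[1:8], QA = g[5:30], PB = g[1:20], QB = g[15:30]),
    source = c("SRCA", "SRCA", "SRCB", "SRCB")
  )
}

## Deterministic hand-built extension fixture: a 100-gene chain network plus
## one pathway of 10 members and an orphan wired to 8 members + 2 others,
## so N = 101, M = 10, n = 10, m = 8.
chain_orphan_fixture <- function() {
  genes <- sprintf("G%03d", 1:100)
  pw_members <- genes[1:10]
  edges <- tibble::tibble(protein_a = genes[-100], protein_b = genes[-1],
                          evidence = "experimental")
  orphan_partners <- c(pw_members[1:8], genes[51:52])
  edges <- dplyr::bind_rows(edges, tibble::tibble(
    protein_a = "ORPHAN", protein_b = orphan_partners, evidence = "experimental"))
  list(
    network = ppi_network(edges, "Hs"),
    collection = make_collection(list(P = pw_members)),
    orphan = "ORPHAN",
    contingency = list(N = 101, M = 10, n = 10, m = 8)
  )
}
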