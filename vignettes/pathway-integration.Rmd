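---
title: "Methods: pathway integration, network extension and consolidated enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway integration, network extension and consolidated enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design decisions that were
genuinely open, and what the synthetic benchmarks do and do not demonstrate.

```{r setup, message = FALSE}
library(pathmosaic)
```

## The data model

A `pathway_collection` pairs a pathway-level tibble (id, name, source,
species, set kind, type, category) with a long membership tibble (pathway,
member, member kind, provenance). Members are genes or metabolites; a given
identifier has one fixed kind across a collection. Set kinds record
provenance of the whole set: `core` (literature-curated), `ortholog`
(projected across species), `extended_experimental` / `extended_full`
(augmented from PPI connectivity under the two evidence classes). Pathway
ids are namespaced as `source:id` at load time, because identical raw ids in
different source databases denote different pathways.

Two size floors apply, deliberately different:

* **`min_core_members = 2`** at load: a "pathway" with a single member
  carries no set-level information, so single-member sets are excluded (the
  count is reported, not silent). The threshold is configurable.
* **`min_members = 3`** after ortholog projection: projection loses members
  (not every gene has a one-to-one ortholog), and a surviving single protein
  or single interacting pair is not meaningfully a pathway in the target
  species. Metabolites are dropped before projection — orthology is a
  gene-level relation.

Identifier resolution walks a fixed namespace precedence — exact primary id,
exact alternate id, case-insensitive symbol, case-insensitive synonym — and
an alias matching several records at its winning tier is reported as
ambiguous rather than guessed. The precedence order itself is a design
choice (more authoritative namespaces first); what is not negotiable is that
ambiguity is surfaced, never silently resolved.

## Membership prediction from network connectivity

The extension step is guilt-by-association made exact. For protein $i$ with
$n$ interaction partners in a network of $N$ proteins, and a pathway with
$M$ network proteins among its curated members of which $m$ are partners of
$i$, the probability of at least $m$ in-pathway partners under random wiring
is the upper-tail hypergeometric sum

$$\Pr(X \ge m) \;=\; \sum_{j=m}^{\min(n,M)}
\frac{\binom{M}{j}\binom{N-M}{n-j}}{\binom{N}{n}}.$$

Decisions embedded in the implementation, and why:

* **$N$ counts proteins incident to at least one edge** in the chosen
  evidence subset. An edge-list format has no natural notion of an isolated
  node, so edge-incidence is the only self-consistent reading; restricting
  the evidence class (experimental-only vs full) therefore shrinks $N$ too.
* **Candidate family**: all pathways containing at least one partner of the
  protein, *excluding* pathways the protein already belongs to. Predicting a
  known member is vacuous and would distort the correction family size.
* **BH correction runs within each protein's candidate family**
  (`scope = "per_protein"`), i.e. the multiple-testing question asked is
  "which of the pathways suggested by this protein's neighbourhood are
  credible?". A global variant (one family across all protein–pathway
  tests) is available behind `scope = "global"` but is not the default: the
  per-protein family matches how predictions are consumed (per protein) and
  keeps a protein's results invariant to unrelated proteins.
* **Retention is strict**: adjusted probability $< \alpha$ with
  $\alpha = 0.01$ by default. At $\alpha = 0$ nothing is retained — a useful
  boundary check that the extension is a pure augmentation (curated
  membership is never removed; every core pathway is a subset of its
  extended counterpart).
* Conflicting duplicate edges merge with **experimental evidence winning**,
  since experimental detection subsumes a computational prediction of the
  same contact; self-loops are dropped (a protein is never its own partner).

## Over-representation analysis

The enrichment test is the one-sided Fisher exact test: with background size
$N_S$, in-background query size $N_U$, pathway size $N_{Pw}$ and overlap
$N_u$,

$$p \;=\; \sum_{x=N_u}^{\min(N_U,\,N_{Pw})}
\frac{\binom{N_{Pw}}{x}\binom{N_S-N_{Pw}}{N_U-x}}{\binom{N_S}{N_U}}.$$

A two-sided variant is intentionally not offered; depletion is a different
scientific question from over-representation.

* **The background is user-selected**: the union of distinct members of the
  requested kind (gene or metabolite) across the pathways surviving the
  source/type/set-kind selection. Query ids outside the background are
  excluded from $N_U$ — forced by the definition of $N_U$ — and surfaced in
  the coverage report instead of being silently dropped. Distinct members
  (not member–source annotation pairs) are counted, the plain reading of a
  "number of proteins" denominator.
* **Correction family = pathways actually tested** in the active mode. Both
  corrections (BH as `q_bh`, Bonferroni as `q_bonferroni`) are reported per
  row; the adjusted-p filter tiers are 0.01 / 0.05 / 0.1 / none, applied by
  strict inequality to a selectable column (BH by default).
* **Per-source mode** repeats the full procedure independently per source:
  own background, own family, own corrections. With sources spanning the
  same member universe this provably never inflates Bonferroni q-values and
  in practice yields smaller adjusted values (the smaller family). One
  caveat found during development and worth stating: BH adjustment is *not*
  universally monotone under family restriction — a sub-family q-value can
  exceed the full-family one when another source contributes p-values just
  above the pathway's own. The mode-consistency guarantee is therefore a
  property of comparable backgrounds and is tested as such, not claimed as
  a theorem for arbitrary inputs.
* **Ordering** is deterministic: ascending p, ties broken by larger overlap,
  then name. TSV exports fix floating-point formatting to 6 significant
  digits so repeated runs are byte-identical.
* **miRNA mode** resolves each query miRNA to its target set and, by
  default, intersects them — enrichment of genes targeted by *all* query
  miRNAs — with union available. Intersection is the default because the
  per-miRNA union question is already answered by running each miRNA
  separately; the intersection is the genuinely new composite query.

## Taxonomy and consolidation

The taxonomy declares exactly 7 pathway types and exactly 53 categories,
each category under one type, and validates those cardinalities at load.
The shipped configuration follows the top-level classes of the KEGG pathway
ontology for the types and reconstructs the categories from KEGG sub-classes
plus categories (e.g. *Cellular response to stimuli*, *Muscular and bone
system*) covering pathway space KEGG does not organise; it is an explicit,
user-replaceable YAML file, not a canonical list.

Assignment applies ordered rules with fixed precedence **manual >
ontology-term > regex**: curation overrides heuristics, and an ontology
placement (a high-level term mapped to a category, descendants inheriting
it) is more reliable than a name pattern. Among matching ontology rules the
*deepest* matching ancestor wins — ancestor closures are supplied
root-to-parent, so the most specific placement decides; ties fall to the
earlier rule. Assignment is total: unmatched pathways get the flagged
fallback `Unclassified`, which is outside the 53 categories and never forms
a row of the consolidated view.

The consolidated view keeps, per category present in the input, the row with
minimal **raw p** (ties: larger overlap, then name), annotated with the
category's pathway count and minimal `q_bh`. Raw p rather than q ranks the
representatives because q-values are family-dependent and not comparable
across per-source runs; the ranking column is a parameter for users who
disagree. Output is therefore bounded at 53 rows by construction.

## The synthetic generator

`synth_config()` / `generate_bundle()` emit every input format the engine
consumes, deterministically from one integer seed (per-file derived
substreams, so adding an output file never perturbs earlier ones), plus a
JSON manifest of planted truths for scoring.

The generator emulates exactly the structure the methods exploit:

* a planted-partition PPI network — within-pathway edge probability `p_in =
  0.3`, background `p_out = 0.05`, 30% of edges labelled predicted;
* **pathway orphans**: proteins absent from every gene set, wired to 10
  partners of which 8 sit in one planted 10-member pathway — discoverable
  only through the network;
* degree-matched **random probes** wired uniformly, as negative controls;
* a query list with 7 of 10 genes drawn from the signal pathway;
* an id map, a one-to-one ortholog table covering 70% of genes, and miRNA
  target sets sharing a common core.

The default universe is 100 genes and 12 pathways of 5–15 members. These are
the benchmark conditions used throughout the test suite: the exhaustive
oracle grid runs at $N \le 25$ (with literal subset enumeration at
$N \le 12$ and exact Pascal-recurrence binomials above), orphan recovery
uses 50 seeded bundles, and the null false-positive check uses 500
uniform-background query replicates — sizes at which every check is exact or
tightly concentrated.

What the generator does **not** emulate, and hence what passing tests do not
show: real interactomes are scale-free and study-biased (hub proteins are
over-annotated), real pathway databases overlap heavily and non-randomly,
and real identifier maps contain genuine many-to-many tangles. The
benchmarks validate the *contracts* — correct tail probabilities, correct
corrections, recovery of planted structure at the configured effect size,
nominal false-positive control — not field performance on any particular
release of curated data.

## Numerical notes

* Both tail sums accumulate $\log$-binomial terms (`lchoose`) and reduce via
  log-sum-exp; results are clipped into $[0,1]$. This is stable to network
  and background sizes around $10^5$.
* `k = 0` returns exactly 1 (full support) without touching the sum.
* BH adjustment delegates to the standard step-up implementation
  (`stats::p.adjust`); the test suite verifies it against a direct
  evaluation of $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ on a thousand
  seeded vectors including ties and all-ones.
* Contingency bounds are validated before any computation; violations are
  domain errors, not NaNs.

## Known limitations

* Ortholog projection is strictly one-to-one; many-to-many orthology is out
  of scope, and violating records are rejected with a report rather than
  resolved.
* Enrichment is over-representation only — no ranked-list (GSEA-style) or
  topology-aware statistics.
* The shipped taxonomy's category list is a faithful-cardinality
  reconstruction; analyses that depend on specific category semantics should
  supply their own configuration.
* Chart functions return ggplot objects built from the chart-ready tables;
  the tables, not the renderings, are the tested interface.
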