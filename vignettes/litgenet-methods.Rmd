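---
title: "Mining gene trends, networks and clusters from abstract corpora"
author: "litgenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene trends, networks and clusters from abstract corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litgenet)
```

# The problem

Given a large set of biomedical abstracts on one disease topic — the motivating
case is a breast-cancer retrieval of several hundred thousand PubMed records —
litgenet derives three families of hypotheses about the *research landscape*,
not about biology itself:

* **who studies what**: which countries' author affiliations co-occur with
  which genes, how much of each country's output a gene absorbs (the *effort*
  fraction), and which countries collaborate;
* **what is studied together**: maximal closed frequent gene itemsets over
  per-country and per-year transactions, and communities in the gene–gene
  co-occurrence network;
* **how the gene landscape organises**: complete-link clustering of countries
  by gene profile, and fuzzy c-means clustering of genes with partition
  validity indices.

Everything runs offline. The services a live deployment would call (PubMed
retrieval, a web annotation service, an online geocoder) are replaced by file
readers, a dictionary matcher over a synonym lexicon, and a gazetteer, so
results are reproducible from the repository alone.

# Pipeline stages and their models

## Corpus intake

`read_medline_xml()` and `read_jsonl()` build a corpus of records (id, title,
abstract, year, journal, authors with verbatim affiliation strings).
`filter_complete()` keeps records with an abstract, a title, at least one
author and a journal, reporting per-reason removal counts. Records without a
*year* are kept at this stage: only year-dependent analyses drop them, which
keeps the completeness filter orthogonal to the time axis. Text fields are
whitespace-normalised on read so downstream matching is stable.

## Dictionary gene recognition

`build_lexicon()` ingests (symbol, synonym) pairs; a synonym claimed by two
symbols is ambiguous and is dropped with a report, so lookup is single-valued.
Protein names are handled by listing them as synonyms of their gene, which
keeps the matcher single-pass. `annotate()` finds longest, non-overlapping,
token-boundary-respecting matches over title and abstract (both are scanned;
counting is per-abstract presence, so the choice only widens recall).
Numerical/matching choices:

* token boundaries are non-alphanumeric characters on both sides; hyphens are
  boundaries, because gene names embed in hyphenated phrases;
* synonyms of three characters or fewer match case-sensitively — short
  acronyms collide with ordinary words and place abbreviations — while longer
  synonyms match case-insensitively;
* among equal candidates the leftmost-then-longest match wins, which makes
  annotation a pure, order-insensitive function of text and lexicon. The test
  suite checks it against a try-every-synonym-at-every-offset oracle.

## Country resolution

Affiliations are comma-split into sub-addresses. The query starts at the
*rightmost* sub-address, which usually carries the country, and while it
matches zero or two-or-more countries the next sub-address to the left is
prepended and the lookup retried; success means exactly one distinct country.
Gazetteer aliases match by case-insensitive word-bounded containment (so
"AB Canada" resolves without a geocoder); *hints* — city or institution
keywords — match by exact equality of the whole query and are consulted only
when no alias matches. Hints may legitimately point at several countries;
that simply leaves the query ambiguous until more context is added, which is
what makes leftward escalation useful. A cache keyed by resolved query
strings skips repeated gazetteer work; it can never change a result, only
avoid recomputing it, and the suite asserts cache-on/cache-off equality.
A record's countries are the union over all its authors' resolved
affiliations, matching the collaboration definition, which needs
multi-country sets per paper.

## Count metrics

`gene_country_counts()` counts *abstracts* (presence, not token frequency);
a multi-country paper counts fully toward each of its countries, so
per-country totals stay integers. Records with no resolved country are kept
in a reserved `"(unresolved)"` row, excluded from rankings and effort, so
totals remain checkable. `effort()` divides each cell by the country's paper
count; at the stage where counts are computed the corpus is the gene-bearing
set, so that is the denominator. Effort rows may sum above 1 because one
abstract can mention several genes. Rankings break ties lexicographically.

## Itemset mining

Transactions are binary presence sets: one per country (all genes any of its
abstracts mention) and one per year. This reproduces the natural support
denominators — the number of countries or years — and deliberately applies no
minimum abstract count per gene. Support is reported as a percentage rounded
half-even to two decimals.

Two exact mining routes are provided. `mine_frequent()` enumerates all
frequent itemsets depth-first with transaction-id intersection; it is meant
for small item universes and is verified against exhaustive subset
enumeration. `filter_closed_maximal()` then flags itemsets per the standard
definitions (maximal: no frequent superset; closed: no superset of equal
support). For corpus-scale data the transactions are *long* — a country
transaction holds hundreds of genes — and the frequent collection is
astronomically large while the closed collection stays small, so
`mine_maximal_closed()` enumerates closed itemsets directly as intersections
of transaction subsets. Because maximal itemsets are always closed, the
maximal flags computed within the closed collection equal those over the
full frequent collection; the two routes are cross-checked on random small
databases. The shipped pipeline default threshold is 40%, below all the
supports the desk-scale analyses print. Reported rankings order by
descending support, then smaller cardinality, then lexicographically,
because printed tables list tied supports without stating an order.

## Co-occurrence network

Edge weight between two genes is the number of abstracts mentioning both.
The analysis chain is: giant (largest) connected component, pruning of edges
with weight below 10 (the value used for the corpus-scale analysis; weight
10 itself survives) followed by removal of degree-0 nodes, then centralities
and communities. Betweenness and closeness are computed on the unweighted
skeleton and normalised to [0, 1]; closeness is the harmonic variant, which
stays well-defined on disconnected graphs. Community detection uses greedy
multilevel (Louvain) modularity on the *weighted* graph — co-occurrence
strength is the natural affinity — under a fixed seed, with labels relabelled
to a contiguous 0-based range. Stage summaries recompute node and edge
percentages from counts rather than copying any reported figure.

## Clustering

Countries are clustered by their gene-count rows with agglomerative
complete linkage; the default metric is cosine distance because row
magnitudes (publication volume) would otherwise dominate. Ties between
merge candidates are broken by the lexicographically smallest pair of
cluster signatures, so dendrograms are deterministic; the result coerces to
`hclust` and exports to Newick.

Genes are clustered with fuzzy c-means in the full feature space (per-year
or per-country counts); the 2-D PCA projection is for visualisation only.
Defaults: fuzzifier `m = 2`, tolerance `1e-5` on the centre shift, 300
iteration cap, initial centres sampled from the data under the given seed.
A point coincident with a centre takes full membership there (the limit
convention). Per candidate cluster count the four validity indices are
reported — PC, CE, PI (the partition / SC index) and XBI, with the formulas
stated in `?validity_indices`. Duplicate centres make XBI undefined and it
is reported as `NA`. Choosing the optimal count is *not* automated: PC and
CE are monotone in `c` and useful mainly for confirmation, so the package
reports the index table for inspection; the tests assert the behaviour that
motivates this (PI's largest relative drop and XBI's minimum at the planted
count on three-cluster synthetic data). The *fuzzy area* of a partition is
the set of entities whose largest membership is below `tau = 0.6`; no
standard quantitative definition exists, so the threshold is explicit and
configurable, and `crossmatch_itemsets()` reports, per mined itemset, the
fraction of its genes in that area.

# The synthetic corpus

`synthetic_spec()` / `generate_corpus()` produce a fully annotated corpus
whose statistical structure is known by construction, so that every pipeline
stage is testable without downloads. The reference conditions used across
the test suite are the defaults: 2,000 records; three gene communities of 15
genes with intra-block inclusion rate `p_in = 0.6` and inter-block rate
`p_out = 0.02`; eight countries, each with one preferred gene boosted with
probability 0.5 in that country's records; twenty publication years
(1995–2014) with one late-trending gene; one country per record with
probability 0.9, two with probability 0.1; and one three-gene itemset
planted into 80% of year transactions through genes that occur nowhere
else, so its support is exact. These sizes keep the full suite comfortably
desk-scale while leaving wide margins: intra-community co-occurrence
weights are an order of magnitude above the pruning threshold, and the
preference boost dominates the base inclusion rate, so recovery failures
indicate real defects rather than noise. When communities are disabled the
generator falls back to a 20-gene background pool with a truncated-Poisson
(mean 2, minimum 1) gene count per abstract — the sparse regime in which
planted itemsets are themselves maximal.

Affiliations are rendered as raw comma-delimited strings and re-parsed by
the resolver, and gene mentions are embedded in generated sentences and
re-found by the matcher: the generator exercises the real code paths, not
shortcuts around them. `expected_support()` gives the analytic transaction
support under the sampling model (inclusion-exclusion over items, per-record
miss probabilities conditioned on the community), cross-checked by Monte
Carlo in the suite.

What the generator does *not* emulate: the marginal scale of a real corpus
(thousands of genes, hundreds of thousands of abstracts), realistic synonym
ambiguity, misspelt or free-form affiliations, and any actual gene–disease
biology. Passing tests therefore demonstrate correctness of the machinery
and recoverability of planted structure, not fidelity of scientific claims
on real literature.

# Determinism and limitations

A single pipeline seed fans out to fixed per-stage offsets (community
detection, each fuzzy-clustering fit), so stages never share an RNG stream
and two runs with the same configuration produce byte-identical manifests;
the manifest deliberately records no timestamps. Known limitations: the
dictionary matcher does no acronym disambiguation beyond the case policy;
the resolver does no institution-level geocoding, so affiliations whose
country never appears as an alias or hint stay unresolved (a status, not an
error); and `mine_frequent()` on dense transaction data is intentionally
refused work that only the closed-itemset route can do at scale.
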