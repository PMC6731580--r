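---
title: "Composite annotation and discovery of biosimulation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite annotation and discovery of biosimulation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdisc)
```

## The problem

Repositories of biosimulation models hold hundreds of CellML files whose
variables carry names like `J_NHE3_Na` — meaningful to the model's author,
opaque to everyone else. A modeller looking for "a sodium flux across the
apical membrane of a proximal tubule cell" cannot find it by text search
alone. `semdisc` implements the machinery that makes such models
discoverable: composite semantic annotations on model variables, an RDF
triple index with graph-pattern querying, dictionary-based mapping of
free-text queries onto ontology terms, ranked retrieval of matching model
entities, and a recommender that proposes similar models from shared
anatomical location and protein sequence identity.

## The annotation model

A **composite annotation** describes one model entity (a variable or
component, addressed as `file#component.variable`) by combining terms from
several reference ontologies:

* a biophysical **property** (OPB — e.g. chemical flow, concentration);
  always present;
* a **chemical** species (ChEBI — sodium, hydrogen, glucose);
* anatomical **locations** (FMA). Process-type properties (fluxes) carry a
  *source* and a *sink* chain; state-type properties (concentrations) carry
  a *located-in* chain. Chains are ordered most specific first and are
  location context, not strict mereology — a basolateral flux's source
  chain `[cytosol, basolateral plasma membrane]` reads "from the cytosol,
  at the basolateral membrane";
* an optional protein **mediator** (PR / UniProt), plus free-text species
  and gene names as displayed to users.

Each annotation renders deterministically to text, e.g.

```{r}
render_description(example_nhe3_annotation())
```

The fragment of an entity URI is split at the *first* dot: CellML component
identifiers cannot contain a dot, while variable names occasionally do, so
`m.cellml#c.v.with.dots` parses as component `c`, variable `v.with.dots`.
Ontology terms are equal exactly when their IRIs are equal after trimming;
no case folding is applied, because ontology IRIs are case-sensitive. Term
prefixes (OPB/FMA/CHEBI/PR/...) are derived from a longest-stem-wins prefix
registry, with unknown stems classified `OTHER` rather than rejected.

## RDF encoding and the triple store

Annotations are exchanged as RDF. The predicate vocabulary (SemSim-style
relation names) lives in a single table
(`inst/extdata/vocabulary.tsv`), so a different annotation dialect is a
configuration change. Location chains become linked participant nodes:
the entity points at a blank node which `refersTo` the most specific term
and is `partOf` the next node. Term labels travel as `rdfs:label`
statements so a corpus round-trips with its vocabulary intact.

Serialization is canonical — IRI subjects sorted, predicates sorted within
subject, blank nodes renumbered by a structural walk — so writing the same
graph twice is byte-identical, which makes determinism testable. Both
Turtle and RDF/XML are read and written; annotations may live inside a
CellML file's `rdf:RDF` block (subjects resolved against the file name) or
in sibling documents, with siblings winning per entity on conflict.

The in-memory store answers conjunctive basic-graph-pattern queries by
ordered nested-loop join, most selective pattern first. Full SPARQL is
deliberately not parsed — the engine needs only BGP joins — but a thin
adapter renders pattern lists as SPARQL SELECT text for remote read-only
endpoints speaking the standard JSON protocol, and the local and remote
routes return identical solution sets on the same data. Literals compare
by lexical form with no numeric coercion.

## Query decomposition and ranking

A free-text query is lowercased, split on punctuation, stripped of a small
stopword list, and mapped onto ontology terms through a static key–value
dictionary with exact matching; multi-word keys are tried greedily longest
first. There is intentionally no fuzzy matching, spelling correction or
synonym expansion — mapping quality is a property of the dictionary, and
failures are reported as unmapped tokens rather than guessed at.

Matching then cascades: mapped terms are matched against the annotation
slots (property, chemical, location, mediator) through the corpus term
index, raw tokens are matched against model names, and surviving entities
are enriched with protein accession, species and gene. Enrichment never
filters: an entity without a protein annotation still appears.

The score of an entity is the sum of the weights of its matched slots,
with defaults

```{r}
default_weights()
```

The weights are configuration, not science: the only behaviour the method
fixes is ordinal — an entity matching both the property and the chemical of
"flux of sodium" (0.70) must outrank a chemical-only match such as a sodium
concentration (0.35), and a strict superset of matched slots must never
rank lower. Positivity of the weights guarantees that monotonicity by
construction, and scores depend only on the entity's own annotation, so
adding unrelated models can never reorder existing results. Ties break
deterministically: variable-level entities before component-level, then
model name, then entity URI.

## Sequence similarity and the recommender

Selecting an entity yields an overview card (anatomical location, rendered
biological meaning, species, gene, protein name with mediator tooltip)
assembled purely from the corpus annotations and the label cache — the
label cache resolves term IRIs locally first and only consults a
lookup-service resolver when one is explicitly attached, so nothing
touches the network by default.

Candidate similar models are annotated entities of *other* files whose
location chains intersect the selection's — sharing a membrane or
compartment. Because basolateral fluxes share more chain terms with each
other (cytosol, basolateral membrane, interstitial fluid) than with apical
ones (cytosol only), the two membrane populations separate in the ranking
without any special casing. One candidate is kept per model. Candidates
whose mediator protein has a retrievable sequence are ranked first by
percent identity to the selected protein; the rest follow by shared
location count. A failed sequence fetch degrades that candidate to
location-only with a warning instead of failing the recommendation.
`rank_score` is `identity/100` for sequence-ranked candidates and
`0.5 × shared/|selected locations|` otherwise; the constant is exposed
because only "more relevant nearer the top" is fixed by the method.

Percent identity follows the Clustal convention: identical columns divided
by columns where **both** sequences have a residue, rounded half-up to two
decimals. Alignment is Needleman–Wunsch global alignment with linear gap
penalty (via Biostrings). The default toy scoring is match +1, mismatch 0,
**gap −4**. The gap penalty is deliberately heavy relative to a mismatch:
with a near-zero gap cost the optimizer pads alignments of strongly
diverged substitution-only pairs with spurious gaps, which inflates
gap-excluded identity by several points at 20% identity and would make
planted divergences unrecoverable. With gap −4 such pairs align gap-free
and measured identity equals per-site identity (deviation 0 across 50
random 240-residue trials). For biologically calibrated alignment a
substitution matrix can be passed instead. An alternative remote route
submits all sequences to a Clustal-style multiple-alignment service and
parses its percent-identity matrix text; whether a service's matrix is
MSA-derived or pairwise is service-defined, so the two routes are kept
distinct rather than conflated.

## The synthetic corpus generator

Real annotated cohorts live in external repositories, so the package ships
a deterministic generator that emulates one: `corpus_spec()` defaults to
the "epithelial-mini" profile — 4 models, both membranes, a basolateral
sodium flux per model (the first mediated by a reference protein, the next
three by candidates planted at 90/50/20% identity), an apical flux of a
rotating second chemical, and cytosolic concentration variables; one CellML
file and one sibling Turtle document per model, a mediator FASTA, a
dictionary covering every label used, and a manifest listing every
annotated entity. All fixture ontology terms live in a reserved
`example.org` namespace so synthetic data can never be mistaken for real
OPB/FMA/ChEBI/PR identifiers.

Planted identities use exact-count substitution: exactly
`round(n·(1−identity/100))` positions are changed, each to a different
residue. A Bernoulli per-site model at the same rate would add sampling
noise of ≈2.6 identity points (sd) at 240 residues and 20% identity —
larger than the ±2 band within which the recommender tests require the
plant to be recovered — so the count is fixed and the realized identity
verified by direct position-wise comparison after generation. The entire
output tree is a pure function of the spec and seed (byte-identical
reruns).

What the generator does *not* emulate: real model mathematics (components
carry plausible variables but no MathML), annotation noise (every entity
is either cleanly annotated or cleanly unannotated), multi-file imports,
and the scale and heterogeneity of a curated repository cohort. Green
tests on this corpus therefore demonstrate the correctness of the engine's
mechanics — encoding, indexing, querying, ranking, recommending — not
retrieval quality on real curation.

## Numerical and testing choices

* Exact-identity checks (round trips, determinism) compare canonical
  serializations byte for byte; there is no floating-point tolerance
  anywhere in the RDF or ranking paths.
* Percent identities are rounded half-up to 2 decimals at the single point
  where they are reported; comparisons in the recommender use the rounded
  values.
* Property-style tests run at fixed problem sizes chosen to finish in
  minutes on one CPU: 100 generated corpora for the write/read/extract
  round trip; 50 random graphs of up to 200 triples with 3-pattern joins
  against a relational-join oracle (plus fully exhaustive row-combination
  enumeration on small graphs); alignment scores against exhaustive
  enumeration for every sequence pair up to length 3 over a 3-letter
  alphabet plus 200 seeded pairs at lengths 4–6.
* Degenerate inputs are first-class: empty query text, fully unmapped
  queries, empty stores, single-model corpora, missing sequences and
  label-less terms all have defined, tested behaviour (empty results,
  diagnostics, degradations or typed errors — never silent guesses).

## Limitations

Exact dictionary matching means vocabulary coverage bounds recall; the
mapper reports what it could not map but does not attempt repair. The BGP
engine supports conjunction only — no OPTIONAL/UNION/FILTER — which is
sufficient for the cascading slot queries but not for arbitrary SPARQL.
CellML 2.0 uses a different metadata mechanism and is rejected explicitly.
The recommender's evidence combination (sequence-ranked block before
location-only block) is one documented choice among defensible ones; both
ingredients are exposed separately in the results so downstream users can
re-rank.
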