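---
title: "Methods: curation rules, SBGN generation and topology in cftrmapkit"
author: "cftrmapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation rules, SBGN generation and topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrmapkit)
```

## Scope and model

`cftrmapkit` builds and analyses two-layer molecular interaction maps:
a manually curated **core layer** of mechanistic reactions drawn in
SBGN Process Description (PD), and a high-throughput **coarse layer**
of interactor lists drawn as SBGN Activity Flow (AF) submaps. The
package assumes the field's usual keying conventions: every molecular
entity is identified by its uppercased HUGO-approved gene symbol (ChEBI
names for small molecules), aliases are resolved only through an
explicit alias table, and identifier annotations (HGNC, UniProt, ChEBI,
PubChem CID, PMID) follow MIRIAM-style per-namespace syntax. Unknown
enumeration values in input tables are errors, never coerced: curated
data should fail loudly.

## The inclusion rule

An interactor is accepted into the core layer iff

* it has ≥ 2 `small_scale_experiment` records with `human_cells = TRUE`
  and **distinct PMIDs**, or
* it has ≥ 2 `review` records from **distinct research groups**.

"Independent references" is operationalized as distinct PMIDs for
experiments and distinct research-group keys for reviews; the choice of
key is the caller's, since independence of publications is not formally
decidable from the records themselves. `high_throughput` records are
stored but never counted; they mark coarse-layer candidates. Two
properties follow from the counting form of the rule and are enforced
by tests: adding evidence can never flip an accepted interactor to
rejected (monotonicity), and duplicate PMIDs never change a decision
(idempotence; duplicates by `(symbol, pmid)` are already collapsed on
load, since a PMID denotes one publication).

## Polarity provenance and the percentage denominator

Cell lines are classified by their *general ability to polarize*, not
by their state in a specific experiment (which the underlying records
rarely resolve). An interactor is `polarized` if any supporting record
names a polarizable line, `non_polarized_only` if it has cell-based
records but none polarizable, and `no_cell_evidence` otherwise (e.g.
review-only support).

`summarizeSubmaps()` reports, per submap, the percentage of interactors
identified in at least one polarized cell line. The denominator is a
genuinely open design point: entity kinds without cell-line provenance
(small molecules known from reviews, ions, gene elements) cannot be
classified either way. We define

```
polarized_fraction = 100 * n_polarized / (n_polarized + n_non_polarized_only)
```

i.e. the denominator is the set of interactors that carry cell-line
evidence at all. This is the only denominator under which the reported
integer percentages of the reference dataset (97/69/52/82/74 across the
five core submaps) are arithmetically reachable from its per-submap
composition, and it matches the question being asked ("of the
interactors whose provenance we know, how many were seen in polarized
cells?"). Percentages are rounded **half-up** to integers
(`floor(x + 0.5)`), the convention of integer percentage tables; R's
default `round()` is half-even, which resolves exact .5 cases by
parity (36.5 → 36 but 37.5 → 38) rather than consistently upward.

## PD core map generation

`buildCoreMap()` creates one glyph per (entity, localization)
occurrence; an entity present in several compartments receives one
glyph per compartment plus an SBGN clone marker (the source maps do not
state their convention; clone markers are SBGN's standard device for
duplicated entity pools). Species kinds map onto PD classes:
gene/RNA → *nucleic acid feature*; protein, truncated protein,
receptor, ion channel → *macromolecule*; simple molecule/ion →
*simple chemical*; complex → *complex*; degradation pool →
*source and sink*. Each reaction becomes a *process* glyph with
consumption/production arcs; regulations map to the PD arc classes
catalysis, inhibition, stimulation (physical stimulation) and
modulation. Reaction participants resolve to the participant's glyph in
the reaction's compartment (`SYMBOL@compartment` tokens override, for
transport steps); regulators attach from the regulator's first listed
compartment, since regulation is not compartment-qualified in the input
format. An unresolvable participant or a reaction in a compartment
missing from the layout is an error, not a silent skip.

Fill colors are a pure function of role: the focal protein
(symbol `focal` or `focal-*`) is blue (`#2B6CB0`), polarized
interactors green (`#8FBF8F`), non-polarized yellow (`#F2E394`),
degradation-associated red (`#E57373`), recycling-associated orange
(`#F2C879`), compartments grey (`#D9D9D9`). The sources specify color
*families* only; these concrete values are package defaults and fully
configurable through the `colorScheme` argument.

## AF coarse submaps

Each coarse submap abstracts one lifecycle step into a central state
transition: a focal input activity, a transition activity named after
the step, and a focal output activity, joined by positive influences.
Every interactor becomes one *biological activity* glyph with exactly
one influence arc, routed onto the **input (gene) node** when any of
its functional categories is gene-directed (`dna_replication`,
`dna_repair`, `chromatin` — a generalization of the reference map's
two-way split in its Transcription submap) and onto the **transition**
otherwise. Because AF has no process nodes, the transition is itself a
biological activity; the three abstraction glyphs have fixed ids
(`cftr_input`, `cftr_transition`, `cftr_output`) so
`interactorGlyphCount()` can count interactor glyphs unambiguously.
Influence arcs default to *unknown influence* — the nature of
high-throughput interactions is unreported — with *positive influence*
available via `influenceClass`.

## Layout and serialization

`layoutMap()` is deterministic by construction: within each
compartment, glyphs are sorted by (class, label, id) and placed on an
integer grid (`columns` per row, default 5; cells 130 × 70 units;
entity glyphs 100 × 40, process glyphs 24 × 24). Compartments take the
width of the grid, grow vertically to hold their glyphs (they never
overflow; an empty compartment keeps one cell row), and are stacked
bottom-to-top in the order nucleus → ER → Golgi → cytoplasm → plasma
membrane → extracellular space, mirroring the focal protein's journey
upward through the cell. All coordinates are integers, so SBGN-ML
serialization is byte-identical for identical input and configuration —
the property the round-trip and determinism tests assert. The target
format is SBGN-ML 0.2 (language `"process description"` or
`"activity flow"`), with fill colors carried in a
`renderInformation` extension whose styles list member glyph ids, the
convention SBGN editors use for styling. No attempt is made to
reproduce hand-drawn editor coordinates; the layout is a readable,
reproducible grid, not aesthetics.

## Layer integration

Both layers are keyed by gene symbol after alias resolution (not by
UniProt accession), because both input lists are gene lists. Overlap is
plain set arithmetic after uppercasing and deduplication, hence
invariant to input order and duplicates; deduplication keeps shared
symbols in the core layer only and is idempotent. `consistencyReport()`
cross-checks the arithmetic that must hold between the tables: coarse
category counts sum to the deduplicated coarse size, species-kind
counts sum to the entity total, and claimed (externally printed) counts
match the observed ones.

## Network topology

The PPI network is a weighted, undirected, simple graph: edge weight is
the number of distinct supporting interaction records, PMIDs are
unioned, self-loops are rejected. Betweenness is exact (Brandes, via
igraph) and normalized by `(n-1)(n-2)/2`; shortest paths are unweighted
by default — the provenance counts in the edge weights say how often an
interaction was observed, not how "short" it is — with `weighted = TRUE`
switching to `1/weight` distances. Hub ranking breaks degree ties
lexicographically, so it is fully deterministic. Louvain community
detection pins its internal randomness with an explicit seed and
reports modularity (resolution 1 by default). Nodes named in the input
but absent from the edge list are kept as isolates and reported, never
silently dropped.

### Power-law plausibility

`fitDegreePowerLaw()` fits a discrete power law by maximum likelihood
with the lower cut-off `x_min` chosen by KS-distance minimization
(igraph's `plfit`). The *plausibility* verdict is deliberately stricter
than "KS < 0.1": with a free `x_min`, the far tail of a light-tailed
(Poisson) degree distribution can also achieve a small KS distance —
but only with a diverging exponent and a sliver of the data. A degree
distribution is reported as plausibly scale-free iff the fit succeeded,
KS < `ksMax` (default 0.1), the exponent is in `(1, alphaMax]`
(default 5; empirical scale-free networks cluster around 2–3), and the
fitted tail holds ≥ `minTail` observations (default 10). All four
bounds are arguments. Degenerate input (all degrees equal) yields a
fit-failure result rather than an exception; fewer than 10 positive
degrees violate the fit's precondition and raise an error.

## Over-representation analysis

The enrichment module is a transparent stand-in for proprietary
semantic-network prioritization tools, which publish no algorithm to
reimplement: per term, the hypergeometric upper tail
P(X ≥ k | N, K, n), Benjamini–Hochberg adjustment across all tested
terms, and ranks strictly ordered by (adjusted p, term id) so results
are reproducible to the byte. The universe defaults to the union of all
genes in the loaded annotation and is overridable — enrichment is
meaningless without an explicit universe choice, so the default is
conservative and visible. Top-k comparisons between two ranked lists
are plain set arithmetic; any published "k of top 20 shared" figure
from a proprietary ranker is database-version- and
algorithm-dependent, so such comparisons are validated on constructed
rankings, not reproduced from live annotation releases.

## The synthetic generator and the packaged fixture

`generateDataset()` emulates the *shape* of curated disease-map data:
per-submap interactor counts with exact polarized counts
(`round(n * polarizedFraction)`, half-up), evidence that satisfies or
violates the inclusion rule in controlled proportions (`reviewOnly`
members carry two reviews and no cell line; `nRejected` candidates get
a single record), a coarse layer with a prescribed overlap, interaction
graphs from three standard models (preferential attachment,
Erdős–Rényi, planted partition), and GMT annotations. All randomness
flows from one explicit seed; identical spec + seed give byte-identical
files. Its defaults are the study conditions of the reference dataset
(submap sizes 33/45/27/44/23, polarized fractions 32/33, 31/45, 14/27,
36/44, 17/23; coarse 1384 with 46 shared).

`packagedCftrFixture()` is the fully specified reference dataset: 262
core entities (149 proteins incl. subtypes, 58 complexes, 28 simple
molecules, 13 ions, 6 genes, 5 RNAs, 3 pools), 170 evidenced
interactors citing 221 distinct publications, 156 reactions in 6 main
compartments, a coarse layer of 1384 (46 shared; category counts
7/10/36/57/1/3/653/22/38/145/12/32/62/10/250 summing to 1338 after
deduplication), and a 145-node / 326-edge interaction network realized
deterministically (Havel–Hakimi) from a degree sequence with maximum
degree 38 at CFTR, the named hubs next (HSP90AA1, STUB1, UBE2I, NR3C1,
VCP), exactly 30 degree-1 and 10 degree-6 nodes. One interactor protein
is deliberately absent from the edge list to exercise isolate
reporting.

What the fixture does **not** emulate: member-level identities (symbols
beyond the named hubs are generated), the true wiring of the published
network (only its degree facts), per-submap species-kind compositions
where the printed per-submap counts are not jointly satisfiable with
the map-wide census (the census takes precedence), and real GO/Reactome
term structure. Tests passing on this fixture therefore demonstrate
correctness of the *computations* on data of realistic shape — not
biological conclusions about CFTR.

## Problem sizes and determinism in the test suite

The suite exercises betweenness against an exhaustive all-pairs oracle
on random graphs of up to 40 nodes, ORA p-values against full
combinatorial enumeration on universes of up to 15 genes, and
power-law plausibility on preferential-attachment versus Erdős–Rényi
graphs of 2000 nodes across 20 seeds — sizes chosen so each oracle is
feasible by brute force while still covering non-trivial structure.
Every stochastic test fixes its seed.

## Known limitations

* The inclusion rule trusts the evidence table's `human_cells` and
  `research_group` fields; it cannot detect mislabeled provenance.
* Whether a cultured cell line was actually polarized under specific
  experimental conditions is out of scope; the flag encodes the line's
  general ability to polarize.
* The AF routing rule is category-based; interactors annotated only
  with categories outside the submap are skipped (with a warning)
  rather than guessed.
* The layout optimizes reproducibility, not edge-crossing aesthetics.
* `fitDegreePowerLaw()` assesses plausibility, not proof of
  scale-freeness; formal model comparison (e.g. against log-normal
  alternatives) is not implemented.
* Live database queries (BioGRID, GeneMania, UniProt, Human Protein
  Atlas) are out of scope; the toolkit consumes pre-resolved offline
  tables.
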