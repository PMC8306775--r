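# cftrmapkit

Evidence-curated multi-layer interactome maps in SBGN, with network
topology and enrichment analysis.

## The problem

Disease-map projects such as the CFTR (cystic fibrosis transmembrane
conductance regulator) lifecycle interactome combine two very different
kinds of knowledge. A **core layer** is manually curated from
small-scale experiments: few interactors, but each reaction is known
mechanistically and can be drawn in the SBGN Process Description (PD)
dialect. A **coarse layer** comes from high-throughput
co-immunoprecipitation screens: more than a thousand interactors, but
nothing is known beyond "it interacts", so each lifecycle step is
abstracted into a single state transition and drawn in the SBGN
Activity Flow (AF) dialect. `cftrmapkit` implements the full workflow
for building, integrating and analysing such two-layer maps, for
curators and systems biologists who want the pipeline reproducible and
testable rather than hand-drawn.

## What the package computes

* **Inclusion rule.** An interactor enters the core layer iff it was
  identified in ≥ 2 small-scale experiments in human cells from
  independent references (distinct PMIDs), or acknowledged in ≥ 2
  reviews from different research groups. High-throughput records
  never count (`passesInclusionRule()`, `curateInteractors()`).
* **Polarity provenance.** Each interactor is flagged by whether any
  supporting cell line has the general ability to polarize
  (`polarityStatus()`); per-submap polarized percentages are reported
  over the cell-evidenced interactors (`summarizeSubmaps()`).
* **Map generation.** `buildCoreMap()` emits a PD map (one glyph per
  entity–compartment occurrence, one process per reaction, regulation
  arcs for catalysis/inhibition/stimulation/modulation);
  `buildCoarseSubmap()` emits AF submaps with a central CFTR-in →
  transition → CFTR-out abstraction and one influence arc per
  interactor. `layoutMap()` assigns deterministic grid coordinates
  (compartments stacked nucleus → plasma membrane, mirroring the
  protein's journey); `writeSbgnMl()`/`readSbgnMl()` round-trip
  SBGN-ML 0.2 byte-identically.
* **Layer integration.** `computeOverlap()` and `dedupCoarse()` keep
  shared interactors in the core layer only; `consistencyReport()`
  checks the cross-table arithmetic.
* **Network topology.** `buildNetwork()` builds the weighted undirected
  PPI graph (edge weight = number of supporting records). Degree
  statistics, discrete maximum-likelihood power-law fits with
  KS-selected x_min (`fitDegreePowerLaw()`), exact normalized
  betweenness (`betweennessTable()`), hub ranking (`topHubs()`) and
  seeded Louvain communities (`detectCommunities()`).
* **Enrichment.** Hypergeometric over-representation analysis of GMT
  gene sets with Benjamini–Hochberg correction (`ora()`), and top-k
  comparison of two ranked term lists (`compareTopTerms()`). For a
  query of size *n* drawn from a universe of size *N*, a term with *K*
  members and overlap *k* is scored by P(X ≥ k), X ~
  Hypergeometric(N, K, n).
* **Synthetic data.** `generateDataset()` writes deterministic
  six-file dataset bundles (interactors, evidence, reactions, coarse
  list, edges, GMT); `packagedCftrFixture()` ships a CFTR-shaped
  reference dataset (see below). `runCli()` / `inst/scripts/cftrmapkit.R`
  expose the whole pipeline as `simulate` / `curate` / `build-map` /
  `integrate` / `topology` / `enrich` subcommands.

## Worked example

```r
library(cftrmapkit)

fx <- packagedCftrFixture()
entityCensus(fx$dataset, layer = "core", groupProteins = TRUE)$counts
#>         protein            gene             rna         complex simple_molecule
#>             149               6               5              58              28
#>             ion   degraded_pool
#>              13               3

computeOverlap(fx$coreInteractors, fx$coarseInteractors)
#> Layer overlap: core-only 124 | shared 46 | coarse-only 1338

summarizeSubmaps(fx$dataset)[, c("submap", "n_interactors", "polarized_fraction")]
#>                  submap n_interactors polarized_fraction
#> 1     secretory_pathway            27                 52
#> 2   activity_regulation            44                 82
#> 3 endocytosis_recycling            23                 74
#> 4    er_quality_control            45                 69
#> 5         transcription            33                 97

round(averageDegree(fx$network), 2)
#> [1] 4.5
topHubs(fx$network, 6)
#>       node degree
#> 1     CFTR     38
#> 2 HSP90AA1     22
#> 3    STUB1     20
#> 4    UBE2I     18
#> 5    NR3C1     16
#> 6      VCP     14
fitDegreePowerLaw(fx$network)
#> Power-law fit: alpha=3.058 xmin=5 KS=0.0472 n_tail=52 plausible=TRUE
```

The census says the core map holds 262 molecular entities of which 170
(entities with literature evidence, excluding the focal protein's own
species) are interactors; after deduplication the coarse layer keeps
1338 of its 1384 interactors. The PPI network over the core proteins
has 145 nodes and 326 edges (mean 4.5 neighbors), a plausibly
scale-free degree distribution, and CFTR as its strongest hub.

Building and serializing a coarse submap:

```r
tr <- fx$coarseTable[fx$coarseTable$submap == "transcription", ]
m <- layoutMap(buildCoarseSubmap("transcription",
       data.frame(symbol = tr$symbol,
                  functional_categories = tr$functional_category)))
interactorGlyphCount(m)
#> [1] 17
writeSbgnMl(m, "transcription.sbgn")
```

## A note on the packaged fixture

The packaged dataset is synthetic: it reproduces the published
aggregate counts (entity census, interactor totals, layer overlap,
per-submap polarized percentages, coarse category counts, and the
network's degree facts) but not the member-level identities, which are
generated symbols except for the named hub proteins (CFTR, HSP90AA1,
STUB1, UBE2I, NR3C1, VCP, SLC9A3R1, ANO1), placed according to their
described roles. See the methods vignette (`vignettes/methods.Rmd`)
for the modelling choices and their rationale.
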