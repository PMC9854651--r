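---
title: "Methods: disease-gene and PPI network analysis for pigmentation disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-gene and PPI network analysis for pigmentation disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentnet)
```

`pigmentnet` models the gene-to-phenotype and protein-interaction structure
of skin pigmentation disorders. This vignette records the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic tests demonstrate.

## The diseasome model

Curated gene–disease associations form a bipartite graph: gene nodes on one
side, disease/phenotype nodes on the other, one link per curated
association. Three modelling commitments shape everything downstream:

* **Disease identity is the exact (trimmed) curated name.** Disease
  subtypes with distinct names are distinct nodes; no fuzzy matching is
  attempted, because subtype-level resolution is exactly what makes the
  disease panel fine-grained.
* **Symbols are upper-cased and matched to an official catalog**; anything
  unmatched is removed during `curate()`. Duplicate (gene, disease) pairs
  collapse to one association that remembers every contributing source.
  When sources disagree on a phenotype class the manual-review source
  outranks the curated-appendix source, which outranks the database pull —
  a precedence we chose because the review classification is the primary
  scheme; the conflict is always warned about.
* **One class per gene.** A gene linked only to hyperpigmentation diseases
  is HYPER (likewise HYPO, MIXED, PHENOTYPE); a gene whose diseases span
  two or more classes is MULTIPLE rather than multi-labeled. Single labels
  keep cluster composition tables and edge-category counts well-defined.

Upset counts over a disease subset assign each covered gene to the exact
subset of those diseases it links to; the patterns are exclusive by
construction, so they partition the covered genes — a property the test
suite checks by brute-force enumeration of membership vectors.

## Confidence filtering and the seed network

Interaction confidence scores live in [0, 1] (a 0–1000 integer dialect is
divided by 1000 on ingest). The seed network keeps edges with score ≥ τ,
τ = 0.700 by default, **inclusive**, matching the "minimum required score"
semantics of STRING-style exports. Nodes are the endpoints of surviving
edges; seed proteins left with no interaction are excluded from the node
count but reported as unconnected, so the "connected fraction" is the
integer percentage (half-up rounding) of seeds that made it into the
network. Filtering is monotone in τ — raising the threshold can only shrink
the network — and the suite asserts this as a property.

## Markov clustering

MCL is implemented from scratch, since the clustering is part of the
method rather than plumbing. The transition matrix weights adjacency by
edge score and adds one self-loop per node before column normalization;
the default self-loop weight is the node's maximum incident edge weight
(isolated nodes get 1), a common choice that damps the odd/even
oscillations of pure random-walk powers. A constant-1 policy is available.

Each iteration applies expansion (matrix squaring; the expansion power is
fixed at 2, the standard choice), inflation (entrywise power r, columns
renormalized), then pruning: entries below 1e-5 are zeroed and columns
renormalized. Iteration stops when the largest absolute entry change falls
below 1e-6 or after 200 iterations, in which case the result carries a
convergence warning rather than an error. These tolerances are standard MCL
practice at the few-hundred-node scale this package targets; dense base-R
matrices are entirely adequate there, so no sparse machinery is used.

Clusters are read from the limit matrix as the supports of attractor rows
(nodes with positive diagonal mass, ε = 1e-7); overlapping supports are
merged, and any node outside every support follows the attractor holding
most of its column mass. Merging guarantees a partition — every node in
exactly one cluster — which the suite verifies on random graphs, alongside
equivalence with an independent numpy reference implementation on all
small-graph fixtures and exact recovery of planted stochastic-block
modules (4 blocks of 10, within-block edge probability 0.9, between 0.02).
Inflation (default 2.5) controls granularity; cluster counts are
non-decreasing in inflation on planted graphs, and clusters are numbered
strictly by decreasing size. Published MCL variants sometimes number
clusters differently (e.g. by discovery order), so identical partitions can
carry different labels; all comparisons here are label-free.

## Over-representation statistics

Functional profiling uses a three-level annotation in which every gene has
exactly one class per level; the coarsest level is a fixed 15-name
vocabulary including "Unknown", which is also where unannotated genes land.
Enrichment of a query set is the upper-tail hypergeometric probability
P(X ≥ k) of drawing k or more term genes in n draws from an N-gene
universe — computed with `stats::phyper`, and checked in the tests against
exhaustive combinatorial enumeration for every N ≤ 12 case. The universe
defaults to all annotated genes and is configurable, since enrichment
conclusions are known to be background-sensitive. Multiple testing uses
Benjamini–Hochberg step-up adjustment (`stats::p.adjust`), validated
against the literal step-up definition, with significance at adjusted
p ≤ 0.05. A 1000-replicate null simulation in the acceptance suite confirms
the significant fraction stays at the nominal level. Ranked gene-set
methods are deliberately out of scope: the analyses here are unranked set
overlaps.

## Greedy network expansion

Interactive databases expand a network by repeatedly pulling in the "next
best" outside protein; the exact ranking those interfaces use is not
published, so this package defines it explicitly: the candidate with the
greatest **summed score** of above-threshold edges to current members wins,
with ties broken by more edges and then lexically smaller symbol. A plain
edge-count criterion is available as an option. After each addition, all
above-threshold background edges among members enter the network, and
expansion stops at the first state whose edge count exceeds the target
(default 2000 realized edges; an "expected edges" statistic is a different,
database-internal quantity this package does not model). If the background
runs out first, the maximal network is returned with a warning. The greedy
rule is deterministic, and the suite checks the added-node sequence against
a from-scratch re-ranking oracle at every step.

## LFQ overlay

Detection is "quantified (intensity > 0) in at least 2 of 3 replicates" —
triplicates are the study convention, the majority rule is ours and
configurable (published detection counts may correspond to any-replicate
presence; both rules are one argument away). Per-line protein abundance is
the mean over quantified replicates; fold change is the larger mean over
the smaller (≥ 1 by construction) with a direction field, and a protein is
differential only when the fold strictly exceeds 2. No replicate-level test
statistic is applied — the differential call is a pure fold-change rule,
matching how such overlays are typically reported. Proteins detected in
one line only are flagged exclusive and excluded from ratio calls rather
than given pseudo-counts. Log transforms use base 10 and leave undetected
proteins missing — a missing attribute is honest where a fabricated zero
(or −∞) is not.

## The synthetic study system

The generators emulate the scale of a curated pigmentation panel, and their
defaults are the package's study conditions:

* 174 diseases apportioned **exactly** (largest remainder) to class
  proportions 73/55/40/6; per-disease gene counts of 1 + Poisson(0.6), so
  the expected association count is ≈ 278 over ≈ 240 genes; gene reuse at
  0.12 within-class and 0.03 cross-class, chosen once to give the ~13%
  association-to-gene redundancy such panels show.
* PPI edges from a stochastic block model whose score bands straddle the
  0.700 threshold (within-module U(0.70, 0.999), between-module
  U(0.15, 0.699)), so threshold filtering exactly recovers the planted
  blocks and the boundary is always exercised; a background interactome
  attaches extra proteins with ~10 high-confidence partners each for
  expansion, emulating the edge density of a several-hundred-node expanded
  map. The `"pigmentation-scale"` preset uses 16 modules of 10, so about
  two-thirds of seed genes are connected, plus a 210-protein background and
  a ~3900-protein expressed background proteome so whole-proteome detection
  counts land in the low thousands.
* LFQ intensities are log-normal (median 1e7) with multiplicative replicate
  noise exp(N(0, σ)), σ = 0.1 by default; planted differential proteins
  (10, fold 3, second line higher) are always expressed so the planted
  signal is recoverable by design; measurements drop out with probability
  0.05.

Every generator is a pure function of its spec and seed — identical specs
give byte-identical files — and emitted files pass the package's own
readers warning-free.

What passing these tests shows — and does not. Recovery of planted modules
at ARI 1.0 shows the MCL implementation is correct on well-separated
community structure; real interactomes have overlapping pathways, hubs and
score noise that no block model reproduces, so real cluster counts will be
messier. Planted fold changes at σ = 0.1 validate the calling rule, not the
biology of expression differences; real LFQ data carry batch structure and
intensity-dependent missingness that the uniform dropout model ignores.
Synthetic class mixtures validate counting and partition logic, not the
curation judgments that produce real association tables.

## Problem sizes and degenerate inputs

The suite and the acceptance script run at the scales above (≈ 160-node
clustering, ≈ 2000-edge expansion, ≈ 4300-protein expression tables),
chosen as representative of the real system while keeping a full run in
seconds. Degenerate inputs are first-class: empty networks export valid
documents, an edgeless graph clusters into singletons, empty gene lists
profile to empty tables, empty queries warn rather than fail, and every
configuration error (thresholds outside [0, 1], inflation ≤ 1, impossible
replicate minima, infeasible generator specs) is raised with a typed
condition naming the offending field.

## Known limitations

* SIF carries topology only; scores and labels round-trip through GraphML
  and the node-attribute CSV, and the SIF reader accepts score/attribute
  side tables to compensate.
* The expansion criterion is an explicit interpretation of an unpublished
  interactive ranking; identical edge counts against other tools are not
  guaranteed, which is why the criterion and target are parameters.
* MCL cluster *labels* (not memberships) can differ from other
  implementations' numbering conventions.
* The pipeline ingests processed LFQ tables; raw spectra, peptide search
  and protein inference are out of scope, as are live database queries —
  all inputs are files.
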