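# pigmentnet

Network analysis of skin-pigmentation disease genes and their protein–protein
interactions, for researchers who work with curated disease–gene catalogs,
STRING-style scored interaction tables, and label-free quantification (LFQ)
proteomics.

Disorders of melanin production — hyperpigmentation, hypopigmentation, mixed
forms, and benign pigmentation phenotypes — involve hundreds of genes whose
products act together in pathways (melanosome biogenesis, Ras–MAPK signaling,
DNA repair, immune destruction of melanocytes). `pigmentnet` turns curated
gene–disease association tables into a bipartite **diseasome**, builds
confidence-filtered **PPI networks** among the disease proteins, clusters them,
profiles their functions, expands the network against a background
interactome, and overlays protein-abundance measurements from melanoma cell
lines — all with seeded synthetic generators so every stage is testable
without any database downloads.

## What it computes

- **Curation**: gene symbols matched to an official catalog, duplicate
  (gene, disease) associations merged with source tracking; diseases
  partitioned into the four phenotype classes (HYPER / HYPO / MIXED /
  PHENOTYPE); each gene labeled with its unique class, or MULTIPLE when its
  diseases span classes. Exclusive gene-overlap ("upset") counts across any
  disease subset.
- **PPI network**: induced subnetwork among seed proteins keeping edges with
  combined confidence score ≥ τ (default τ = 0.700, inclusive); connectivity
  reported as the integer percentage of seeds that survive.
- **Markov clustering (MCL)**, implemented from scratch: with the
  column-stochastic transition matrix M built from score-weighted adjacency
  (self-loop = max incident weight), iterate

      M ← prune( normalize( (M²)^{∘ r} ) ),   r = inflation (default 2.5)

  until convergence; clusters are the supports of attractor rows, merged into
  a partition. Verified against an independent reference implementation.
- **Over-representation analysis**: upper-tail hypergeometric
  P(X ≥ k) for a query of n genes overlapping a K-gene term in an N-gene
  universe, with Benjamini–Hochberg FDR across terms (α = 0.05), plus
  three-level functional class profiles.
- **Expansion**: greedy growth against a background interactome — repeatedly
  add the outside protein with the greatest summed edge score to current
  members (ties: more edges, then lexical) until the realized edge count
  exceeds the target (default 2000) — then count edges per unordered pair of
  protein classes.
- **LFQ overlay**: detection (quantified in ≥ 2 of 3 replicates), coverage
  percentages against gene lists, fold changes as max(mean)/min(mean) with a
  strict > 2-fold differential call, and log₁₀ LFQ node attributes exported
  to GraphML/CSV for Cytoscape.

## Worked example

```r
library(pigmentnet)

spec  <- synthetic_preset("pigmentation-scale", rng_seed = 1)
paths <- simulate_inputs(spec, "sim")
cur   <- curate(read_association_table(paths$associations),
                read_gene_catalog(paths$catalog))
classify_diseases(cur)
#>     HYPER      HYPO     MIXED PHENOTYPE
#>        73        55        40         6

gc  <- assign_gene_classes(cur)
net <- induced_subnetwork(read_scored_edges(paths$edges), unique(cur$gene),
                          threshold = 0.700, classes = gc)
net
#> ppi_network: 160 nodes, 638 edges (score >= 0.700)
#>   classes: HYPER=75, HYPO=41, MIXED=38, MULTIPLE=4, PHENOTYPE=2
#>   unconnected seeds: 76

connectivity_summary(net, unique(cur$gene))$connected_fraction
#> [1] 68

mcl(net, inflation = 2.5)
#> mcl_clusters: 16 cluster(s) over 160 node(s), inflation 2.50 (converged in 12 iterations)
#>   sizes: 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10 ...
```

174 synthetic diseases fall into the four phenotype classes exactly as
configured; 160 of the 236 curated genes (68%) carry at least one
high-confidence interaction; MCL at inflation 2.5 recovers the sixteen
planted ten-protein modules exactly. `run_pipeline()` chains all seven
stages and writes a manifest plus all summary tables into one run directory.

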