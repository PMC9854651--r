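# seeded synthetic-data generators with planted structure
#
# The generators emulate the five input kinds of the pipeline at the scale of
# a published pigmentation disease-gene curation effort: 174 disease entries
# in class proportions 73/55/40/6, roughly 278 associations over roughly 243
# genes (per-disease gene counts 1 + Poisson(0.6), modest gene sharing),
# a modular high-confidence PPI core with score bands straddling the 0.700
# threshold, a denser background interactome for expansion, a three-level
# functional annotation with GMT term sets, and triplicate two-cell-line LFQ
# tables with planted fold changes.

#' Specification for the synthetic-data generators
#'
#' All distributions are stated, seeded defaults; every field can be
#' overridden. Probabilities must lie in \[0, 1\] and the class mixture must
#' sum to 1. The seed is mandatory: every generator is a pure function of
#' (spec, seed).
#'
#' @param n_genes Gene-catalog size (pool for associations).
#' @param n_diseases Number of synthetic diseases/phenotypes.
#' @param class_mixture Named proportions over `HYPER`, `HYPO`, `MIXED`,
#'   `PHENOTYPE`; disease class counts hit the mixture exactly (largest
#'   remainder apportionment).
#' @param assoc_lambda Per-disease gene count is 1 + Poisson(`assoc_lambda`).
#' @param share_within Probability an association reuses a gene already
#'   linked to a disease of the same class.
#' @param share_between Probability it reuses a gene from another class.
#' @param n_modules,module_size Planted PPI modules (stochastic blocks).
#' @param p_in,p_out Within/between-module edge probabilities.
#' @param score_in,score_out Uniform score bands for within-module
#'   (above-threshold) and between-module (below-threshold) edges.
#' @param background_size Extra background-interactome proteins.
#' @param background_attach Mean high-confidence partners per background
#'   protein.
#' @param n_planted_differential Proteins planted with a fold change.
#' @param planted_fold Planted fold change (applied in the second cell line).
#' @param noise_sigma Multiplicative log-normal replicate noise (sdlog).
#' @param dropout Per-measurement dropout probability (intensity zeroed).
#' @param expressed_fraction Fraction of the supplied proteins expressed at
#'   all in the cell lines (planted proteins are always expressed).
#' @param proteome_extra Additional expressed background-proteome proteins
#'   appended to expression tables (emulating whole-proteome LFQ output).
#' @param cell_lines Two cell-line identifiers.
#' @param rng_seed Mandatory integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 300,
                           n_diseases = 174,
                           class_mixture = c(HYPER = 73, HYPO = 55,
                                             MIXED = 40, PHENOTYPE = 6) / 174,
                           assoc_lambda = 0.6,
                           share_within = 0.12,
                           share_between = 0.03,
                           n_modules = 4,
                           module_size = 10,
                           p_in = 0.9,
                           p_out = 0.02,
                           score_in = c(0.70, 0.999),
                           score_out = c(0.15, 0.699),
                           background_size = 150,
                           background_attach = 10,
                           n_planted_differential = 10,
                           planted_fold = 3,
                           noise_sigma = 0.1,
                           dropout = 0.05,
                           expressed_fraction = 0.35,
                           proteome_extra = 0,
                           cell_lines = c("A375", "FM55"),
                           rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed) || is.na(rng_seed)) {
    pn_stop("rng_seed is mandatory for synthetic generation",
            "pigmentnet_config_error")
  }
  spec <- as.list(environment())
  spec$rng_seed <- as.integer(rng_seed)
  probs <- c(spec$share_within, spec$share_between, spec$p_in, spec$p_out,
             spec$dropout, spec$expressed_fraction, spec$class_mixture)
  if (any(probs < 0) || any(probs > 1)) {
    pn_stop("all probabilities must lie in [0, 1]", "pigmentnet_config_error")
  }
  if (abs(sum(spec$class_mixture) - 1) > 1e-8) {
    pn_stop("class_mixture must sum to 1", "pigmentnet_config_error")
  }
  if (!all(names(spec$class_mixture) %in% PHENOTYPE_CLASSES)) {
    pn_stop("class_mixture names must be HYPER/HYPO/MIXED/PHENOTYPE",
            "pigmentnet_config_error")
  }
  if (spec$share_within + spec$share_between > 1) {
    pn_stop("share_within + share_between must not exceed 1",
            "pigmentnet_config_error")
  }
  structure(spec, class = "synthetic_spec")
}

# run `expr` under a deterministic seed without disturbing the caller's RNG
with_spec_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(expr)
}

# exact apportionment of n items to proportions (largest remainder)
apportion <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic gene-disease association table
#'
#' Diseases are apportioned to the four phenotype classes exactly per the
#' mixture; each disease draws 1 + Poisson(lambda) genes, reusing an
#' already-linked gene of the same class with probability `share_within`, of
#' another class with `share_between`, and otherwise consuming a fresh
#' catalog gene.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `associations` (`association_table`), `catalog`
#'   (`gene_catalog`), `truth` (disease class map, per-disease gene sets).
#' @export
gen_associations <- function(spec) {
  with_spec_seed(spec$rng_seed, 0L, {
    pool <- sprintf("GENE%04d", seq_len(spec$n_genes))
    counts <- apportion(spec$class_mixture, spec$n_diseases)
    classes <- rep(names(spec$class_mixture), counts)
    diseases <- sprintf("Synthetic disorder %03d", seq_len(spec$n_diseases))

    used_by_class <- setNames(vector("list", length(PHENOTYPE_CLASSES)),
                              PHENOTYPE_CLASSES)
    next_free <- 1L
    rows_gene <- character(); rows_dis <- character(); rows_cls <- character()
    for (i in seq_len(spec$n_diseases)) {
      cls <- classes[i]
      n_d <- 1L + rpois(1, spec$assoc_lambda)
      genes_i <- character()
      for (k in seq_len(n_d)) {
        u <- runif(1)
        same <- setdiff(used_by_class[[cls]], genes_i)
        other <- setdiff(unlist(used_by_class[setdiff(PHENOTYPE_CLASSES, cls)]),
                         genes_i)
        g <- if (u < spec$share_within && length(same)) {
          same[sample.int(length(same), 1)]
        } else if (u < spec$share_within + spec$share_between && length(other)) {
          other[sample.int(length(other), 1)]
        } else {
          if (next_free > length(pool)) {
            pn_stop("gene pool exhausted: spec requests more associations than genes",
                    "pigmentnet_config_error")
          }
          gg <- pool[next_free]
          next_free <- next_free + 1L
          gg
        }
        genes_i <- c(genes_i, g)
      }
      genes_i <- unique(genes_i)
      used_by_class[[cls]] <- union(used_by_class[[cls]], genes_i)
      rows_gene <- c(rows_gene, genes_i)
      rows_dis <- c(rows_dis, rep(diseases[i], length(genes_i)))
      rows_cls <- c(rows_cls, rep(cls, length(genes_i)))
    }
    source <- sample(ASSOCIATION_SOURCES, length(rows_gene), replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    tab <- association_table(rows_gene, rows_dis, rows_cls, source)
    truth <- list(
      disease_classes = setNames(classes, diseases),
      disease_genes = split(tab$gene, tab$disease),
      class_counts = setNames(counts, names(spec$class_mixture))
    )
    list(associations = tab, catalog = gene_catalog(pool), truth = truth)
  })
}

#' Generate a synthetic scored PPI edge table with planted modules
#'
#' Stochastic block structure over the first `n_modules * module_size` of the
#' supplied genes: within-module edges appear with probability `p_in` and
#' scores above the 0.700 threshold, between-module edges with `p_out` and
#' scores below it (so threshold filtering exactly recovers the blocks).
#' `background_size` extra proteins attach with high-confidence edges for
#' expansion tests.
#'
#' @param spec A `synthetic_spec`.
#' @param genes A `gene_catalog` or character vector of gene symbols.
#' @return List: `edges` (`scored_edge_table`), `truth` (module membership,
#'   background proteins).
#' @export
gen_ppi <- function(spec, genes) {
  if (inherits(genes, "gene_catalog")) genes <- genes$symbols
  genes <- unique(canonical_symbol(genes))
  if (spec$n_modules < 1) {
    pn_stop("n_modules must be >= 1", "pigmentnet_config_error")
  }
  n_mod_genes <- spec$n_modules * spec$module_size
  if (length(genes) < n_mod_genes) {
    pn_stop(sprintf("need at least %d genes for %d modules of %d",
                    n_mod_genes, spec$n_modules, spec$module_size),
            "pigmentnet_config_error")
  }
  with_spec_seed(spec$rng_seed, 1L, {
    # modules sample uniformly from the gene list, so planted blocks cut
    # across whatever ordering (and class correlation) the list carries
    members <- genes[sample.int(length(genes), n_mod_genes)]
    module <- rep(seq_len(spec$n_modules), each = spec$module_size)
    names(module) <- members

    pairs <- utils::combn(members, 2)
    a <- pairs[1, ]; b <- pairs[2, ]
    same <- module[a] == module[b]
    keep_in <- same & runif(length(a)) < spec$p_in
    keep_out <- !same & runif(length(a)) < spec$p_out
    ea <- c(a[keep_in], a[keep_out])
    eb <- c(b[keep_in], b[keep_out])
    sc <- c(runif(sum(keep_in), spec$score_in[1], spec$score_in[2]),
            runif(sum(keep_out), spec$score_out[1], spec$score_out[2]))

    background <- character()
    if (spec$background_size > 0) {
      background <- sprintf("BGP%04d", seq_len(spec$background_size))
      existing <- members
      for (bp in background) {
        k <- min(1L + rpois(1, max(spec$background_attach - 1, 0)),
                 length(existing))
        partners <- existing[sample.int(length(existing), k)]
        ea <- c(ea, rep(bp, k)); eb <- c(eb, partners)
        sc <- c(sc, runif(k, spec$score_in[1], spec$score_in[2]))
        # sub-threshold noise edges keep the 0.700 boundary exercised
        j <- rpois(1, 1)
        if (j > 0) {
          partners2 <- existing[sample.int(length(existing), min(j, length(existing)))]
          ea <- c(ea, rep(bp, length(partners2))); eb <- c(eb, partners2)
          sc <- c(sc, runif(length(partners2), spec$score_out[1], spec$score_out[2]))
        }
        existing <- c(existing, bp)
      }
    }
    list(edges = scored_edge_table(ea, eb, sc),
         truth = list(module_membership = module, background = background))
  })
}

#' Generate a synthetic three-level functional annotation and GMT term sets
#'
#' Every supplied gene gets exactly one class per level (level 3 drawn from
#' the fixed 15-name vocabulary with realistic, uneven weights); term sets
#' include one term per planted module (when `modules` is given) plus random
#' terms tagged MF/BP/WP/HP.
#'
#' @param spec A `synthetic_spec`.
#' @param genes Character vector (the annotation universe).
#' @param modules Optional named module membership (as from [gen_ppi()]'s
#'   truth) to plant module-matching terms.
#' @return List: `annotation` (`functional_annotation`), `terms` (named list
#'   of gene sets), `truth` (planted term-to-module map).
#' @export
gen_annotation <- function(spec, genes, modules = NULL) {
  genes <- unique(canonical_symbol(genes))
  with_spec_seed(spec$rng_seed, 2L, {
    l3_pool <- functional_level3_classes()
    w <- c(8, 5, 4, 4, 3, 2, 3, 2, 2, 3, 1, 1, 1, 2, 1)
    l3 <- sample(l3_pool, length(genes), replace = TRUE, prob = w / sum(w))
    l2 <- paste0(l3, " / group ", sample.int(4, length(genes), replace = TRUE))
    l1 <- paste0(l3, " / class ", sample.int(22, length(genes), replace = TRUE))
    ann <- data.frame(gene = genes, class_l1 = l1, class_l2 = l2, class_l3 = l3,
                      stringsAsFactors = FALSE)
    class(ann) <- c("functional_annotation", "data.frame")

    terms <- list()
    planted <- character()
    if (!is.null(modules)) {
      for (m in sort(unique(modules))) {
        mem <- names(modules)[modules == m]
        extra <- sample(setdiff(genes, mem), min(3, length(setdiff(genes, mem))))
        id <- sprintf("BP:PLANTED_MODULE_%02d", m)
        terms[[id]] <- sort(c(mem, extra))
        planted[id] <- m
      }
    }
    src <- c("MF", "BP", "WP", "HP")
    for (i in seq_len(20)) {
      sz <- sample(10:40, 1)
      id <- sprintf("%s:RANDOM_%02d", src[(i - 1) %% 4 + 1], i)
      terms[[id]] <- sort(sample(genes, min(sz, length(genes))))
    }
    attr(terms, "description") <- names(terms)
    list(annotation = ann, terms = terms,
         truth = list(planted_terms = planted))
  })
}

#' Generate a synthetic two-cell-line triplicate LFQ expression table
#'
#' Per-protein base intensities are log-normal; replicate intensities carry
#' multiplicative log-normal noise exp(N(0, sigma)); planted proteins are
#' multiplied by `planted_fold` in the second cell line; measurements drop
#' out (zero) with probability `dropout`. A fraction of the supplied proteins
#' is unexpressed entirely (all zeros), emulating partial proteome coverage;
#' planted proteins are always expressed so the planted signal is
#' recoverable.
#'
#' @param spec A `synthetic_spec`.
#' @param proteins Character vector of proteins of interest.
#' @return List: `expression` (`expression_table`), `truth` (planted
#'   differential proteins, expressed set).
#' @export
gen_expression <- function(spec, proteins) {
  proteins <- unique(canonical_symbol(proteins))
  if (spec$n_planted_differential > length(proteins)) {
    pn_stop("n_planted_differential exceeds the number of proteins",
            "pigmentnet_config_error")
  }
  with_spec_seed(spec$rng_seed, 3L, {
    planted <- sort(proteins[sample.int(length(proteins),
                                        spec$n_planted_differential)])
    expressed <- proteins[runif(length(proteins)) < spec$expressed_fraction]
    expressed <- union(expressed, planted)
    extras <- if (spec$proteome_extra > 0) {
      sprintf("PROT%05d", seq_len(spec$proteome_extra))
    } else character()
    all_prot <- c(sort(proteins), extras)
    is_expressed <- all_prot %in% expressed | all_prot %in% extras

    base <- rlnorm(length(all_prot), meanlog = log(1e7), sdlog = 1)
    rows <- vector("list", 2L * 3L)
    idx <- 0L
    for (li in 1:2) {
      line <- spec$cell_lines[li]
      fold <- ifelse(li == 2L & all_prot %in% planted, spec$planted_fold, 1)
      for (r in 1:3) {
        noise <- exp(rnorm(length(all_prot), 0, spec$noise_sigma))
        inten <- base * fold * noise * is_expressed
        drop <- runif(length(all_prot)) < spec$dropout
        inten[drop] <- 0
        idx <- idx + 1L
        rows[[idx]] <- data.frame(protein = all_prot, cell_line = line,
                                  replicate = r, intensity = inten,
                                  stringsAsFactors = FALSE)
      }
    }
    long <- do.call(rbind, rows)
    list(expression = expression_table(long$protein, long$cell_line,
                                       long$replicate, long$intensity),
         truth = list(planted_differential = planted,
                      expressed = sort(expressed),
                      higher_line = spec$cell_lines[2]))
  })
}

#' Named synthetic presets
#'
#' `"default"` returns [synthetic_spec()] defaults. `"pigmentation-scale"`
#' scales the generators to the size of the curated pigmentation study
#' system: 174 diseases (73/55/40/6 across classes), ~278 associations over
#' ~243 genes, a modular PPI core covering about 70% of the seed proteins
#' (16 modules of 10), a ~210-protein background interactome dense enough to
#' expand past 2000 edges (~10 high-confidence partners each, emulating the
#' ~4700-edge, 452-node expanded map), and a ~3900-protein expressed
#' background proteome so whole-proteome detection counts land in the low
#' thousands.
#'
#' @param name Preset name.
#' @param rng_seed Mandatory integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_preset <- function(name = c("default", "pigmentation-scale"),
                             rng_seed) {
  name <- match.arg(name)
  switch(name,
    "default" = synthetic_spec(rng_seed = rng_seed),
    "pigmentation-scale" = synthetic_spec(
      n_genes = 300, n_diseases = 174,
      n_modules = 16, module_size = 10,
      background_size = 210, background_attach = 10,
      proteome_extra = 3900, expressed_fraction = 0.35,
      rng_seed = rng_seed)
  )
}

#' Write a complete synthetic input set to a directory
#'
#' Emits all five pipeline input kinds (association TSV, gene-catalog TSV,
#' scored-edge TSV, annotation TSV + GMT, expression TSV) plus a ground-truth
#' JSON, all derived deterministically from the spec.
#'
#' @param spec A `synthetic_spec`.
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths plus the `truth` list, invisibly.
#' @export
simulate_inputs <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  assoc <- gen_associations(spec)
  genes <- sort(unique(assoc$associations$gene))
  ppi <- gen_ppi(spec, genes)
  ann <- gen_annotation(spec,
                        c(assoc$catalog$symbols, ppi$truth$background),
                        modules = ppi$truth$module_membership)
  expr <- gen_expression(spec, c(genes, ppi$truth$background))

  paths <- list(
    associations = file.path(outdir, "associations.tsv"),
    catalog = file.path(outdir, "catalog.tsv"),
    edges = file.path(outdir, "ppi_edges.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    gmt = file.path(outdir, "terms.gmt"),
    expression = file.path(outdir, "expression.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json")
  )
  df <- as.data.frame(assoc$associations)
  names(df) <- c("gene", "disease", "class", "source", "omim_note")
  write_tsv(df, paths$associations)
  write_tsv(data.frame(symbol = assoc$catalog$symbols), paths$catalog)
  ed <- as.data.frame(ppi$edges)
  names(ed) <- c("protein_a", "protein_b", "combined_score")
  write_tsv(ed, paths$edges)
  write_functional_annotation(ann$annotation, paths$annotation)
  write_gmt(ann$terms, paths$gmt)
  write_expression_table(expr$expression, paths$expression)

  truth <- list(
    disease_classes = as.list(assoc$truth$disease_classes),
    class_counts = as.list(assoc$truth$class_counts),
    module_membership = as.list(ppi$truth$module_membership),
    background = ppi$truth$background,
    planted_terms = as.list(ann$truth$planted_terms),
    planted_differential = expr$truth$planted_differential,
    higher_line = expr$truth$higher_line
  )
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}
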