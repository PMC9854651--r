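# end-to-end pipeline with run manifest

PIPELINE_STAGES <- c("curate", "diseasome", "ppi", "cluster", "enrich",
                     "expand", "overlay")

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — curation, diseasome summaries,
#' confidence-filtered PPI network, MCL clustering, functional profiling and
#' over-representation, network expansion, LFQ overlay — writing plain-file
#' outputs (TSV/CSV/SIF/GraphML) under `outdir` and a JSON run manifest
#' recording the configuration, input digests and per-stage outputs. Any
#' stage failure halts the run with a stage-named error. The pipeline itself
#' is deterministic: identical inputs and config give byte-identical summary
#' tables.
#'
#' @param config A `pigmentnet_config`.
#' @param inputs Named list of input paths: `associations`, `catalog`,
#'   `edges`, `annotation`, `gmt`, `expression` (e.g. from
#'   [simulate_inputs()]).
#' @param outdir Run directory (created if needed).
#' @param skip Character vector of stage names to skip (downstream stages
#'   that need a skipped stage are skipped too, marked in the manifest).
#' @param cell_lines The two cell-line identifiers for the overlay stage.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, inputs, outdir, skip = character(),
                         cell_lines = c("A375", "FM55")) {
  stopifnot(inherits(config, "pigmentnet_config"))
  required <- c("associations", "catalog", "edges", "annotation", "gmt",
                "expression")
  missing_in <- setdiff(required, names(inputs))
  if (length(missing_in)) {
    pn_stop(sprintf("missing input(s): %s (provide --%s)",
                    paste(missing_in, collapse = ", "), missing_in[1]),
            "pigmentnet_config_error")
  }
  for (nm in required) stopifnot_file(inputs[[nm]])
  bad_skip <- setdiff(skip, PIPELINE_STAGES)
  if (length(bad_skip)) {
    pn_stop(sprintf("unknown stage(s) in skip: %s",
                    paste(bad_skip, collapse = ", ")),
            "pigmentnet_config_error")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    tool = "pigmentnet",
    version = as.character(packageVersion("pigmentnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = lapply(inputs[required], function(p) {
      list(path = p, md5 = unname(md5sum(p)))
    }),
    stages = list()
  )

  state <- new.env(parent = emptyenv())
  stage_ok <- function(name) {
    identical(manifest$stages[[name]]$status, "ok")
  }
  run_stage <- function(name, fun, deps = character()) {
    if (name %in% skip || !all(vapply(deps, stage_ok, TRUE))) {
      manifest$stages[[name]] <<- list(status = "skipped", outputs = list())
      return(invisible(NULL))
    }
    outputs <- tryCatch(fun(), error = function(e) {
      pn_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "pigmentnet_stage_error")
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     outputs = as.list(outputs))
  }

  run_stage("curate", fun = function() {
    raw <- read_association_table(inputs$associations)
    catalog <- read_gene_catalog(inputs$catalog)
    curated <- curate(raw, catalog)
    state$curated <- curated
    p1 <- file.path(outdir, "curated.tsv")
    write_association_table(curated, p1)
    p2 <- file.path(outdir, "curation_summary.tsv")
    write_tsv(data.frame(
      n_associations = attr(curated, "n_associations"),
      n_genes = attr(curated, "n_genes"),
      n_diseases = attr(curated, "n_diseases"),
      n_unmatched_removed = attr(curated, "n_unmatched")), p2)
    c(curated = p1, summary = p2)
  })

  run_stage("diseasome", deps = "curate", fun = function() {
    curated <- state$curated
    dis <- build_diseasome(curated)
    state$diseasome <- dis
    state$gene_classes <- assign_gene_classes(curated)
    cls <- classify_diseases(curated)
    p1 <- file.path(outdir, "disease_class_counts.tsv")
    write_tsv(data.frame(phenotype_class = names(cls),
                         n_diseases = as.integer(cls)), p1)
    p2 <- file.path(outdir, "gene_classes.tsv")
    write_tsv(state$gene_classes, p2)
    p3 <- file.path(outdir, "diseasome_links.tsv")
    write_tsv(dis$links, p3)
    # upset over the diseases with the most genes (ties by name)
    deg <- sort(table(dis$links$disease), decreasing = TRUE)
    top <- names(deg)[order(-as.integer(deg), names(deg))][seq_len(min(6, length(deg)))]
    p4 <- file.path(outdir, "upset_counts.tsv")
    write_tsv(upset_counts(dis, top), p4)
    c(class_counts = p1, gene_classes = p2, links = p3, upset = p4)
  })

  run_stage("ppi", deps = c("curate", "diseasome"), fun = function() {
    edges <- read_scored_edges(inputs$edges)
    state$edges <- edges
    seeds <- unique(state$curated$gene)
    state$seeds <- seeds
    net <- induced_subnetwork(edges, seeds,
                              threshold = config$score_threshold,
                              classes = state$gene_classes)
    state$network <- net
    conn <- connectivity_summary(net, seeds)
    files <- write_network(net,
                           sif = file.path(outdir, "ppi_network.sif"),
                           graphml = file.path(outdir, "ppi_network.graphml"),
                           node_attrs = file.path(outdir, "ppi_nodes.csv"))
    p <- file.path(outdir, "connectivity.tsv")
    write_tsv(data.frame(n_seeds = conn$n_seeds,
                         n_connected = conn$n_connected,
                         connected_fraction_pct = conn$connected_fraction,
                         n_components = length(conn$components),
                         largest_component = if (length(conn$components))
                           conn$components[1] else 0L), p)
    c(files, connectivity = p)
  })

  run_stage("cluster", deps = "ppi", fun = function() {
    cl <- mcl(state$network, inflation = config$mcl_inflation)
    state$clusters <- cl
    p1 <- file.path(outdir, "clusters.tsv")
    write_tsv(data.frame(node = names(cl$membership),
                         cluster = unname(cl$membership)), p1)
    p2 <- file.path(outdir, "cluster_summary.tsv")
    write_tsv(cluster_summary(cl, state$gene_classes), p2)
    c(assignments = p1, summary = p2)
  })

  run_stage("enrich", deps = c("diseasome", "cluster"), fun = function() {
    ann <- read_functional_annotation(inputs$annotation)
    terms <- read_gmt(inputs$gmt)
    gc <- state$gene_classes
    hyper <- gc$gene[gc$network_class == "HYPER"]
    hypo <- gc$gene[gc$network_class == "HYPO"]
    prof <- rbind(
      cbind(set = "exclusive_hyper", class_profile(hyper, ann, level = 3)),
      cbind(set = "exclusive_hypo", class_profile(hypo, ann, level = 3)))
    p1 <- file.path(outdir, "class_profile_l3.tsv")
    write_tsv(prof, p1)
    universe <- ann$gene
    query <- intersect(state$clusters$clusters[[1]], universe)
    ora <- hypergeometric_ora(query, terms, universe,
                              alpha = config$fdr_alpha)
    p2 <- file.path(outdir, "ora_largest_cluster.tsv")
    write_tsv(ora, p2)
    c(class_profile = p1, ora = p2)
  })

  run_stage("expand", deps = "ppi", fun = function() {
    exp_net <- expand_network(state$network, state$edges,
                              threshold = config$score_threshold,
                              edge_target = config$expansion_edge_target,
                              classes = state$gene_classes)
    state$expanded <- exp_net
    files <- write_network(exp_net,
                           graphml = file.path(outdir, "expanded.graphml"),
                           node_attrs = file.path(outdir, "expanded_nodes.csv"))
    p <- file.path(outdir, "edge_categories.tsv")
    write_tsv(categorize_edges(exp_net), p)
    c(files, edge_categories = p)
  })

  run_stage("overlay", deps = "ppi", fun = function() {
    expr <- read_expression_table(inputs$expression)
    det <- detect(expr)
    net <- state$expanded %||% state$network
    cov <- data.frame(
      cell_line = rep(names(det), each = 2),
      reference = rep(c("seed_proteins", "network_nodes"), length(det)),
      coverage_pct = unlist(lapply(det, function(d) {
        c(coverage(d, state$seeds), coverage(d, net$nodes$symbol))
      })),
      n_detected = rep(lengths(det), each = 2))
    p1 <- file.path(outdir, "coverage.tsv")
    write_tsv(cov, p1)
    fc <- fold_changes(expr, cell_lines[1], cell_lines[2],
                       threshold = config$fold_change_threshold)
    p2 <- file.path(outdir, "differential.tsv")
    write_tsv(fc[fc$differential, , drop = FALSE], p2)
    overlay <- attach_to_network(net, fc)
    files <- write_network(overlay$network,
                           graphml = file.path(outdir, "overlay.graphml"),
                           node_attrs = file.path(outdir, "overlay_nodes.csv"),
                           extra_node_attrs = overlay$node_attrs)
    c(coverage = p1, differential = p2, files)
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
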