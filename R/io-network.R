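# network export/import: SIF, GraphML, node-attribute CSV

#' Write a network to interchange formats
#'
#' Exports any subset of: SIF (`A pp B` lines, the Cytoscape simple
#' interaction format; scores are not representable in SIF itself), GraphML
#' (full fidelity: scores and node attributes travel with the file), and a
#' node-attribute CSV (one row per node). Paths left `NULL` are skipped.
#'
#' @param network A `ppi_network`.
#' @param sif,graphml,node_attrs Output file paths or `NULL`.
#' @param extra_node_attrs Optional data frame keyed by `symbol` with
#'   additional per-node columns (e.g. LFQ overlay attributes) merged into
#'   the CSV and GraphML exports.
#' @return Named character vector of the files written, invisibly.
#' @export
write_network <- function(network, sif = NULL, graphml = NULL,
                          node_attrs = NULL, extra_node_attrs = NULL) {
  stopifnot(inherits(network, "ppi_network"))
  written <- character()

  nodes <- network$nodes
  if (!is.null(extra_node_attrs)) {
    stopifnot(is.data.frame(extra_node_attrs), "symbol" %in% names(extra_node_attrs))
    nodes <- merge(nodes, extra_node_attrs, by = "symbol", all.x = TRUE,
                   sort = FALSE)
    nodes <- nodes[match(network$nodes$symbol, nodes$symbol), , drop = FALSE]
    rownames(nodes) <- NULL
  }

  if (!is.null(sif)) {
    lines <- if (nrow(network$edges)) {
      paste(network$edges$protein_a, "pp", network$edges$protein_b)
    } else character()
    # degree-0 nodes appear as bare names so the node set survives round-trip
    deg0 <- setdiff(nodes$symbol,
                    c(network$edges$protein_a, network$edges$protein_b))
    con <- file(sif, open = "wt", encoding = "UTF-8")
    writeLines(c(lines, deg0), con)
    close(con)
    written["sif"] <- sif
  }

  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = network$edges$protein_a,
                     to = network$edges$protein_b,
                     score = network$edges$score,
                     stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = nodes
    )
    igraph::write_graph(g, graphml, format = "graphml")
    written["graphml"] <- graphml
  }

  if (!is.null(node_attrs)) {
    write.csv(nodes, node_attrs, row.names = FALSE, quote = FALSE)
    written["node_attrs"] <- node_attrs
  }
  invisible(written)
}

#' Read a network from GraphML
#'
#' Inverse of the GraphML branch of [write_network()]: node set, edge set,
#' scores and class/provenance attributes are restored.
#'
#' @param path GraphML file written by [write_network()].
#' @return A `ppi_network`.
#' @export
read_network_graphml <- function(path) {
  stopifnot_file(path)
  g <- igraph::read_graph(path, format = "graphml")
  vattr <- igraph::vertex_attr(g)
  nodes <- data.frame(symbol = vattr$name, stringsAsFactors = FALSE)
  nodes$network_class <- vattr$network_class %||% rep("NONE", nrow(nodes))
  nodes$provenance <- vattr$provenance %||% rep("SEED", nrow(nodes))
  el <- igraph::as_edgelist(g, names = TRUE)
  score <- igraph::edge_attr(g, "score") %||% rep(NA_real_, nrow(el))
  edges <- scored_edge_table(el[, 1], el[, 2], score)
  ppi_network(nodes, edges)
}

#' Read a network from SIF (plus optional attribute side files)
#'
#' SIF carries topology only; provide `node_attrs` (the CSV written by
#' [write_network()]) and/or an `edge_scores` table to restore labels and
#' scores.
#'
#' @param path SIF file.
#' @param node_attrs Optional node-attribute CSV path.
#' @param edge_scores Optional `scored_edge_table` supplying scores.
#' @return A `ppi_network` (scores default to 1 when unavailable).
#' @export
read_network_sif <- function(path, node_attrs = NULL, edge_scores = NULL) {
  stopifnot_file(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  a <- character(); b <- character(); solo <- character()
  for (p in parts) {
    if (length(p) >= 3) {
      # "source interaction target1 [target2 ...]"
      targets <- p[3:length(p)]
      a <- c(a, rep(p[1], length(targets)))
      b <- c(b, targets)
    } else if (length(p) == 1) {
      solo <- c(solo, p[1])
    }
  }
  score <- rep(1, length(a))
  edges <- scored_edge_table(a, b, score)
  if (!is.null(edge_scores)) {
    key <- paste(edges$protein_a, edges$protein_b)
    skey <- paste(edge_scores$protein_a, edge_scores$protein_b)
    hit <- match(key, skey)
    edges$score[!is.na(hit)] <- edge_scores$score[hit[!is.na(hit)]]
  }
  nodes <- data.frame(symbol = unique(c(edges$protein_a, edges$protein_b, solo)),
                      stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    at <- read.csv(node_attrs, stringsAsFactors = FALSE)
    nodes <- merge(nodes, at, by = "symbol", all.x = TRUE, sort = FALSE)
    nodes$network_class[is.na(nodes$network_class)] <- "NONE"
    nodes$provenance[is.na(nodes$provenance)] <- "SEED"
  }
  ppi_network(nodes, edges)
}

#' Read a node-attribute CSV written by [write_network()]
#' @param path CSV path.
#' @return Data frame with one row per node.
#' @export
read_node_attributes <- function(path) {
  stopifnot_file(path)
  read.csv(path, stringsAsFactors = FALSE)
}
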