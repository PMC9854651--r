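# labeled PPI network container

NETWORK_CLASSES <- c("HYPER", "HYPO", "MIXED", "PHENOTYPE", "MULTIPLE", "NONE")

#' Construct a labeled PPI network
#'
#' A PPI network is an undirected, self-loop-free graph whose nodes carry a
#' pigmentation network class (`HYPER`, `HYPO`, `MIXED`, `PHENOTYPE`,
#' `MULTIPLE`, or `NONE` for proteins not linked to pigmentation disorders)
#' and a provenance flag (`SEED` for the original disease proteins, `ADDED`
#' for proteins pulled in by expansion), and whose edges carry confidence
#' scores.
#'
#' @param nodes Data frame with columns `symbol`, `network_class`,
#'   `provenance` (missing class/provenance filled with `NONE`/`SEED`).
#' @param edges A `scored_edge_table` (or data frame coercible to one); every
#'   endpoint must appear in `nodes`.
#' @param threshold The confidence threshold the edge set satisfies, if any.
#' @param unconnected Seed symbols that had no surviving interaction and are
#'   therefore not nodes of the network, kept for reporting.
#' @return A `ppi_network` object.
#' @export
ppi_network <- function(nodes, edges, threshold = NA_real_,
                        unconnected = character()) {
  if (is.character(nodes)) {
    nodes <- data.frame(symbol = nodes, stringsAsFactors = FALSE)
  }
  nodes$symbol <- canonical_symbol(nodes$symbol)
  if (anyDuplicated(nodes$symbol)) {
    pn_stop("duplicate node symbols in network", "pigmentnet_format_error")
  }
  if (is.null(nodes$network_class)) {
    nodes$network_class <- rep("NONE", nrow(nodes))
  }
  if (is.null(nodes$provenance)) nodes$provenance <- rep("SEED", nrow(nodes))
  nodes <- nodes[, c("symbol", "network_class", "provenance")]
  rownames(nodes) <- NULL

  if (!inherits(edges, "scored_edge_table")) {
    edges <- scored_edge_table(edges$protein_a, edges$protein_b, edges$score)
  }
  stray <- setdiff(c(edges$protein_a, edges$protein_b), nodes$symbol)
  if (length(stray)) {
    pn_stop(sprintf("edge endpoints missing from node table: %s",
                    paste(utils::head(stray, 5), collapse = ", ")),
            "pigmentnet_format_error")
  }
  structure(list(nodes = nodes, edges = edges,
                 threshold = as.numeric(threshold),
                 unconnected = canonical_symbol(unconnected)),
            class = "ppi_network")
}

#' Convert a PPI network to an igraph graph
#' @param network A `ppi_network`.
#' @return An undirected `igraph` graph with `score` edge attribute and
#'   `network_class` / `provenance` vertex attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$protein_a,
                   to = network$edges$protein_b,
                   score = network$edges$score,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$symbol,
                          network_class = network$nodes$network_class,
                          provenance = network$nodes$provenance,
                          stringsAsFactors = FALSE)
  )
}

#' Number of nodes and edges of a network
#' @param network A `ppi_network`.
#' @return Named integer vector with elements `nodes` and `edges`.
#' @export
network_size <- function(network) {
  c(nodes = nrow(network$nodes), edges = nrow(network$edges))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges", nrow(x$nodes), nrow(x$edges)))
  if (!is.na(x$threshold)) cat(sprintf(" (score >= %.3f)", x$threshold))
  cat("\n")
  tb <- table(x$nodes$network_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  if (length(x$unconnected)) {
    cat(sprintf("  unconnected seeds: %d\n", length(x$unconnected)))
  }
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) {
  g <- as_igraph(object)
  comp <- igraph::components(g)
  out <- list(
    nodes = nrow(object$nodes),
    edges = nrow(object$edges),
    components = sort(comp$csize, decreasing = TRUE),
    classes = table(object$nodes$network_class),
    unconnected_seeds = length(object$unconnected)
  )
  class(out) <- "summary.ppi_network"
  out
}

#' @export
print.summary.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges, %d component(s)\n",
              x$nodes, x$edges, length(x$components)))
  cat("  component sizes:", paste(utils::head(x$components, 10), collapse = ", "),
      if (length(x$components) > 10) "..." else "", "\n")
  cat("  unconnected seeds:", x$unconnected_seeds, "\n")
  invisible(x)
}

#' @export
plot.ppi_network <- function(x, ...) {
  g <- as_igraph(x)
  pal <- c(HYPER = "firebrick", HYPO = "steelblue", MIXED = "darkgreen",
           PHENOTYPE = "purple", MULTIPLE = "orange", NONE = "grey70")
  igraph::plot.igraph(
    g,
    vertex.color = pal[igraph::V(g)$network_class],
    vertex.size = 6, vertex.label.cex = 0.6,
    edge.width = 2 * igraph::E(g)$score, ...)
  invisible(x)
}
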