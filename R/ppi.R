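# confidence-filtered seed networks, connectivity, greedy expansion,
# and edge categorization by protein class

#' Induced high-confidence subnetwork among seed proteins
#'
#' Keeps edges whose combined score is at or above the threshold (inclusive,
#' matching STRING's "minimum required interaction score") and whose two
#' endpoints are both seed proteins. Network nodes are the endpoints of the
#' surviving edges; seeds left without any interaction are excluded from the
#' node set but reported in the `unconnected` field.
#'
#' @param edges A `scored_edge_table`.
#' @param seeds Character vector of seed protein symbols.
#' @param threshold Confidence threshold in \[0, 1\] (default 0.700).
#' @param classes Optional gene-class assignment (data frame `gene`,
#'   `network_class`, as from [assign_gene_classes()]) used to label nodes;
#'   unlisted nodes get class `NONE`.
#' @return A `ppi_network`.
#' @export
induced_subnetwork <- function(edges, seeds, threshold = 0.700,
                               classes = NULL) {
  if (!length(seeds)) {
    pn_stop("seed list must be non-empty", "pigmentnet_config_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    pn_stop("threshold must lie in [0, 1]", "pigmentnet_config_error")
  }
  seeds <- unique(canonical_symbol(seeds))
  ed <- as.data.frame(edges)
  keep <- ed$score >= threshold & ed$protein_a %in% seeds &
    ed$protein_b %in% seeds
  ed <- ed[keep, , drop = FALSE]
  members <- sort(unique(c(ed$protein_a, ed$protein_b)))
  nodes <- data.frame(symbol = members, stringsAsFactors = FALSE)
  nodes$network_class <- lookup_classes(members, classes)
  nodes$provenance <- rep("SEED", length(members))
  ppi_network(nodes, scored_edge_table(ed$protein_a, ed$protein_b, ed$score),
              threshold = threshold,
              unconnected = setdiff(seeds, members))
}

lookup_classes <- function(symbols, classes) {
  if (is.null(classes)) return(rep("NONE", length(symbols)))
  hit <- match(symbols, canonical_symbol(classes$gene))
  out <- classes$network_class[hit]
  out[is.na(out)] <- "NONE"
  out
}

#' Connectivity of the seed proteins in the network
#'
#' Reports the percentage of the seed proteins that survive into the network
#' (integer percent, half-up rounding) and the connected-component sizes.
#'
#' @param network A `ppi_network` built from `seeds`.
#' @param seeds The seed symbols the network was induced from.
#' @return List with `connected_fraction` (integer percent), `n_connected`,
#'   `n_seeds`, and `components` (sizes, decreasing).
#' @export
connectivity_summary <- function(network, seeds) {
  if (!length(seeds)) {
    pn_stop("seed list must be non-empty", "pigmentnet_config_error")
  }
  seeds <- unique(canonical_symbol(seeds))
  n_nodes <- nrow(network$nodes)
  comp <- if (n_nodes) {
    sort(igraph::components(as_igraph(network))$csize, decreasing = TRUE)
  } else integer()
  list(
    connected_fraction = as.integer(round_half_up(100 * n_nodes / length(seeds))),
    n_connected = n_nodes,
    n_seeds = length(seeds),
    components = as.integer(comp)
  )
}

# all above-threshold edges of `pool` with both endpoints in `members`,
# merged with `base` keeping max score on collisions
edges_among <- function(pool, members, base = NULL) {
  keep <- pool$protein_a %in% members & pool$protein_b %in% members
  ed <- pool[keep, c("protein_a", "protein_b", "score"), drop = FALSE]
  if (!is.null(base) && nrow(base)) {
    ed <- rbind(ed, as.data.frame(base)[, c("protein_a", "protein_b", "score")])
  }
  scored_edge_table(ed$protein_a, ed$protein_b, ed$score)
}

#' Greedily expand a seed network against a background interactome
#'
#' Repeatedly adds the non-member protein with the greatest summed score of
#' above-threshold edges to the current members (ties broken by more edges,
#' then lexically smaller symbol). After each addition, all above-threshold
#' background edges among members enter the network. Expansion stops at the
#' first state whose edge count exceeds `edge_target`; if the background is
#' exhausted first, the maximal network is returned with a warning. The
#' greedy criterion is configurable to plain edge count via
#' `criterion = "count"`.
#'
#' @param seed_network A `ppi_network` (its threshold is reused unless
#'   `threshold` is given).
#' @param background A `scored_edge_table` of the background interactome.
#' @param threshold Confidence threshold applied to background edges.
#' @param edge_target Stop once the network holds more edges than this.
#' @param classes Optional class assignment for newly added proteins.
#' @param criterion `"score"` (summed edge score, default) or `"count"`.
#' @return A `ppi_network` with added nodes flagged `ADDED`.
#' @export
expand_network <- function(seed_network, background,
                           threshold = seed_network$threshold,
                           edge_target = 2000, classes = NULL,
                           criterion = c("score", "count")) {
  criterion <- match.arg(criterion)
  if (is.na(threshold)) {
    pn_stop("an explicit threshold is required when the seed network has none",
            "pigmentnet_config_error")
  }
  bg <- as.data.frame(background)
  bg <- bg[bg$score >= threshold, , drop = FALSE]

  members <- seed_network$nodes$symbol
  added <- character()
  edges <- edges_among(bg, members, base = seed_network$edges)

  while (nrow(edges) <= edge_target) {
    touch_a <- bg$protein_a %in% members
    touch_b <- bg$protein_b %in% members
    frontier <- touch_a != touch_b  # exactly one endpoint inside
    if (!any(frontier)) {
      warning("background interactome exhausted before reaching edge target",
              call. = FALSE)
      break
    }
    cand <- ifelse(touch_a[frontier], bg$protein_b[frontier],
                   bg$protein_a[frontier])
    sums <- tapply(bg$score[frontier], cand, sum)
    cnts <- tapply(bg$score[frontier], cand, length)
    key <- if (criterion == "score") sums else as.numeric(cnts)
    best <- names(key)[order(-key, -as.numeric(cnts[names(key)]), names(key))][1]
    members <- c(members, best)
    added <- c(added, best)
    edges <- edges_among(bg, members, base = seed_network$edges)
  }

  nodes <- rbind(
    seed_network$nodes,
    data.frame(symbol = added,
               network_class = lookup_classes(added, classes),
               provenance = rep("ADDED", length(added)),
               stringsAsFactors = FALSE)
  )
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL
  out <- ppi_network(nodes, edges, threshold = threshold,
                     unconnected = seed_network$unconnected)
  # the greedy addition sequence, for inspection and auditability
  attr(out, "added_order") <- added
  out
}

#' Count edges per unordered pair of protein classes
#'
#' Classifies every interaction by the network classes of its two endpoints
#' (e.g. `HYPER--HYPER`, `HYPO--NONE`, `NONE--NONE`), so the composition of
#' an expanded network can be compared between disease proteins and newly
#' added interactors.
#'
#' @param network A `ppi_network`.
#' @return Data frame with columns `class_a`, `class_b` (lexically ordered),
#'   `count`; counts sum to the edge total.
#' @export
categorize_edges <- function(network) {
  cls <- setNames(network$nodes$network_class, network$nodes$symbol)
  ca <- cls[network$edges$protein_a]
  cb <- cls[network$edges$protein_b]
  cp <- canonical_pairs(unname(ca), unname(cb))
  if (!length(cp$a)) {
    return(data.frame(class_a = character(), class_b = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tb <- table(paste(cp$a, cp$b, sep = "\r"))
  parts <- strsplit(names(tb), "\r", fixed = TRUE)
  out <- data.frame(class_a = vapply(parts, `[[`, "", 1L),
                    class_b = vapply(parts, `[[`, "", 2L),
                    count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$class_a, out$class_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
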