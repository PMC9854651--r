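# fixtures built in code + independent oracles for derived expectations

make_edges <- function(...) {
  # make_edges("A","B",0.8, "B","C",0.9)
  v <- list(...)
  stopifnot(length(v) %% 3 == 0)
  i <- seq(1, length(v), by = 3)
  scored_edge_table(unlist(v[i]), unlist(v[i + 1]), unlist(v[i + 2]))
}

tiny_network <- function() {
  nodes <- data.frame(symbol = c("A", "B", "C"),
                      network_class = c("HYPER", "HYPO", "NONE"),
                      provenance = c("SEED", "SEED", "ADDED"),
                      stringsAsFactors = FALSE)
  ppi_network(nodes, make_edges("A", "B", 0.8, "B", "C", 0.95),
              threshold = 0.7)
}

# complete k-clique on the given names, constant edge weight
clique_edges <- function(names, weight = 0.9) {
  p <- utils::combn(names, 2)
  scored_edge_table(p[1, ], p[2, ], rep(weight, ncol(p)))
}

network_from_edges <- function(edges, extra_nodes = character()) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b, extra_nodes)))
  ppi_network(data.frame(symbol = nodes, stringsAsFactors = FALSE), edges)
}

# canonical string form of a partition, for order-free comparison
partition_key <- function(clusters) {
  sort(unname(vapply(clusters,
                     function(m) paste(sort(unlist(m)), collapse = ","), "")))
}

# --- independent MCL oracle: numpy implementation shipped under inst/oracle ---

mcl_oracle <- function(network, inflation, prune = 1e-5, tol = 1e-6,
                       max_iter = 200, expansion = 2, self_loop = "max") {
  script <- system.file("oracle", "mcl_reference.py", package = "pigmentnet")
  stopifnot(nzchar(script))
  edges <- unname(Map(function(a, b, s) list(a, b, s),
                      network$edges$protein_a, network$edges$protein_b,
                      network$edges$score))
  problem <- list(nodes = as.list(network$nodes$symbol), edges = edges,
                  inflation = inflation, prune = prune, tol = tol,
                  max_iter = max_iter, expansion = expansion,
                  self_loop = self_loop)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(problem, f, auto_unbox = TRUE, digits = NA)
  out <- system2("python", c(shQuote(script), shQuote(f)), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# --- exhaustive hypergeometric upper tail: sum of combinatorial terms ---

hyper_upper_tail_enum <- function(k, K, N, n) {
  idx <- k:min(n, K)
  sum(choose(K, idx) * choose(N - K, n - idx)) / choose(N, n)
}

# --- Benjamini-Hochberg step-up applied literally from its definition ---

bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# --- from-scratch greedy-expansion oracle: re-ranks every candidate at
#     every step with explicit per-candidate loops ---

oracle_expand_order <- function(seed_network, background, threshold,
                                edge_target, criterion = "score") {
  bg <- as.data.frame(background)
  bg <- bg[bg$score >= threshold, , drop = FALSE]
  members <- seed_network$nodes$symbol
  seed_ed <- as.data.frame(seed_network$edges)

  count_edges <- function(mem) {
    keep <- bg$protein_a %in% mem & bg$protein_b %in% mem
    ed <- rbind(seed_ed[, c("protein_a", "protein_b")],
                bg[keep, c("protein_a", "protein_b")])
    nrow(unique(ed))
  }

  added <- character()
  repeat {
    if (count_edges(members) > edge_target) break
    outside <- setdiff(unique(c(bg$protein_a, bg$protein_b)), members)
    if (!length(outside)) break
    score_sum <- numeric(length(outside))
    n_edges <- integer(length(outside))
    for (i in seq_along(outside)) {
      x <- outside[i]
      sel <- (bg$protein_a == x & bg$protein_b %in% members) |
        (bg$protein_b == x & bg$protein_a %in% members)
      score_sum[i] <- sum(bg$score[sel])
      n_edges[i] <- sum(sel)
    }
    if (all(n_edges == 0)) break
    key <- if (criterion == "score") score_sum else as.numeric(n_edges)
    best <- outside[order(-key, -n_edges, outside)][1]
    members <- c(members, best)
    added <- c(added, best)
  }
  added
}

# adjusted Rand index between two labelings (named vectors over same nodes)
ari <- function(a, b) {
  b <- b[names(a)]
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
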