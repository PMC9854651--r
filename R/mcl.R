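# Markov Cluster algorithm (MCL) on weighted PPI networks
#
# The algorithm alternates expansion (squaring a column-stochastic matrix,
# i.e. two-step random-walk flow) with inflation (entrywise powering and
# column renormalization, which strengthens intra-cluster flow) until the
# matrix converges; clusters are read off the attractors of the limit matrix.

#' Build the column-stochastic transition matrix of a network
#'
#' Adjacency is weighted by edge score. Each node receives a self-loop before
#' normalization: with the default `"max"` policy its weight is the maximum
#' incident edge weight (isolated nodes get 1), with `"one"` a constant 1.
#' Self-loops keep the iteration well-defined and damp odd/even oscillation.
#'
#' @param network A `ppi_network`.
#' @param self_loop `"max"` (default) or `"one"`.
#' @return A `transition_matrix`: list with `matrix` (columns sum to 1) and
#'   `node_order`.
#' @export
build_transition_matrix <- function(network, self_loop = c("max", "one")) {
  self_loop <- match.arg(self_loop)
  nodes <- network$nodes$symbol
  if (!length(nodes)) {
    pn_stop("network has no nodes", "pigmentnet_config_error")
  }
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges)) {
    ia <- match(network$edges$protein_a, nodes)
    ib <- match(network$edges$protein_b, nodes)
    A[cbind(ia, ib)] <- network$edges$score
    A[cbind(ib, ia)] <- network$edges$score
  }
  loops <- if (self_loop == "max") {
    w <- apply(A, 2, max)
    ifelse(w > 0, w, 1)
  } else rep(1, n)
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  structure(list(matrix = M, node_order = nodes),
            class = "transition_matrix")
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  # a column emptied by pruning falls back to a self-loop
  dead <- cs == 0
  if (any(dead)) {
    M[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(M, 2, cs, "/")
}

#' Run the Markov Cluster algorithm
#'
#' Iterates expansion (matrix power `expansion`, default 2), inflation
#' (entrywise power `inflation`, then column renormalization), and pruning
#' (entries below `prune_threshold` zeroed, columns renormalized) until the
#' largest entry change falls below `tol` or `max_iter` is reached. Clusters
#' are the supports of attractor rows (nodes with positive diagonal mass in
#' the limit matrix); overlapping attractor supports are merged so the result
#' is always a partition.
#'
#' @param tm A `transition_matrix` from [build_transition_matrix()], or a
#'   `ppi_network` (converted with default self-loop policy).
#' @param inflation Inflation exponent > 1 (default 2.5); larger values give
#'   finer clusters.
#' @param prune_threshold Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 200); non-convergence is reported
#'   via the `converged` flag and a warning, never an error.
#' @param tol Convergence tolerance on the max absolute entry change
#'   (default 1e-6).
#' @param expansion Expansion power (default 2, the standard choice).
#' @return An `mcl_clusters` object: `clusters` (list of node-name vectors,
#'   decreasing size), `membership` (named integer), `converged`,
#'   `iterations`, `inflation`.
#' @export
mcl <- function(tm, inflation = 2.5, prune_threshold = 1e-5,
                max_iter = 200L, tol = 1e-6, expansion = 2L) {
  if (inherits(tm, "ppi_network")) tm <- build_transition_matrix(tm)
  stopifnot(inherits(tm, "transition_matrix"))
  if (!is.numeric(inflation) || inflation <= 1) {
    pn_stop("inflation must be > 1", "pigmentnet_config_error")
  }
  M <- tm$matrix
  nodes <- tm$node_order
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- M
    for (k in seq_len(expansion - 1L)) M <- M %*% prev  # expansion: M^e
    M <- normalize_columns(M^inflation)                  # inflation
    M[M < prune_threshold] <- 0                          # pruning
    M <- normalize_columns(M)
    if (max(abs(M - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge within %d iterations", max_iter),
            call. = FALSE)
  }

  clusters <- interpret_clusters(M, nodes)
  structure(list(clusters = clusters,
                 membership = cluster_membership(clusters),
                 converged = converged,
                 iterations = iter,
                 inflation = inflation),
            class = "mcl_clusters")
}

# read clusters from the limit matrix: attractor rows' supports, merged when
# they overlap; non-attractor nodes follow the attractor owning most of their
# column mass
interpret_clusters <- function(M, nodes, eps = 1e-7) {
  n <- length(nodes)
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate safeguard
  assign <- rep(NA_integer_, n)
  cluster_of_attr <- integer(length(attractors))
  next_id <- 0L
  for (i in seq_along(attractors)) {
    support <- which(M[attractors[i], ] > eps)
    support <- union(support, attractors[i])
    ids <- unique(assign[support])
    ids <- ids[!is.na(ids)]
    if (!length(ids)) {
      next_id <- next_id + 1L
      id <- next_id
    } else {
      id <- min(ids)
      if (length(ids) > 1) assign[assign %in% ids] <- id  # merge overlaps
    }
    assign[support] <- id
    cluster_of_attr[i] <- id
  }
  # nodes outside every attractor support: follow dominant column mass
  for (j in which(is.na(assign))) {
    mass <- M[attractors, j]
    if (length(mass) && max(mass) > eps) {
      assign[j] <- assign[attractors[which.max(mass)]]
    } else {
      next_id <- next_id + 1L
      assign[j] <- next_id
    }
  }
  cl <- unname(split(nodes, assign))
  cl <- lapply(cl, sort)
  cl[order(-lengths(cl), vapply(cl, `[[`, "", 1L))]
}

cluster_membership <- function(clusters) {
  m <- integer()
  for (i in seq_along(clusters)) {
    m[clusters[[i]]] <- i
  }
  m
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat(sprintf("mcl_clusters: %d cluster(s) over %d node(s), inflation %.2f%s\n",
              length(x$clusters), length(x$membership), x$inflation,
              if (x$converged) sprintf(" (converged in %d iterations)", x$iterations)
              else " (NOT converged)"))
  sizes <- lengths(x$clusters)
  cat("  sizes:", paste(utils::head(sizes, 15), collapse = ", "),
      if (length(sizes) > 15) "..." else "", "\n")
  invisible(x)
}

#' Summarize clusters with sizes and class composition
#'
#' Clusters are numbered 1..k strictly by decreasing size (ties broken by
#' first member name).
#'
#' @param assignment An `mcl_clusters` object.
#' @param classes Optional gene-class assignment (`gene`, `network_class`).
#' @return Data frame: `cluster`, `size`, one count column per network class
#'   present, and `members` (comma-joined symbols).
#' @export
cluster_summary <- function(assignment, classes = NULL) {
  cl <- assignment$clusters
  lv <- c(PHENOTYPE_CLASSES, "MULTIPLE", "NONE")
  out <- data.frame(cluster = seq_along(cl), size = lengths(cl))
  if (!is.null(classes)) {
    comp <- t(vapply(cl, function(members) {
      cls <- lookup_classes(members, classes)
      as.integer(table(factor(cls, levels = lv)))
    }, integer(length(lv))))
    colnames(comp) <- lv
    out <- cbind(out, as.data.frame(comp))
  }
  out$members <- vapply(cl, paste, "", collapse = ",")
  out
}
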