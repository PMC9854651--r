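# Markov clustering: transition matrix, iteration, cluster reading,
# and equivalence with an independent reference implementation

test_that("transition matrices are column-stochastic with the stated self-loop policy", {
  lone <- ppi_network(data.frame(symbol = "A", stringsAsFactors = FALSE),
                      scored_edge_table())
  tm <- build_transition_matrix(lone)
  expect_equal(unname(tm$matrix), matrix(1, 1, 1))

  pair <- network_from_edges(make_edges("A", "B", 0.8))
  tm2 <- build_transition_matrix(pair)
  expect_equal(unname(colSums(tm2$matrix)), c(1, 1), tolerance = 1e-9)
  # max-incident self-loop: diagonal weight equals the 0.8 edge before normalization
  expect_equal(unname(tm2$matrix[1, 1]), 0.5)

  sim <- gen_ppi(synthetic_spec(n_modules = 3, module_size = 5,
                                background_size = 0, rng_seed = 2),
                 sprintf("G%02d", 1:15))
  net <- network_from_edges(sim$edges)
  for (policy in c("max", "one")) {
    M <- build_transition_matrix(net, self_loop = policy)$matrix
    expect_true(all(abs(colSums(M) - 1) < 1e-9))
    expect_true(all(M >= 0))
  }
})

test_that("an edgeless graph yields all singleton clusters", {
  net <- ppi_network(data.frame(symbol = LETTERS[1:6], stringsAsFactors = FALSE),
                     scored_edge_table())
  cl <- mcl(net, inflation = 2.5)
  expect_equal(length(cl$clusters), 6)
  expect_true(all(lengths(cl$clusters) == 1))
})

test_that("two disjoint triangles resolve into two clusters of three", {
  edges <- make_edges("A", "B", 1, "B", "C", 1, "A", "C", 1,
                      "X", "Y", 1, "Y", "Z", 1, "X", "Z", 1)
  net <- network_from_edges(edges)
  cl <- mcl(net, inflation = 2.5)
  expect_equal(partition_key(cl$clusters), c("A,B,C", "X,Y,Z"))
  expect_equal(partition_key(cl$clusters),
               partition_key(mcl_oracle(net, inflation = 2.5)))
})

test_that("a weakly bridged barbell splits at the bridge", {
  left <- clique_edges(c("A1", "A2", "A3", "A4"), 0.9)
  right <- clique_edges(c("B1", "B2", "B3", "B4"), 0.9)
  bridge <- make_edges("A1", "B1", 0.71)
  net <- network_from_edges(scored_edge_table(
    c(left$protein_a, right$protein_a, bridge$protein_a),
    c(left$protein_b, right$protein_b, bridge$protein_b),
    c(left$score, right$score, bridge$score)))
  cl <- mcl(net, inflation = 2.5)
  expect_equal(partition_key(cl$clusters),
               c("A1,A2,A3,A4", "B1,B2,B3,B4"))
  expect_equal(partition_key(cl$clusters),
               partition_key(mcl_oracle(net, inflation = 2.5)))
})

test_that("clustering always returns a partition and preserves column stochasticity", {
  for (seed in c(3, 9, 27)) {
    sim <- gen_ppi(synthetic_spec(n_modules = 3, module_size = 6,
                                  background_size = 10, p_out = 0.1,
                                  rng_seed = seed),
                   sprintf("G%02d", 1:18))
    net <- network_from_edges(sim$edges)
    cl <- mcl(net, inflation = 2.5)
    members <- sort(unlist(cl$clusters))
    expect_equal(members, sort(net$nodes$symbol))  # disjoint and exhaustive
    expect_equal(sort(names(cl$membership)), sort(net$nodes$symbol))
  }
})

test_that("planted modules are recovered exactly and cluster counts grow with inflation", {
  spec <- synthetic_spec(n_modules = 4, module_size = 10, p_in = 0.9,
                         p_out = 0.02, background_size = 0, rng_seed = 42)
  sim <- gen_ppi(spec, sprintf("G%02d", 1:40))
  net <- induced_subnetwork(sim$edges, sprintf("G%02d", 1:40), 0.7)
  cl <- mcl(net, inflation = 2.5)
  truth <- sim$truth$module_membership[net$nodes$symbol]
  expect_equal(ari(cl$membership, truth), 1.0)

  ks <- vapply(c(1.5, 2.5, 4.0), function(inf) {
    length(mcl(net, inflation = inf)$clusters)
  }, 0L)
  expect_true(all(diff(ks) >= 0))
})

test_that("partitions match the reference implementation on small random graphs", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- sample(3:8, 1)
    syms <- sprintf("N%d", 1:n)
    pairs <- utils::combn(syms, 2)
    keep <- runif(ncol(pairs)) < 0.45
    net <- if (any(keep)) {
      network_from_edges(scored_edge_table(pairs[1, keep], pairs[2, keep],
                                           runif(sum(keep), 0.3, 1)),
                         extra_nodes = syms)
    } else {
      ppi_network(data.frame(symbol = syms, stringsAsFactors = FALSE),
                  scored_edge_table())
    }
    ours <- mcl(net, inflation = 2.5)
    ref <- mcl_oracle(net, inflation = 2.5)
    expect_equal(partition_key(ours$clusters), partition_key(ref),
                 info = sprintf("random graph seed %d", seed))
  }
})

test_that("non-convergence is reported, never silently dropped", {
  sim <- gen_ppi(synthetic_spec(n_modules = 2, module_size = 8,
                                background_size = 0, p_out = 0.2, rng_seed = 8),
                 sprintf("G%02d", 1:16))
  net <- network_from_edges(sim$edges)
  expect_warning(cl <- mcl(net, inflation = 2.5, max_iter = 1L),
                 "did not converge")
  expect_false(cl$converged)
})

test_that("cluster summaries number clusters by decreasing size with class composition", {
  edges <- make_edges("A", "B", 1, "B", "C", 1, "A", "C", 1, "X", "Y", 1)
  net <- network_from_edges(edges)
  cl <- mcl(net, inflation = 2.5)
  classes <- data.frame(gene = c("A", "B", "C", "X", "Y"),
                        network_class = c("HYPER", "HYPER", "HYPO",
                                          "NONE", "NONE"),
                        stringsAsFactors = FALSE)
  summ <- cluster_summary(cl, classes)
  expect_equal(summ$size, sort(summ$size, decreasing = TRUE))
  expect_equal(summ$size[1], 3)
  expect_equal(summ$HYPER[1], 2)
  expect_equal(summ$HYPO[1], 1)
  expect_equal(sum(summ$size), 5)
})
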