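# induced subnetworks, connectivity, greedy expansion, edge categories

test_that("induced subnetwork applies the inclusive threshold and the seed rule", {
  edges <- make_edges("A", "B", 0.700, "A", "C", 0.699)
  net <- induced_subnetwork(edges, c("A", "B", "C"), 0.700)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes$symbol, c("A", "B"))
  expect_equal(net$unconnected, "C")  # seed without surviving edges

  # an edge to a non-seed protein never enters the induced network
  net2 <- induced_subnetwork(make_edges("A", "X", 0.9), c("A", "B"), 0.7)
  expect_equal(nrow(net2$nodes), 0)
  expect_equal(nrow(net2$edges), 0)

  expect_error(induced_subnetwork(edges, c("A"), threshold = 1.5),
               class = "pigmentnet_config_error")
  expect_error(induced_subnetwork(edges, character(), 0.7),
               class = "pigmentnet_config_error")
})

test_that("threshold filtering is monotone in nodes and edges", {
  sim <- gen_ppi(synthetic_spec(n_modules = 3, module_size = 6,
                                background_size = 10, rng_seed = 5),
                 sprintf("G%02d", 1:30))
  seeds <- unique(c(sim$edges$protein_a, sim$edges$protein_b))
  sizes <- vapply(c(0.2, 0.5, 0.7, 0.9), function(thr) {
    network_size(induced_subnetwork(sim$edges, seeds, thr))
  }, c(nodes = 0, edges = 0))
  expect_true(all(diff(sizes["nodes", ]) <= 0))
  expect_true(all(diff(sizes["edges", ]) <= 0))
})

test_that("connectivity summary reports half-up integer percents and component sizes", {
  # 139 of 200 seeds connected: 69.5% rounds up to 70
  seeds <- sprintf("P%03d", 1:200)
  edges <- scored_edge_table(seeds[1:138], seeds[2:139], rep(0.9, 138))
  net <- induced_subnetwork(edges, seeds, 0.7)
  conn <- connectivity_summary(net, seeds)
  expect_equal(conn$n_connected, 139)
  expect_equal(conn$connected_fraction, 70L)
  expect_equal(conn$components, 139L)

  # all seeds isolated -> 0%; complete graph -> 100%, one component
  empty <- induced_subnetwork(scored_edge_table(), seeds, 0.7)
  expect_equal(connectivity_summary(empty, seeds)$connected_fraction, 0L)
  full <- induced_subnetwork(clique_edges(seeds[1:20]), seeds[1:20], 0.7)
  connf <- connectivity_summary(full, seeds[1:20])
  expect_equal(connf$connected_fraction, 100L)
  expect_equal(length(connf$components), 1L)
})

test_that("expansion picks the strongest candidate and stops past the edge target", {
  seed_net <- network_from_edges(make_edges("A", "B", 0.9))
  bg <- make_edges("A", "B", 0.9,
                   "A", "X", 0.9, "B", "X", 0.9,
                   "A", "Y", 0.8)
  grown <- expand_network(seed_net, bg, threshold = 0.7, edge_target = 2)
  expect_equal(attr(grown, "added_order")[1], "X")  # summed 1.8 beats 0.8

  # already past the target: returned unchanged
  seed5 <- network_from_edges(clique_edges(c("A", "B", "C", "D"), 0.9))  # 6 edges
  same <- expand_network(seed5, clique_edges(c("A", "B", "C", "D", "E"), 0.9),
                         threshold = 0.7, edge_target = 0)
  expect_equal(network_size(same), network_size(seed5))
  expect_equal(attr(same, "added_order"), character())

  # background exhausted before the target -> maximal network with warning
  expect_warning(
    maxed <- expand_network(seed_net, bg, threshold = 0.7, edge_target = 100),
    "exhausted")
  expect_setequal(maxed$nodes$symbol, c("A", "B", "X", "Y"))
  expect_equal(maxed$nodes$provenance[maxed$nodes$symbol == "X"], "ADDED")
})

test_that("expansion equals brute-force candidate re-ranking and is deterministic", {
  spec <- synthetic_spec(n_modules = 3, module_size = 8, background_size = 60,
                         background_attach = 4, rng_seed = 17)
  sim <- gen_ppi(spec, sprintf("G%02d", 1:24))
  seeds <- sprintf("G%02d", 1:24)
  seed_net <- induced_subnetwork(sim$edges, seeds, 0.7)

  grown1 <- expand_network(seed_net, sim$edges, threshold = 0.7,
                           edge_target = 150)
  grown2 <- expand_network(seed_net, sim$edges, threshold = 0.7,
                           edge_target = 150)
  expect_identical(attr(grown1, "added_order"), attr(grown2, "added_order"))
  expect_identical(grown1$edges, grown2$edges)

  oracle <- oracle_expand_order(seed_net, sim$edges, 0.7, 150)
  expect_identical(attr(grown1, "added_order"), oracle)
  expect_gt(nrow(grown1$edges), 150)
})

test_that("the expanded network induces back to the seed network at the same threshold", {
  spec <- synthetic_spec(n_modules = 2, module_size = 6, background_size = 30,
                         background_attach = 3, rng_seed = 23)
  seeds <- sprintf("G%02d", 1:12)
  sim <- gen_ppi(spec, seeds)
  seed_net <- induced_subnetwork(sim$edges, seeds, 0.7)
  grown <- expand_network(seed_net, sim$edges, threshold = 0.7,
                          edge_target = nrow(seed_net$edges) + 20)
  back <- induced_subnetwork(grown$edges, seeds, 0.7)
  expect_setequal(back$nodes$symbol, seed_net$nodes$symbol)
  expect_equal(back$edges[order(back$edges$protein_a, back$edges$protein_b), ],
               seed_net$edges[order(seed_net$edges$protein_a,
                                    seed_net$edges$protein_b), ])
})

test_that("edge categories count unordered class pairs and conserve the total", {
  nodes <- data.frame(symbol = c("A", "B", "C"),
                      network_class = c("HYPER", "HYPER", "HYPO"),
                      provenance = "SEED", stringsAsFactors = FALSE)
  tri <- ppi_network(nodes, clique_edges(c("A", "B", "C"), 0.9))
  cats <- categorize_edges(tri)
  expect_equal(cats$count[cats$class_a == "HYPER" & cats$class_b == "HYPER"], 1)
  expect_equal(cats$count[cats$class_a == "HYPER" & cats$class_b == "HYPO"], 2)
  expect_equal(sum(cats$count), nrow(tri$edges))

  # single class: one category holds everything
  nodes$network_class <- "HYPO"
  mono <- categorize_edges(ppi_network(nodes, clique_edges(c("A", "B", "C"))))
  expect_equal(nrow(mono), 1)
  expect_equal(mono$count, 3)

  # conservation on a generated network with mixed classes
  sim <- gen_ppi(synthetic_spec(n_modules = 3, module_size = 6,
                                background_size = 15, rng_seed = 31),
                 sprintf("G%02d", 1:18))
  net <- induced_subnetwork(sim$edges,
                            unique(c(sim$edges$protein_a, sim$edges$protein_b)),
                            0.7)
  expect_equal(sum(categorize_edges(net)$count), nrow(net$edges))
})
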