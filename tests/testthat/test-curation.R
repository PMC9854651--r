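# curation, disease classification, gene classes, diseasome, upset counts

simple_catalog <- function() gene_catalog(c("TYR", "KIT", "MC1R", "MITF", "FANCA"))

test_that("curation removes unmatched genes and deduplicates with merged sources", {
  raw <- association_table(
    gene = c("TYR", "FAKE1", "TYR", "KIT"),
    disease = c("Vitiligo", "Ghost disease", "Vitiligo", "Piebaldism"),
    phenotype_class = c("HYPO", "HYPO", "HYPO", "HYPO"),
    source = c("YAMAGUCHI", "YAMAGUCHI", "OPENTARGETS", "BAXTER"))
  cur <- curate(raw, simple_catalog())
  expect_equal(attr(cur, "n_associations"), 2)
  expect_equal(attr(cur, "n_genes"), 2)
  expect_equal(attr(cur, "n_diseases"), 2)
  expect_equal(attr(cur, "n_unmatched"), 1)
  tyr <- cur[cur$gene == "TYR", ]
  expect_equal(tyr$source, "OPENTARGETS,YAMAGUCHI")  # both sources recorded

  expect_error(gene_catalog(character()), "empty",
               class = "pigmentnet_config_error")
})

test_that("conflicting class annotations resolve by source precedence with a warning", {
  raw <- association_table(
    gene = c("TYR", "TYR"),
    disease = c("Vitiligo", "Vitiligo"),
    phenotype_class = c("HYPER", "HYPO"),
    source = c("OPENTARGETS", "YAMAGUCHI"))
  expect_warning(cur <- curate(raw, simple_catalog()), "conflicting")
  expect_equal(cur$phenotype_class, "HYPO")  # review classification wins
})

test_that("disease class counts partition the unique diseases", {
  one <- curate(association_table("TYR", "Vitiligo", "HYPO", "YAMAGUCHI"),
                simple_catalog())
  counts <- classify_diseases(one)
  expect_equal(unname(counts["HYPO"]), 1L)
  expect_equal(sum(counts), 1L)

  empty <- curate(association_table(character(), character(), character(),
                                    character()),
                  simple_catalog())
  expect_equal(sum(classify_diseases(empty)), 0L)

  bad <- association_table("TYR", "Vitiligo", "ULTRAVIOLET", "YAMAGUCHI")
  expect_error(classify_diseases(bad), "row 1",
               class = "pigmentnet_validation_error")

  # conservation on generated tables of varying structure
  for (seed in 1:3) {
    sim <- gen_associations(synthetic_spec(n_diseases = 40, n_genes = 120,
                                           rng_seed = seed))
    cur <- curate(sim$associations, sim$catalog)
    counts <- classify_diseases(cur)
    expect_equal(sum(counts), length(unique(cur$disease)))
    expect_equal(counts[names(sim$truth$class_counts)],
                 sim$truth$class_counts)
  }
})

test_that("gene classes are the unique disease class, or MULTIPLE when classes span", {
  raw <- association_table(
    gene = c("TYR", "TYR", "KIT", "KIT", "KIT", "MC1R"),
    disease = c("Melasma", "Vitiligo", "HPS1", "HPS2", "HPS3", "Melasma"),
    phenotype_class = c("HYPER", "HYPO", "HYPO", "HYPO", "HYPO", "HYPER"),
    source = "YAMAGUCHI")
  cur <- curate(raw, simple_catalog())
  gc <- assign_gene_classes(cur)
  expect_equal(gc$network_class[gc$gene == "TYR"], "MULTIPLE")
  expect_equal(gc$network_class[gc$gene == "KIT"], "HYPO")
  expect_equal(gc$network_class[gc$gene == "MC1R"], "HYPER")
  counts <- attr(gc, "exclusive_counts")
  expect_equal(sum(counts), attr(cur, "n_genes"))
})

test_that("the diseasome is bipartite with one link per association", {
  one <- curate(association_table("TYR", "Vitiligo", "HYPO", "YAMAGUCHI"),
                simple_catalog())
  d1 <- build_diseasome(one)
  expect_equal(length(d1$genes) + nrow(d1$diseases), 2)
  expect_equal(nrow(d1$links), 1)

  raw <- association_table(
    gene = c("TYR", "TYR", "KIT"),
    disease = c("Vitiligo", "Melasma", "Piebaldism"),
    phenotype_class = c("HYPO", "HYPER", "HYPO"),
    source = "YAMAGUCHI")
  cur <- curate(raw, simple_catalog())
  d2 <- build_diseasome(cur)
  expect_equal(sum(d2$links$gene == "TYR"), 2)  # degree 2
  expect_equal(nrow(d2$links), attr(cur, "n_associations"))
  g <- diseasome_igraph(d2)
  expect_true(igraph::is_bipartite(g))
})

test_that("upset patterns are exclusive and partition the covered genes", {
  raw <- association_table(
    gene = c("TYR", "KIT", "KIT", "MITF"),
    disease = c("D1", "D1", "D2", "D2"),
    phenotype_class = "HYPO", source = "YAMAGUCHI")
  dis <- build_diseasome(curate(raw,
                                gene_catalog(c("TYR", "KIT", "MITF"))))
  up <- upset_counts(dis, c("D1", "D2"))
  expect_equal(up$gene_count[up$pattern == "D1"], 1)       # TYR only
  expect_equal(up$gene_count[up$pattern == "D2"], 1)       # MITF only
  expect_equal(up$gene_count[up$pattern == "D1 & D2"], 1)  # KIT shared

  expect_error(upset_counts(dis, c("D1", "D9")), "D9",
               class = "pigmentnet_lookup_error")

  # disjoint diseases yield no joint pattern
  raw2 <- association_table(c("TYR", "KIT"), c("D1", "D2"), "HYPO", "YAMAGUCHI")
  up2 <- upset_counts(build_diseasome(curate(raw2, simple_catalog())),
                      c("D1", "D2"))
  expect_false("D1 & D2" %in% up2$pattern)
})

test_that("upset counts equal exhaustive membership enumeration on synthetic diseasomes", {
  sim <- gen_associations(synthetic_spec(n_diseases = 40, n_genes = 80,
                                         share_within = 0.5,
                                         share_between = 0.2, rng_seed = 11))
  dis <- build_diseasome(curate(sim$associations, sim$catalog))
  subset <- dis$diseases$disease[1:4]
  up <- upset_counts(dis, subset)

  # brute force: one membership vector per gene
  links <- dis$links[dis$links$disease %in% subset, ]
  genes <- unique(links$gene)
  pats <- vapply(genes, function(g) {
    d <- links$disease[links$gene == g]
    paste(subset[subset %in% d], collapse = " & ")
  }, "")
  expected <- table(pats)
  expect_equal(sum(up$gene_count), length(genes))
  for (p in names(expected)) {
    expect_equal(up$gene_count[up$pattern == p], unname(unclass(expected[p])))
  }
})
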