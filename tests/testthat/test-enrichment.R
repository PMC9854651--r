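# class profiling, hypergeometric over-representation, BH adjustment

toy_annotation <- function() {
  genes <- sprintf("G%02d", 1:10)
  l3 <- c(rep("Signaling", 4), rep("Metabolism", 3),
          rep("Immune system and Inflammation", 2), "Unknown")
  df <- data.frame(gene = genes,
                   class_l1 = paste(l3, "/ class 1"),
                   class_l2 = paste(l3, "/ group 1"),
                   class_l3 = l3, stringsAsFactors = FALSE)
  class(df) <- c("functional_annotation", "data.frame")
  df
}

test_that("class profiles count each gene once and total 100 percent", {
  ann <- toy_annotation()
  prof <- class_profile(sprintf("G%02d", 1:10), ann, level = 3)
  expect_equal(sum(prof$count), 10)
  expect_equal(sum(prof$percent), 100)
  expect_equal(prof$count[prof$class == "Signaling"], 4)

  # unannotated genes fall into Unknown
  prof2 <- class_profile(c("G01", "NOVEL1"), ann, level = 3)
  expect_equal(prof2$count[prof2$class == "Unknown"], 1)

  # all genes of one class -> 100%
  prof3 <- class_profile(sprintf("G%02d", 1:4), ann, level = 3)
  expect_equal(prof3$percent[prof3$class == "Signaling"], 100)

  expect_equal(nrow(class_profile(character(), ann, 3)), 0)
  expect_error(class_profile("G01", ann, level = 4),
               class = "pigmentnet_config_error")

  # profiles of disjoint sets are computed independently
  a <- class_profile(sprintf("G%02d", 1:5), ann, 3)
  b <- class_profile(sprintf("G%02d", 6:10), ann, 3)
  both <- class_profile(sprintf("G%02d", 1:5), ann, 3)
  expect_identical(a, both)
  expect_equal(sum(b$count), 5)
})

test_that("hypergeometric p-values equal exhaustive enumeration", {
  # N=10, K=4, n=5, k=3: [C(4,3)C(6,2)+C(4,4)C(6,1)]/C(10,5) = 66/252
  universe <- sprintf("U%02d", 1:10)
  term <- list(T1 = universe[1:4])
  query <- universe[c(1, 2, 3, 5, 6)]
  res <- hypergeometric_ora(query, term, universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p_value, hyper_upper_tail_enum(3, 4, 10, 5),
               tolerance = 1e-12)

  # k = 0 has upper tail 1; the full-overlap degenerate case is also 1
  res0 <- hypergeometric_ora(universe[5:9], list(T1 = universe[1:4]), universe)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p_value, 1.0)
  resF <- hypergeometric_ora(universe, list(T1 = universe), universe)
  expect_equal(resF$p_value, 1.0)

  # full grid N <= 12 against the combinatorial oracle
  for (N in c(5, 8, 12)) {
    uni <- sprintf("X%02d", 1:N)
    for (K in c(1, floor(N / 2), N - 1)) {
      for (n in c(1, floor(N / 2), N)) {
        for (k in 0:min(n, K)) {
          # build a query realizing exactly overlap k
          if (n - k > N - K) next
          query <- c(uni[seq_len(k)], uni[K + seq_len(n - k)])
          res <- hypergeometric_ora(query, list(T = uni[seq_len(K)]), uni)
          expect_equal(res$p_value, hyper_upper_tail_enum(k, K, N, n),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("ORA validates its query and flags significance at the adjusted level", {
  universe <- sprintf("U%02d", 1:20)
  terms <- list(T1 = universe[1:5], T2 = universe[6:19])
  expect_error(hypergeometric_ora(c("U01", "ALIEN"), terms, universe),
               "ALIEN", class = "pigmentnet_validation_error")
  expect_warning(empty <- hypergeometric_ora(character(), terms, universe),
                 "empty")
  expect_equal(nrow(empty), 0)

  res <- hypergeometric_ora(universe[1:5], terms, universe, alpha = 0.05)
  expect_true(res$significant[res$term == "T1"])
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  expect_equal(res$adjusted_p, sort(res$adjusted_p))  # sorted output
})

test_that("Benjamini-Hochberg matches the literal step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))
  expect_error(benjamini_hochberg(c(0.1, 1.2)),
               class = "pigmentnet_validation_error")

  set.seed(99)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_by_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in sorted order
    expect_true(all(adj <= 1))
  }
})

test_that("the null false-positive rate stays at the nominal level", {
  # small-scale null simulation; the full 1000-replicate version runs in the
  # acceptance suite
  set.seed(7)
  universe <- sprintf("U%03d", 1:200)
  terms <- lapply(1:20, function(i) sample(universe, 15))
  names(terms) <- sprintf("T%02d", 1:20)
  n_sig <- 0L
  n_tests <- 0L
  for (r in 1:200) {
    res <- hypergeometric_ora(sample(universe, 25), terms, universe)
    n_sig <- n_sig + sum(res$significant)
    n_tests <- n_tests + nrow(res)
  }
  rate <- n_sig / n_tests
  se <- sqrt(0.05 * 0.95 / n_tests)
  expect_lte(rate, 0.05 + 3 * se)
})
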