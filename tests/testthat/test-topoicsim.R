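test_that("reference fixture distances follow the path formulas", {
  fx <- metabolism_fixture()
  # unique combined path through GO:0071704: 5 IIC terms, 4 edges;
  # root path: 2 IIC terms, 2 edges (direct arithmetic on the reference ICs)
  d1_expected <- ((1 / 2.158 + 1 / 2.086 + 1 / 1.255 + 1 / 1.479 + 1 / 1.617) * 4) /
    ((1 / 1.255 + 1 / 1.098) * 2)
  d2_expected <- ((1 / 2.158 + 1 / 1.999 + 1 / 1.329 + 1 / 1.617) * 3) /
    ((1 / 1.329 + 1 / 0.407) * 2)
  expect_equal(term_distance_via_ancestor(fx$graph, fx$ic, fx$leaves[1],
                                          fx$leaves[2], "GO:0071704"),
               d1_expected, tolerance = 1e-9)
  expect_equal(term_distance_via_ancestor(fx$graph, fx$ic, fx$leaves[1],
                                          fx$leaves[2], "GO:0044237"),
               d2_expected, tolerance = 1e-9)
  td <- term_distance(fx$graph, fx$ic, fx$leaves[1], fx$leaves[2])
  expect_identical(td$ancestor, "GO:0044237")
  expect_equal(td$distance, min(d1_expected, d2_expected), tolerance = 1e-9)
  expect_error(term_distance_via_ancestor(fx$graph, fx$ic, fx$leaves[1],
                                          fx$leaves[2], "GO:0008152"),
               "not a disjunctive common ancestor")
})

test_that("distance-to-similarity mapping is the arctan transform", {
  expect_equal(similarity_from_distance(0), 1)
  expect_equal(similarity_from_distance(Inf), 0)
  expect_equal(round(similarity_from_distance(1.076), 3), 0.477)
  # strictly decreasing on a grid
  grid <- seq(0, 50, by = 0.25)
  expect_true(all(diff(similarity_from_distance(grid)) < 0))
})

test_that("identical terms and root-only ancestors hit the analytic limits", {
  fx <- metabolism_fixture()
  for (t in fx$graph$terms$id) {
    ts <- term_similarity(fx$graph, fx$ic, t, t)
    expect_equal(ts$distance, 0)
    expect_equal(ts$similarity, 1)
  }
  f <- fork_graph()
  ic <- make_ic(A = 0, B = 1, C = 1)
  ts <- term_similarity(f, ic, "B", "C")
  expect_equal(ts$distance, Inf)
  expect_equal(ts$similarity, 0)
})

test_that("term distance matches exhaustive enumeration on random DAGs", {
  for (seed in 1:30) {
    n <- c(6L, 9L, 12L)[(seed %% 3L) + 1L]
    g <- random_rdag(n, seed = seed + 500L)
    ic <- compute_ic(random_corpus(g, n_genes = 6L, seed = seed + 600L), g)
    ids <- g$terms$id
    pairs <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(pairs))) {
      t1 <- pairs[1L, k]; t2 <- pairs[2L, k]
      d <- term_distance(g, ic, t1, t2)$distance
      expect_equal(d, o_term_distance(g, ic, t1, t2), tolerance = 1e-9,
                   info = sprintf("seed %d pair (%s, %s)", seed, t1, t2))
    }
  }
})

test_that("term similarity is symmetric and within range on random fixtures", {
  for (seed in 1:10) {
    g <- random_rdag(10L, seed = seed + 40L)
    ic <- compute_ic(random_corpus(g, n_genes = 6L, seed = seed + 50L), g)
    ids <- g$terms$id
    pairs <- utils::combn(ids, 2L)[, seq_len(min(10L, choose(length(ids), 2L)))]
    for (k in seq_len(ncol(pairs))) {
      a <- term_similarity(g, ic, pairs[1L, k], pairs[2L, k])
      b <- term_similarity(g, ic, pairs[2L, k], pairs[1L, k])
      expect_equal(a$similarity, b$similarity, tolerance = 1e-12)
      expect_gte(a$similarity, 0)
      expect_lte(a$similarity, 1)
      expect_gte(a$distance, 0)
    }
  }
})

test_that("rcmax/avg/bma aggregate the similarity matrix per their formulas", {
  S <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(topoicsim:::aggregate_matrix(S, "rcmax"), 1)
  expect_equal(topoicsim:::aggregate_matrix(S, "avg"), 0.5)
  expect_equal(topoicsim:::aggregate_matrix(S, "bma"), 1)
  withr::with_seed(11, {
    S <- matrix(stats::runif(6), 3, 2)
  })
  expect_equal(topoicsim:::aggregate_matrix(S, "rcmax"),
               max(mean(apply(S, 1, max)), mean(apply(S, 2, max))))
  expect_equal(topoicsim:::aggregate_matrix(S, "bma"),
               mean(c(mean(apply(S, 1, max)), mean(apply(S, 2, max)))))
})

test_that("gene similarity is 1 on identical genes and symmetric otherwise", {
  g <- random_rdag(15L, seed = 9)
  corpus <- random_corpus(g, n_genes = 5L, k_max = 4L, seed = 9)
  ic <- compute_ic(corpus, g)
  genes <- corpus_genes(corpus)
  expect_equal(gene_similarity(g, ic, corpus, genes[1], genes[1], "BP"), 1)
  s12 <- gene_similarity(g, ic, corpus, genes[1], genes[2], "BP")
  s21 <- gene_similarity(g, ic, corpus, genes[2], genes[1], "BP")
  expect_equal(s12, s21, tolerance = 1e-12)
  expect_error(gene_similarity(g, ic, corpus, "ghost", genes[1], "BP"),
               "not in corpus")
})

test_that("pairwise matrix is cache-consistent with uncached recomputation", {
  g <- random_rdag(15L, seed = 21)
  corpus <- random_corpus(g, n_genes = 5L, k_max = 5L, seed = 21)
  ic <- compute_ic(corpus, g)
  genes <- corpus_genes(corpus)
  M <- pairwise_gene_similarity(g, ic, corpus, genes, "BP")
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, length(genes)))
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      expect_equal(M[i, j],
                   gene_similarity(g, ic, corpus, genes[i], genes[j], "BP"),
                   tolerance = 1e-12)
    }
  }
})

test_that("shared caches leave results identical", {
  g <- random_rdag(12L, seed = 33)
  corpus <- random_corpus(g, n_genes = 4L, seed = 33)
  ic <- compute_ic(corpus, g)
  cache <- similarity_cache()
  genes <- corpus_genes(corpus)
  a1 <- gene_similarity(g, ic, corpus, genes[1], genes[2], "BP", cache = cache)
  a2 <- gene_similarity(g, ic, corpus, genes[1], genes[2], "BP", cache = cache)
  a3 <- gene_similarity(g, ic, corpus, genes[1], genes[2], "BP")
  expect_identical(a1, a2)
  expect_equal(a1, a3, tolerance = 1e-12)
})
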