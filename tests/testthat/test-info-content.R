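test_that("information content follows -log(G_t / G_Tot)", {
  g <- chain_graph()
  corpus <- make_corpus(list(g1 = "C", g2 = "B", g3 = "B", g4 = "B", g5 = "B",
                             g6 = "B", g7 = "B", g8 = "B", g9 = "B", g10 = "B"))
  ic <- compute_ic(corpus, g, propagate = FALSE)
  expect_equal(unname(ic$ic[["C"]]), -log(0.1))
  expect_equal(unname(ic$ic[["A"]]), Inf)  # nothing annotated directly to the root

  ic_p <- compute_ic(corpus, g)
  expect_equal(unname(ic_p$ic[["A"]]), 0)  # all genes propagate to the root
})

test_that("propagated counts follow hand propagation on a chain", {
  g <- chain_graph()
  corpus <- make_corpus(list(g1 = "C", g2 = "B"))
  ic <- compute_ic(corpus, g)
  # counts: C = 1, B = 2, A = 2 with G_Tot = 2
  expect_equal(unname(ic$ic[["C"]]), -log(1 / 2))
  expect_equal(unname(ic$ic[["B"]]), 0)
  expect_equal(unname(ic$ic[["A"]]), 0)
})

test_that("log base rescales IC", {
  g <- chain_graph()
  corpus <- make_corpus(list(g1 = "C", g2 = "B"))
  ic_e <- compute_ic(corpus, g)
  ic_2 <- compute_ic(corpus, g, log_base = 2)
  expect_equal(unname(ic_2$ic[["C"]]), unname(ic_e$ic[["C"]]) / log(2))
  expect_error(compute_ic(corpus, g, log_base = 1), "log_base")
})

test_that("IC is monotone along edges under propagation", {
  for (seed in 1:10) {
    g <- random_rdag(15L, seed = seed)
    ic <- compute_ic(random_corpus(g, n_genes = 8L, seed = seed), g)
    for (k in seq_len(nrow(g$edges))) {
      child_ic <- ic$ic[[g$edges$child[k]]]
      parent_ic <- ic$ic[[g$edges$parent[k]]]
      expect_gte(child_ic, parent_ic - 1e-12)
    }
  }
})

test_that("path IIC sums inverse IC excluding root, zero and infinite terms", {
  ic <- make_ic(A = 0, B = 2.0, C = 4.0, D = Inf)
  expect_equal(path_iic("B", ic, root = "A"), 0.5)
  expect_equal(path_iic(c("B", "C"), ic, root = "A"), 0.75)
  expect_equal(path_iic(c("D", "B", "A"), ic, root = "A"), 0.5)
  # reference root path: nodes with IC 1.329 and 0.407, root excluded
  ic2 <- make_ic(x = 1.329, r = 0.407, root = 0)
  expect_equal(path_iic(c("x", "r", "root"), ic2, root = "root"),
               1 / 1.329 + 1 / 0.407, tolerance = 1e-12)
})

test_that("IIC-weighted shortest path prefers high-IC interior nodes", {
  d <- diamond_graph()
  ic <- make_ic(A = 0, B = 5.0, C = 1.0, D = 2.0)
  sp <- weighted_shortest_path(d, ic, "D", "A")
  expect_identical(sp$path, c("D", "B", "A"))  # 1/5 < 1/1
  expect_equal(sp$iic, 1 / 2 + 1 / 5)
  expect_equal(sp$weighted, sp$iic * 2)

  g <- chain_graph()
  icc <- make_ic(A = 0, B = 1, C = 1)
  expect_identical(weighted_shortest_path(g, icc, "C", "A")$path, c("C", "B", "A"))
})

test_that("IIC-weighted longest path to root maximises IIC", {
  fx <- metabolism_fixture()
  lp <- weighted_longest_path(fx$graph, fx$ic, "GO:0044237")
  expect_identical(lp$path, c("GO:0044237", "GO:0009987", "GO:0008150"))
  expect_equal(lp$weighted, (1 / 1.329 + 1 / 0.407) * 2, tolerance = 1e-9)
})

test_that("weighted path selection matches exhaustive enumeration on random DAGs", {
  for (seed in 1:40) {
    n <- c(6L, 9L, 12L)[(seed %% 3L) + 1L]
    g <- random_rdag(n, seed = seed)
    ic <- compute_ic(random_corpus(g, n_genes = 7L, seed = seed + 100L), g)
    ids <- g$terms$id
    t <- ids[length(ids)]
    for (x in c(t, term_ancestors(g, t))) {
      sp <- weighted_shortest_path(g, ic, t, x)
      osp <- o_wsp(g, ic, t, x)
      expect_equal(sp$iic, osp$iic, tolerance = 1e-9)
      expect_equal(sp$length, osp$length)
    }
    lp <- weighted_longest_path(g, ic, t)
    olp <- o_wlp(g, ic, t)
    expect_equal(lp$iic, olp$iic, tolerance = 1e-9)
    expect_equal(lp$length, olp$length)
  }
})
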