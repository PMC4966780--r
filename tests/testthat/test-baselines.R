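test_that("LCA info reports the deepest common ancestor and its path length", {
  g <- chain_graph()
  li <- lca_info(g, "C", "C")
  expect_identical(li$lca, "C")
  expect_equal(li$min_spl, 0)
  f <- fork_graph()
  li <- lca_info(f, "B", "C")
  expect_identical(li$lca, "A")
  expect_equal(li$depth, 0L)
  expect_equal(li$min_spl, 2)
  for (seed in 1:15) {
    g <- random_rdag(10L, seed = seed + 70L)
    ids <- g$terms$id
    t1 <- ids[(seed %% 9L) + 2L]
    t2 <- ids[((seed + 4L) %% 9L) + 2L]
    li <- lca_info(g, t1, t2)
    expect_identical(li$lca, o_lca(g, t1, t2))
    expect_equal(li$depth, o_depth(g, li$lca))
    expect_equal(li$min_spl, o_min_spl(g, t1, t2, li$lca))
  }
})

test_that("IntelliGO basis dot products and cosine behave per the vector model", {
  # Depth(LCA) = 2, MinSPL = 2 -> e_i . e_j = 4/6
  g <- ontology_graph(
    data.frame(id = c("A", "B", "C", "D", "E"), name = letters[1:5], aspect = "BP"),
    data.frame(child = c("B", "C", "D", "E"), parent = c("A", "B", "C", "C"),
               relation = "is_a")
  )
  expect_equal(topoicsim:::intelligo_basis_dot(g, "D", "E"),
               (2 * 2) / (2 + 2 * 2))
  expect_equal(topoicsim:::intelligo_basis_dot(g, "D", "D"), 1)

  corpus <- make_corpus(list(g1 = c("D", "E"), g2 = c("D", "E"), g3 = "B"))
  expect_equal(sim_intelligo(g, corpus, "g1", "g2", "BP"), 1)
  g13 <- sim_intelligo(g, corpus, "g1", "g3", "BP")
  expect_gte(g13, 0)
  expect_lte(g13, 1)
  expect_equal(g13, sim_intelligo(g, corpus, "g3", "g1", "BP"), tolerance = 1e-12)
})

test_that("Wang semantic contributions follow the recursive max rule", {
  g <- chain_graph()
  sv <- wang_s_values(g, "C")
  expect_equal(unname(sv$s[c("C", "B", "A")]), c(1, 0.8, 0.64))
  expect_equal(sv$sv, 2.44)
  root_only <- wang_s_values(g, "A")
  expect_equal(root_only$sv, 1)
  expect_error(wang_s_values(g, "C", w_is_a = 1.2), "weights")

  for (seed in 1:15) {
    g <- random_rdag(10L, seed = seed + 90L)
    t <- g$terms$id[10L]
    sv <- wang_s_values(g, t)
    for (x in names(sv$s)) {
      expect_equal(unname(sv$s[[x]]), o_wang_s(g, t, x), tolerance = 1e-12,
                   info = sprintf("seed %d ancestor %s", seed, x))
    }
  }
})

test_that("Wang gene similarity: identity, symmetry, and a hand-computed fork", {
  f <- fork_graph()
  corpus <- make_corpus(list(g1 = "B", g2 = "C", g3 = "B"))
  expect_equal(sim_wang(f, corpus, "g1", "g3", "BP"), 1)
  # disjoint leaves share only the root: S = (0.8 + 0.8) / (1.8 + 1.8)
  expect_equal(sim_wang(f, corpus, "g1", "g2", "BP"), 1.6 / 3.6, tolerance = 1e-12)
  expect_equal(sim_wang(f, corpus, "g1", "g2", "BP"),
               sim_wang(f, corpus, "g2", "g1", "BP"), tolerance = 1e-12)
})

test_that("Resnik is the LCA's IC and Lord averages it over the grid", {
  f <- fork_graph()
  corpus <- make_corpus(list(g1 = "B", g2 = "C"))
  ic <- compute_ic(corpus, f)
  expect_equal(sim_resnik(f, ic, "B", "C"), 0)  # LCA is the root
  expect_equal(sim_resnik(f, ic, "B", "B"), unname(ic$ic[["B"]]))
  # 1 x 2 grid by hand
  g <- chain_graph()
  corpus <- make_corpus(list(g1 = "C", g2 = c("B", "C")))
  ic <- compute_ic(corpus, g)
  expected <- mean(c(unname(ic$ic[["C"]]), unname(ic$ic[["B"]])))
  expect_equal(sim_lord(g, ic, corpus, "g1", "g2", "BP"), expected, tolerance = 1e-12)
  expect_equal(sim_lord(g, ic, corpus, "g1", "g2", "BP"),
               sim_lord(g, ic, corpus, "g2", "g1", "BP"))
})

test_that("Al-Mubaid converts mean shortest path lengths with exp(-0.2 PL)", {
  f <- fork_graph()
  corpus <- make_corpus(list(g1 = "B", g2 = "C", g3 = "B"))
  expect_equal(sim_mubaid(f, corpus, "g1", "g3", "BP"), 1)  # PL = 0
  expect_equal(sim_mubaid(f, corpus, "g1", "g2", "BP"), exp(-0.2 * 2))
  expect_equal(sim_mubaid(f, corpus, "g1", "g2", "BP", alpha = 0.5), exp(-0.5 * 2))
  for (seed in 1:10) {
    g <- random_rdag(10L, seed = seed + 110L)
    ids <- g$terms$id
    t1 <- ids[(seed %% 9L) + 2L]
    t2 <- ids[((seed + 5L) %% 9L) + 2L]
    expect_equal(topoicsim:::min_path_length(g, t1, t2), o_mubaid_pl(g, t1, t2))
  }
})

test_that("SimGIC is the IC-weighted Jaccard over ancestor closures", {
  g <- chain_graph()
  corpus <- make_corpus(list(g1 = "C", g2 = "C", g3 = "B"))
  ic <- make_ic(A = 0, B = 1, C = 2)
  expect_equal(sim_simgic(g, ic, corpus, "g1", "g2", "BP"), 1)
  # closures: g1 -> {C,B,A}, g3 -> {B,A}; intersection IC sum 1, union 3
  expect_equal(sim_simgic(g, ic, corpus, "g1", "g3", "BP"), 1 / 3, tolerance = 1e-12)
  # all-zero union is defined as 0
  ic0 <- make_ic(A = 0, B = 0, C = 0)
  expect_equal(sim_simgic(g, ic0, corpus, "g1", "g3", "BP"), 0)
})

test_that("all five baseline measures are symmetric and bounded on random fixtures", {
  for (seed in 1:8) {
    g <- random_rdag(12L, seed = seed + 130L)
    corpus <- random_corpus(g, n_genes = 4L, k_max = 4L, seed = seed + 140L)
    ic <- compute_ic(corpus, g)
    genes <- corpus_genes(corpus)
    g1 <- genes[1L]; g2 <- genes[2L]
    for (m in c("intelligo", "wang", "lord", "mubaid", "simgic")) {
      f <- topoicsim:::measure_function(g, ic, corpus, "BP", m)
      a <- f(g1, g2); b <- f(g2, g1)
      expect_equal(a, b, tolerance = 1e-9, info = paste(m, seed))
      expect_gte(a, 0)
      if (m %in% c("intelligo", "wang", "mubaid", "simgic")) expect_lte(a, 1 + 1e-12)
    }
  }
})
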