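test_that("IntraSet/InterSet means include self-pairs and match direct loops", {
  expect_equal(intraset_similarity(matrix(1, 1, 1)), 1)
  m <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(intraset_similarity(m), 0.75)
  expect_error(intraset_similarity(matrix(numeric(0), 0, 0)), "empty")

  expect_equal(interset_similarity(matrix(1, 1, 1)), 1)
  expect_equal(interset_similarity(matrix(0, 3, 2)), 0)

  withr::with_seed(5, m4 <- matrix(stats::runif(16), 4, 4))
  direct <- 0
  for (i in 1:4) for (j in 1:4) direct <- direct + m4[i, j]
  expect_equal(intraset_similarity(m4), direct / 16)
  expect_equal(interset_similarity(m4[, 1:2]), sum(m4[, 1:2]) / 8)
})

test_that("DP and IDP follow their definitions", {
  intra <- c(a = 0.8, b = 0.8, c = 0.8)
  inter <- matrix(0.8, 3, 3)
  dp <- discriminating_power(intra, inter)
  expect_equal(unname(dp), rep(1, 3))  # statistically identical sets
  expect_equal(unname(idp_scores(intra, dp)), rep(0.8, 3))

  # p = 2 reduces to an Intra/Inter ratio
  intra2 <- c(a = 0.9, b = 0.6)
  inter2 <- matrix(c(0.9, 0.3, 0.3, 0.6), 2, 2)
  dp2 <- discriminating_power(intra2, inter2)
  expect_equal(unname(dp2), c(0.9 / 0.3, 0.6 / 0.3))
  expect_error(discriminating_power(c(a = 1), matrix(1, 1, 1)), "at least two")
  inter_z <- matrix(c(1, 0, 0, 0, 1, 0.5, 0, 0.5, 1), 3, 3)
  expect_warning(dp0 <- discriminating_power(c(0.5, 0.5, 0.5), inter_z), "Inf")
  expect_equal(unname(dp0[1]), Inf)

  withr::with_seed(8, {
    intra3 <- stats::runif(3)
    inter3 <- matrix(stats::runif(9), 3, 3)
  })
  dp3 <- discriminating_power(intra3, inter3)
  for (k in 1:3) {
    expect_equal(dp3[k], 2 * intra3[k] / sum(inter3[k, -k]))
  }
})

test_that("gene-set evaluation ties interset diagonal to intraset", {
  g <- random_rdag(15L, seed = 61)
  corpus <- random_corpus(g, n_genes = 9L, k_max = 4L, seed = 61)
  ic <- compute_ic(corpus, g)
  genes <- corpus_genes(corpus)
  sets <- list(s1 = genes[1:3], s2 = genes[4:6], s3 = genes[7:9])
  rep <- eval_gene_sets(g, ic, corpus, sets, "BP")
  expect_equal(unname(diag(rep$interset)), unname(rep$intraset))
  expect_true(isSymmetric(rep$interset))
  expect_equal(rep$idp, rep$intraset * rep$dp)
  rep1 <- eval_gene_sets(g, ic, corpus, sets["s1"], "BP")
  expect_true(is.na(rep1$dp[["s1"]]))
})

test_that("distance correlation hits the analytic anchors", {
  x <- c(1, 2, 5, 9)
  expect_equal(distance_correlation(x, x)$dcor, 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, rep(3, 4))$dcor, 0)
  expect_error(distance_correlation(x, 1:3), "same number")
  expect_error(distance_correlation(1, 2), "n >= 2")
})

test_that("distance correlation matches the brute-force triple loop and the
           double-centered formulation", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- 4L + seed
      x <- stats::rnorm(n)
      y <- if (seed %% 2L) stats::rnorm(n) else x + stats::rnorm(n, sd = 0.3)
      xm <- matrix(stats::rnorm(2 * n), n, 2)
    })
    dc <- distance_correlation(x, y)
    expect_equal(dc$dcov2, max(o_dcov2(x, y), 0), tolerance = 1e-10)
    expect_equal(dc$dcor, o_dcor(x, y), tolerance = 1e-10)
    expect_equal(dc$dcov2, max(o_dcov2_centered(x, y), 0), tolerance = 1e-10)
    dc2 <- distance_correlation(xm, y)
    expect_equal(dc2$dcov2, max(o_dcov2(xm, y), 0), tolerance = 1e-10)
  }
})

test_that("dcor is invariant to translation and orthogonal rotation", {
  withr::with_seed(17, {
    x <- matrix(stats::rnorm(40), 20, 2)
    y <- matrix(stats::rnorm(40), 20, 2) + 0.5 * x
    theta <- 0.7
  })
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  base <- distance_correlation(x, y)$dcor
  expect_equal(distance_correlation(x + 5, y - 2)$dcor, base, tolerance = 1e-10)
  expect_equal(distance_correlation(x %*% R, y)$dcor, base, tolerance = 1e-10)
  expect_gte(base, 0)
  expect_lte(base, 1)
})

test_that("grouped correlation recovers the obvious limits", {
  perfect <- data.frame(r = 1:60, s = (1:60) * 2)
  expect_equal(grouped_correlation(perfect, "quantile", n_groups = 4L)$estimate, 1)
  withr::with_seed(3, noise <- data.frame(r = stats::rnorm(200), s = stats::rnorm(200)))
  res <- grouped_correlation(noise, "quantile", n_groups = 4L, min_group_corr = 0.9)
  expect_true(is.na(res$estimate))
  expect_error(grouped_correlation(data.frame(r = 1, s = 1), "quantile", n_groups = 5L),
               "smaller than")
})

test_that("grouped correlation accepts grid and injected groupings", {
  pairs <- correlated_pairs(400L, within_cluster_r = 0.8, n_clusters = 3L, seed = 5)
  res_grid <- suppressWarnings(
    grouped_correlation(pairs, "grid", n_groups = 3L, min_group_corr = 0.5))
  expect_false(is.na(res_grid$estimate))
  # injecting the true cluster labels recovers the known within-cluster correlation
  res_inj <- grouped_correlation(pairs, grouping = function(p) pairs$cluster,
                                 min_group_corr = 0.5)
  expect_equal(res_inj$estimate, 0.8, tolerance = 0.1)
})

test_that("length-bias audit reports the convention limits", {
  g <- random_rdag(40L, seed = 71)
  ic <- compute_ic(random_corpus(g, n_genes = 10L, seed = 71), g)
  res_const <- length_bias_audit(g, ic, measure = function(a, b) 0.5,
                                 sizes = 1:5, n_pairs = 10L, seed = 1)
  expect_equal(res_const$spearman_r, 0)
  expect_equal(res_const$p_value, 1)
  res_size <- length_bias_audit(g, ic, measure = function(a, b) length(a),
                                sizes = 1:5, n_pairs = 10L, seed = 1)
  expect_equal(res_size$spearman_r, 1)
})
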