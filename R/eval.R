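# Benchmark statistics: IntraSet/InterSet similarity, discriminating power
# (DP), IntraSet discriminating power (IDP), the empirical distance
# correlation, grouped expression-vs-annotation correlation, and the
# annotation-length-bias audit.

#' IntraSet similarity
#'
#' Mean of all n^2 pairwise gene similarities within one set, self-pairs
#' included (the n^2 denominator is deliberate).
#'
#' @param m square similarity matrix for the set's genes.
#' @return Numeric scalar.
#' @export
intraset_similarity <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty gene set")
  if (nrow(m) != ncol(m)) stop("IntraSet similarity needs a square matrix")
  mean(m)
}

#' InterSet similarity
#'
#' Grand mean of the n x m cross-similarities between two gene sets.
#'
#' @param m cross-similarity matrix (rows: first set, columns: second set).
#' @return Numeric scalar.
#' @export
interset_similarity <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty gene set")
  mean(m)
}

#' Discriminating power of each gene set
#'
#' DP(S_k) = (p - 1) * IntraSet(S_k) / sum over l != k of InterSet(S_k, S_l).
#' A collection of statistically identical sets has DP near 1 for every set.
#'
#' @param intraset numeric vector of per-set IntraSet similarities (length p >= 2).
#' @param interset symmetric p x p InterSet matrix (its diagonal is ignored).
#' @return Named numeric vector of per-set DP values (`Inf` with a warning on
#'   a zero denominator).
#' @export
discriminating_power <- function(intraset, interset) {
  p <- length(intraset)
  if (p < 2L) stop("discriminating power needs at least two sets")
  interset <- as.matrix(interset)
  stopifnot(nrow(interset) == p, ncol(interset) == p)
  dp <- vapply(seq_len(p), function(k) {
    denom <- sum(interset[k, -k])
    if (denom == 0) {
      warning("zero InterSet denominator for set ", k, "; DP set to Inf")
      return(Inf)
    }
    (p - 1) * intraset[k] / denom
  }, numeric(1))
  stats::setNames(dp, names(intraset))
}

#' IntraSet discriminating power
#'
#' IDP(S_k) = IntraSet(S_k) * DP(S_k): high when a measure is both cohesive
#' within a set and discriminative against the others.
#'
#' @param intraset numeric vector of per-set IntraSet similarities.
#' @param dp matching [discriminating_power()] vector.
#' @return Named numeric vector.
#' @export
idp_scores <- function(intraset, dp) {
  stopifnot(length(intraset) == length(dp))
  stats::setNames(intraset * dp, names(intraset))
}

#' Evaluate a gene-set collection with one similarity measure
#'
#' Computes the full pairwise gene-similarity matrix once (with caching) and
#' derives per-set IntraSet similarity, the p x p InterSet matrix (whose
#' diagonal equals the IntraSet values), DP and IDP.
#'
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param corpus an [annotation_corpus()].
#' @param sets named list of gene-id vectors (no empty set).
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @param measure,aggregator,on_missing passed to [pairwise_gene_similarity()].
#' @return An object of class `eval_report`: list with `intraset`, `interset`,
#'   `dp`, `idp` (the latter two `NA` when only one set is given).
#' @export
eval_gene_sets <- function(graph, ic, corpus, sets, aspect,
                           measure = "topoicsim", aggregator = "rcmax",
                           on_missing = "fail") {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  if (any(vapply(sets, length, integer(1)) == 0L)) stop("empty gene set")
  genes <- unique(unlist(sets, use.names = FALSE))
  M <- pairwise_gene_similarity(graph, ic, corpus, genes, aspect,
                                measure = measure, aggregator = aggregator,
                                on_missing = on_missing)
  sets <- lapply(sets, function(s) intersect(s, rownames(M)))
  if (any(vapply(sets, length, integer(1)) == 0L)) {
    stop("a gene set lost all its genes to the missing-annotation filter")
  }
  p <- length(sets)
  labels <- names(sets)
  intraset <- stats::setNames(vapply(sets, function(s) {
    intraset_similarity(M[s, s, drop = FALSE])
  }, numeric(1)), labels)
  interset <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  for (k in seq_len(p)) {
    for (l in seq_len(p)) {
      interset[k, l] <- interset_similarity(M[sets[[k]], sets[[l]], drop = FALSE])
    }
  }
  if (p >= 2L) {
    dp <- discriminating_power(intraset, interset)
    idp <- idp_scores(intraset, dp)
  } else {
    dp <- idp <- stats::setNames(NA_real_, labels)
  }
  structure(list(intraset = intraset, interset = interset, dp = dp, idp = idp,
                 measure = measure),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (", x$measure, "), ", length(x$intraset), " set(s)\n", sep = "")
  print(data.frame(set = names(x$intraset), intraset = x$intraset,
                   dp = x$dp, idp = x$idp, row.names = NULL))
  invisible(x)
}

#' Empirical distance correlation
#'
#' Energy-statistics estimator from pairwise Euclidean distances:
#' dcov^2 = S1 + S2 - 2 S3 with S1 the mean of the elementwise distance
#' products, S2 the product of the two mean distances, and S3 the mean over k
#' of the two row-mean products. dcor divides by the marginal terms; it is 0
#' whenever either marginal dcov^2 is 0 (e.g. a constant sample). Negative
#' dcov^2 from floating error near 0 is clamped to 0 before the square roots.
#'
#' @param x,y numeric vectors or matrices with the same number of
#'   observations (rows); n >= 2. Dimensions may differ between x and y.
#' @return A list with `dcov2` and `dcor` (both in `[0, 1]` for `dcor`).
#' @export
distance_correlation <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same number of observations")
  if (n < 2L) stop("distance correlation needs n >= 2")
  A <- as.matrix(stats::dist(x))
  B <- as.matrix(stats::dist(y))
  dc2 <- function(A, B) {
    s1 <- sum(A * B) / n^2
    s2 <- (sum(A) / n^2) * (sum(B) / n^2)
    s3 <- sum(rowSums(A) * rowSums(B)) / n^3
    s1 + s2 - 2 * s3
  }
  vxy <- max(dc2(A, B), 0)
  vxx <- max(dc2(A, A), 0)
  vyy <- max(dc2(B, B), 0)
  dcor <- if (vxx == 0 || vyy == 0) 0 else sqrt(vxy) / (sqrt(sqrt(vxx)) * sqrt(sqrt(vyy)))
  list(dcov2 = vxy, dcor = min(1, dcor))
}

#' Grouped correlation between expression and annotation similarity
#'
#' Deterministic stand-in for SOM clustering of (r, s) pairs: partitions the
#' sample into groups (quantile bins on r, a fixed 2-D grid on (r, s), or an
#' arbitrary grouping function), computes the within-group correlation, and
#' averages the groups whose correlation reaches `min_group_corr`. Degenerate
#' (constant or too-small) groups are skipped with a warning.
#'
#' @param pairs data.frame with numeric columns `r` (expression similarity)
#'   and `s` (annotation similarity).
#' @param grouping `"quantile"`, `"grid"`, or a function of the pairs
#'   data.frame returning group labels (e.g. an injected SOM).
#' @param n_groups number of quantile bins, or cells per axis for the grid.
#' @param method within-group correlation: `"pearson"`, `"spearman"`, or
#'   `"dcor"`.
#' @param min_group_corr only groups with correlation at or above this enter
#'   the average (the >= 0.5 rule by default).
#' @return A list with `estimate` (`NA` when no group qualifies) and a
#'   `groups` data.frame (group, n, correlation, used).
#' @export
grouped_correlation <- function(pairs, grouping = c("quantile", "grid"),
                                n_groups = 6L, method = c("pearson", "spearman", "dcor"),
                                min_group_corr = 0.5) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs), all(c("r", "s") %in% names(pairs)))
  if (!all(is.finite(pairs$r)) || !all(is.finite(pairs$s))) {
    stop("pairs must contain finite values only")
  }
  if (nrow(pairs) < n_groups) stop("sample smaller than the number of groups")

  labels <- if (is.function(grouping)) {
    as.character(grouping(pairs))
  } else {
    grouping <- match.arg(grouping)
    if (grouping == "quantile") {
      brk <- unique(stats::quantile(pairs$r, probs = seq(0, 1, length.out = n_groups + 1L)))
      as.character(cut(pairs$r, breaks = brk, include.lowest = TRUE))
    } else {
      cell <- function(v) {
        brk <- unique(seq(min(v), max(v), length.out = n_groups + 1L))
        if (length(brk) < 2L) rep(1L, length(v)) else
          as.integer(cut(v, breaks = brk, include.lowest = TRUE))
      }
      paste(cell(pairs$r), cell(pairs$s), sep = ":")
    }
  }

  groups <- split(pairs[, c("r", "s")], labels)
  res <- data.frame(group = names(groups),
                    n = vapply(groups, nrow, integer(1)),
                    correlation = NA_real_, used = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (nrow(g) < 3L || stats::sd(g$r) == 0 || stats::sd(g$s) == 0) {
      warning("skipping degenerate group ", names(groups)[k],
              " (n = ", nrow(g), ")")
      next
    }
    res$correlation[k] <- switch(method,
      pearson = stats::cor(g$r, g$s),
      spearman = stats::cor(g$r, g$s, method = "spearman"),
      dcor = distance_correlation(g$r, g$s)$dcor)
  }
  res$used <- !is.na(res$correlation) & res$correlation >= min_group_corr
  estimate <- if (any(res$used)) mean(res$correlation[res$used]) else NA_real_
  list(estimate = estimate, groups = res)
}

#' Annotation-length-bias audit
#'
#' Draws random pairs of equal-sized term groups for each group size, scores
#' them with a term-set similarity measure, and reports the Spearman rank
#' correlation between group size and the per-size mean score (a strongly
#' length-biased measure approaches r = 1). A constant measure is reported as
#' r = 0 with p = 1 by convention. Optional bootstrap (resampling scores
#' within each size) yields a percentile confidence interval for r.
#'
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param measure a function of two character vectors of term ids returning a
#'   similarity; `NULL` uses TopoICSim with rcmax aggregation and a shared
#'   cache.
#' @param sizes integer group sizes to audit (default 1..10).
#' @param n_pairs random group pairs per size.
#' @param seed RNG seed; the draw is a pure function of it.
#' @param n_boot bootstrap replicates for the CI (0 disables).
#' @param conf_level bootstrap CI coverage.
#' @return A list with `spearman_r`, `p_value`, a `per_size` data.frame and
#'   optionally `boot_ci`.
#' @export
length_bias_audit <- function(graph, ic, measure = NULL, sizes = 1:10,
                              n_pairs = 100L, seed = 1L, n_boot = 0L,
                              conf_level = 0.95) {
  terms <- graph$terms$id
  if (length(terms) < max(sizes)) {
    stop("graph has fewer terms (", length(terms), ") than the largest group size")
  }
  if (is.null(measure)) {
    cache <- similarity_cache()
    measure <- function(a, b) term_set_similarity(graph, ic, a, b, cache = cache)
  }
  scores <- withr::with_seed(seed, {
    lapply(sizes, function(k) {
      vapply(seq_len(n_pairs), function(i) {
        a <- terms[sample.int(length(terms), k)]
        b <- terms[sample.int(length(terms), k)]
        measure(a, b)
      }, numeric(1))
    })
  })
  per_size <- data.frame(size = sizes,
                         mean_score = vapply(scores, mean, numeric(1)))
  spear <- function(ms) {
    if (stats::sd(ms) == 0 || stats::sd(sizes) == 0) 0 else
      stats::cor(sizes, ms, method = "spearman")
  }
  r <- spear(per_size$mean_score)
  p <- if (r == 0 && stats::sd(per_size$mean_score) == 0) 1 else {
    suppressWarnings(stats::cor.test(sizes, per_size$mean_score,
                                     method = "spearman")$p.value)
  }
  out <- list(spearman_r = unname(r), p_value = unname(p), per_size = per_size)
  if (n_boot > 0L) {
    boot_r <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_boot), function(b) {
        spear(vapply(scores, function(s) mean(s[sample.int(length(s), replace = TRUE)]),
                     numeric(1)))
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    out$boot_ci <- unname(stats::quantile(boot_r, c(alpha, 1 - alpha)))
  }
  out
}
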