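# TopoICSim: term distance as the ratio of the IIC-weighted shortest path
# between two terms through a disjunctive common ancestor to the IIC-weighted
# longest path from that ancestor to the aspect root, minimised over all
# disjunctive common ancestors, then mapped to [0, 1] with arctan.

#' Memoisation cache for term-pair similarities
#'
#' Pass the same cache to repeated [term_similarity()] /
#' [term_set_similarity()] / [gene_similarity()] calls over one
#' (graph, IC table) pair so each unordered term pair is computed once.
#' Gene-level workloads are quadratic in annotations, so this matters.
#'
#' @return An environment used as a key-value store.
#' @export
similarity_cache <- function() new.env(parent = emptyenv())

pair_key <- function(t1, t2) {
  if (t1 <= t2) paste(t1, t2, sep = "\r") else paste(t2, t1, sep = "\r")
}

#' Term distance through one disjunctive common ancestor
#'
#' D(t1, t2, x) = wSP(t1, t2, x) / wLP(x, root). The combined shortest path
#' runs up from t1 to the hinge x and down to t2; its IIC counts the hinge
#' once and its length is the sum of the two edge counts. When x is the
#' aspect root, wLP(x, root) = 0 and the distance is `+Inf`.
#'
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param t1,t2 term ids (same aspect).
#' @param ancestor a member of `disjunctive_common_ancestors(graph, t1, t2)`.
#' @return Non-negative numeric scalar, possibly `Inf`.
#' @export
term_distance_via_ancestor <- function(graph, ic, t1, t2, ancestor) {
  dca <- disjunctive_common_ancestors(graph, t1, t2)
  if (!ancestor %in% dca) {
    stop(ancestor, " is not a disjunctive common ancestor of ", t1, " and ", t2)
  }
  root <- aspect_root(graph, t1)
  sp1 <- weighted_shortest_path(graph, ic, t1, ancestor)
  sp2 <- weighted_shortest_path(graph, ic, t2, ancestor)
  hinge <- inv_ic_contrib(ic, ancestor, root)
  combined_iic <- sp1$iic + sp2$iic - hinge
  combined_len <- sp1$length + sp2$length
  wsp <- combined_iic * combined_len
  wlp <- weighted_longest_path(graph, ic, ancestor)$weighted
  if (wlp == 0) return(Inf)
  wsp / wlp
}

# internal: distance + argmin ancestor + the winning combined wSP (tie-break)
term_distance_impl <- function(graph, ic, t1, t2) {
  if (term_aspect(graph, t1) != term_aspect(graph, t2)) {
    stop("aspect mismatch: ", t1, " and ", t2)
  }
  if (t1 == t2) {
    return(list(distance = 0, ancestor = t1))
  }
  root <- aspect_root(graph, t1)
  dca <- disjunctive_common_ancestors(graph, t1, t2)
  if (identical(dca, root)) {
    return(list(distance = Inf, ancestor = root))
  }
  best <- NULL
  for (x in dca) {  # dca is sorted, so lexicographic tie-break is implicit
    sp1 <- weighted_shortest_path(graph, ic, t1, x)
    sp2 <- weighted_shortest_path(graph, ic, t2, x)
    wsp <- (sp1$iic + sp2$iic - inv_ic_contrib(ic, x, root)) *
      (sp1$length + sp2$length)
    wlp <- weighted_longest_path(graph, ic, x)$weighted
    d <- if (wlp == 0) Inf else wsp / wlp
    update <- if (is.null(best)) {
      TRUE
    } else if (is.infinite(d) || is.infinite(best$distance)) {
      # both infinite: fall back to the smaller combined weighted path
      is.infinite(best$distance) && (!is.infinite(d) || wsp < best$wsp - 1e-12)
    } else if (d < best$distance - 1e-12) {
      TRUE
    } else if (d > best$distance + 1e-12) {
      FALSE
    } else {
      wsp < best$wsp - 1e-12
    }
    if (update) best <- list(distance = d, ancestor = x, wsp = wsp)
  }
  best[c("distance", "ancestor")]
}

#' TopoICSim term distance
#'
#' Minimum of [term_distance_via_ancestor()] over all disjunctive common
#' ancestors. Identical terms have distance 0; pairs whose only disjunctive
#' common ancestor is the aspect root have distance `+Inf`. Ties between
#' ancestors break toward the smaller combined weighted shortest path, then
#' toward the lexicographically smaller ancestor id.
#'
#' @inheritParams term_distance_via_ancestor
#' @return A list with `t1`, `t2`, `distance`, and `ancestor` (the argmin
#'   disjunctive common ancestor).
#' @export
term_distance <- function(graph, ic, t1, t2) {
  r <- term_distance_impl(graph, ic, t1, t2)
  list(t1 = t1, t2 = t2, distance = r$distance, ancestor = r$ancestor)
}

#' Map a TopoICSim distance to a similarity in [0, 1]
#'
#' S = 1 - arctan(D) / (pi / 2); D = 0 maps to 1 and D = +Inf maps to 0, and
#' S is strictly decreasing in D.
#'
#' @param distance non-negative numeric (vectorised).
#' @return Numeric in `[0, 1]`.
#' @export
similarity_from_distance <- function(distance) {
  1 - atan(distance) / (pi / 2)
}

#' TopoICSim term similarity
#'
#' @inheritParams term_distance_via_ancestor
#' @param cache optional [similarity_cache()] for memoisation.
#' @return A list with `t1`, `t2`, `distance`, `similarity`, `ancestor`.
#' @export
term_similarity <- function(graph, ic, t1, t2, cache = NULL) {
  key <- pair_key(t1, t2)
  if (!is.null(cache)) {
    got <- cache[[key]]
    if (!is.null(got)) return(c(list(t1 = t1, t2 = t2), got))
  }
  r <- term_distance_impl(graph, ic, t1, t2)
  res <- list(distance = r$distance,
              similarity = similarity_from_distance(r$distance),
              ancestor = r$ancestor)
  if (!is.null(cache)) cache[[key]] <- res
  c(list(t1 = t1, t2 = t2), res)
}

aggregate_matrix <- function(S, aggregator = c("rcmax", "avg", "bma")) {
  aggregator <- match.arg(aggregator)
  row_max <- apply(S, 1L, max)
  col_max <- apply(S, 2L, max)
  switch(aggregator,
         rcmax = max(mean(row_max), mean(col_max)),
         avg = mean(S),
         bma = mean(c(mean(row_max), mean(col_max))))
}

#' Similarity matrix between two term sets
#'
#' Builds the n x m matrix of pairwise TopoICSim term similarities.
#'
#' @inheritParams term_similarity
#' @param terms1,terms2 character vectors of term ids (same aspect).
#' @return Numeric matrix with `terms1` as rows and `terms2` as columns.
#' @export
term_similarity_matrix <- function(graph, ic, terms1, terms2, cache = NULL) {
  stopifnot(length(terms1) >= 1L, length(terms2) >= 1L)
  S <- matrix(NA_real_, length(terms1), length(terms2),
              dimnames = list(terms1, terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      S[i, j] <- term_similarity(graph, ic, terms1[i], terms2[j], cache = cache)$similarity
    }
  }
  S
}

#' TopoICSim similarity between two term sets
#'
#' Aggregates the term-pair similarity matrix with `rcmax` (the default: the
#' larger of the row-maxima mean and the column-maxima mean), `avg` (grand
#' mean) or `bma` (mean of the two directional best-match averages).
#'
#' @inheritParams term_similarity_matrix
#' @param aggregator one of `"rcmax"`, `"avg"`, `"bma"`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
term_set_similarity <- function(graph, ic, terms1, terms2,
                                aggregator = "rcmax", cache = NULL) {
  aggregate_matrix(term_similarity_matrix(graph, ic, terms1, terms2, cache = cache),
                   aggregator)
}

#' TopoICSim similarity between two genes
#'
#' Collects each gene's annotation terms in the requested aspect and
#' aggregates the term-pair similarity matrix. Genes missing from the corpus,
#' or annotated only outside the aspect, raise an error (batch interfaces may
#' downgrade this to skip-with-warning).
#'
#' @inheritParams term_set_similarity
#' @param corpus an [annotation_corpus()].
#' @param g1,g2 gene ids.
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
gene_similarity <- function(graph, ic, corpus, g1, g2, aspect,
                            aggregator = "rcmax", cache = NULL) {
  t1 <- gene_terms(corpus, g1, graph, aspect)
  t2 <- gene_terms(corpus, g2, graph, aspect)
  term_set_similarity(graph, ic, t1, t2, aggregator = aggregator, cache = cache)
}

#' Pairwise gene-similarity matrix
#'
#' Symmetric matrix of gene-level similarities for any of the six measures.
#' Term-pair results (for TopoICSim) and per-term structures (for the
#' baselines) are cached so each unordered pair is computed once.
#'
#' @inheritParams gene_similarity
#' @param genes character vector of gene ids (>= 1).
#' @param measure one of `"topoicsim"`, `"intelligo"`, `"wang"`, `"lord"`,
#'   `"mubaid"`, `"simgic"`.
#' @param on_missing `"fail"` (default) raises on genes without annotations
#'   in the aspect; `"skip"` drops them with a warning.
#' @return Symmetric numeric matrix over the (retained) genes.
#' @export
pairwise_gene_similarity <- function(graph, ic, corpus, genes, aspect,
                                     measure = "topoicsim", aggregator = "rcmax",
                                     on_missing = c("fail", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(length(genes) >= 1L)
  genes <- as.character(genes)
  ok <- vapply(genes, function(g) {
    !inherits(try(gene_terms(corpus, g, graph, aspect), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!ok)) {
    if (on_missing == "fail") {
      gene_terms(corpus, genes[!ok][1L], graph, aspect)  # re-raise the informative error
    }
    warning("skipping ", sum(!ok), " gene(s) without usable annotations: ",
            paste(genes[!ok], collapse = ", "))
    genes <- genes[ok]
    if (length(genes) == 0L) stop("no genes left after skipping unannotated ones")
  }
  f <- measure_function(graph, ic, corpus, aspect, measure, aggregator)
  n <- length(genes)
  M <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- f(genes[i], genes[j])
    }
  }
  M
}

# closure dispatching a measure name to a gene-pair function, sharing caches
measure_function <- function(graph, ic, corpus, aspect, measure, aggregator = "rcmax") {
  measure <- match.arg(measure, c("topoicsim", "intelligo", "wang", "lord",
                                  "mubaid", "simgic"))
  cache <- similarity_cache()
  switch(measure,
    topoicsim = function(g1, g2) gene_similarity(graph, ic, corpus, g1, g2, aspect,
                                                 aggregator = aggregator, cache = cache),
    intelligo = {
      ifa <- compute_ic(corpus, graph)  # IFA(t) = log(G_Tot / G_t), the IC itself
      function(g1, g2) sim_intelligo(graph, corpus, g1, g2, aspect, ifa = ifa)
    },
    wang = function(g1, g2) sim_wang(graph, corpus, g1, g2, aspect, cache = cache),
    lord = function(g1, g2) sim_lord(graph, ic, corpus, g1, g2, aspect),
    mubaid = function(g1, g2) sim_mubaid(graph, corpus, g1, g2, aspect),
    simgic = function(g1, g2) sim_simgic(graph, ic, corpus, g1, g2, aspect)
  )
}
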