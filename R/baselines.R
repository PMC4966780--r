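# Comparison measures: IntelliGO (vector/cosine), Wang (semantic
# contributions), Resnik/Lord (IC of the LCA), Al-Mubaid (path length) and
# SimGIC (IC-weighted Jaccard over ancestor closures).

#' Lowest common ancestor information
#'
#' The LCA is the common ancestor of maximal depth, where depth is the length
#' in edges of the longest upward path to the aspect root (the specific-most
#' term); ties break lexicographically. `min_spl` is the shortest
#' `t1 -> LCA -> t2` path in edges.
#'
#' @param graph an [ontology_graph()].
#' @param t1,t2 term ids (same aspect).
#' @return A list with `lca`, `depth`, `min_spl`.
#' @export
lca_info <- function(graph, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  if (length(ca) == 0L) stop("no common ancestors for ", t1, " and ", t2)
  depths <- vapply(ca, function(x) term_depth(graph, x), integer(1))
  lca <- ca[depths == max(depths)][1L]  # ca is sorted -> lexicographic tie-break
  d1 <- shortest_up_lengths(graph, t1)
  d2 <- shortest_up_lengths(graph, t2)
  list(lca = lca, depth = max(depths),
       min_spl = unname(d1[[lca]] + d2[[lca]]))
}

# basis-vector dot product of the IntelliGO vector space
intelligo_basis_dot <- function(graph, ti, tj) {
  if (ti == tj) return(1)
  li <- lca_info(graph, ti, tj)
  if (li$depth == 0 && li$min_spl == 0) return(1)  # both terms are the root
  2 * li$depth / (li$min_spl + 2 * li$depth)
}

#' IntelliGO gene similarity
#'
#' Each gene is a vector sum over its annotation terms with coefficients
#' `w(g, t) * IFA(t)`; `w` is an evidence-code weight (uniform 1 by default)
#' and IFA the inverse annotation frequency `log(G_Tot / G_t)` with
#' propagated counts (equal to the natural-log information content, so
#' IFA(root) = 0). Basis dot products depend on the LCA depth and the
#' shortest inter-term path through the LCA; the gene similarity is the
#' cosine of the two vectors.
#'
#' @param graph an [ontology_graph()].
#' @param corpus an [annotation_corpus()].
#' @param g1,g2 gene ids.
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @param ec_weights optional named numeric, evidence code -> weight;
#'   unlisted codes get weight 1.
#' @param ifa optional precomputed [ic_table()] to use as IFA (natural-log IC
#'   of this corpus); computed on the fly when omitted.
#' @return Numeric scalar in `[0, 1]`.
#' @export
sim_intelligo <- function(graph, corpus, g1, g2, aspect, ec_weights = NULL,
                          ifa = NULL) {
  t1 <- gene_terms(corpus, g1, graph, aspect)
  t2 <- gene_terms(corpus, g2, graph, aspect)
  if (is.null(ifa)) ifa <- compute_ic(corpus, graph)

  coef <- function(gene, terms) {
    w <- rep(1, length(terms))
    if (!is.null(ec_weights)) {
      ann <- corpus$annotations
      for (k in seq_along(terms)) {
        codes <- ann$evidence[ann$gene == gene & ann$term == terms[k]]
        hit <- codes %in% names(ec_weights)
        if (any(hit)) w[k] <- max(ec_weights[codes[hit]])
      }
    }
    v <- ic_of(ifa, terms)
    v[!is.finite(v)] <- 0
    w * v
  }
  a <- coef(g1, t1)
  b <- coef(g2, t2)

  dot <- function(terms_a, ca, terms_b, cb) {
    s <- 0
    for (i in seq_along(terms_a)) {
      for (j in seq_along(terms_b)) {
        s <- s + ca[i] * cb[j] * intelligo_basis_dot(graph, terms_a[i], terms_b[j])
      }
    }
    s
  }
  d12 <- dot(t1, a, t2, b)
  d11 <- dot(t1, a, t1, a)
  d22 <- dot(t2, b, t2, b)
  if (d11 <= 0 || d22 <= 0) return(0)
  min(1, max(0, d12 / (sqrt(d11) * sqrt(d22))))
}

#' Wang semantic contributions of a term's ancestor closure
#'
#' S_t(t) = 1; walking upward, each ancestor x gets the maximum over its
#' children c on t-to-x paths of `w_edge * S_t(c)`, with edge weights 0.8
#' (is_a) and 0.6 (part_of). SV(t) is the sum over the closure.
#'
#' @param graph an [ontology_graph()].
#' @param term a term id.
#' @param w_is_a,w_part_of semantic contribution factors in `(0, 1]`.
#' @return A list with `term`, `s` (named contributions) and `sv`.
#' @export
wang_s_values <- function(graph, term, w_is_a = 0.8, w_part_of = 0.6) {
  if (w_is_a <= 0 || w_is_a > 1 || w_part_of <= 0 || w_part_of > 1) {
    stop("edge weights must be in (0, 1]")
  }
  assert_term(graph, term)
  closure <- c(term, term_ancestors(graph, term))
  w_of <- c(is_a = w_is_a, part_of = w_part_of)
  s <- stats::setNames(numeric(length(closure)), closure)
  for (v in closure_topo_order(graph, closure)) {
    if (v == term) {
      s[[v]] <- 1
      next
    }
    best <- 0
    for (u in intersect(term_children(graph, v), closure)) {
      rel <- graph$edge_rel[[paste(u, v, sep = "\r")]]
      w <- max(w_of[rel])
      best <- max(best, w * s[[u]])
    }
    s[[v]] <- best
  }
  list(term = term, s = s, sv = sum(s))
}

# Wang term-level similarity (shared contributions over common ancestors,
# the pair itself included, normalised by the two SV totals)
wang_term_sim <- function(graph, t1, t2, w_is_a = 0.8, w_part_of = 0.6, cache = NULL) {
  get_sv <- function(t) {
    if (!is.null(cache)) {
      key <- paste0("wang\r", t)
      got <- cache[[key]]
      if (!is.null(got)) return(got)
      res <- wang_s_values(graph, t, w_is_a, w_part_of)
      cache[[key]] <- res
      return(res)
    }
    wang_s_values(graph, t, w_is_a, w_part_of)
  }
  s1 <- get_sv(t1)
  s2 <- get_sv(t2)
  ca <- common_ancestors(graph, t1, t2)
  sum(s1$s[ca] + s2$s[ca]) / (s1$sv + s2$sv)
}

#' Wang gene similarity (best-match average)
#'
#' @inheritParams sim_intelligo
#' @param w_is_a,w_part_of edge semantic contribution factors.
#' @param cache optional [similarity_cache()] reused across gene pairs.
#' @return Numeric scalar in `[0, 1]`.
#' @export
sim_wang <- function(graph, corpus, g1, g2, aspect,
                     w_is_a = 0.8, w_part_of = 0.6, cache = NULL) {
  t1 <- gene_terms(corpus, g1, graph, aspect)
  t2 <- gene_terms(corpus, g2, graph, aspect)
  S <- matrix(NA_real_, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      S[i, j] <- wang_term_sim(graph, t1[i], t2[j], w_is_a, w_part_of, cache)
    }
  }
  (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) / (length(t1) + length(t2))
}

#' Resnik term similarity
#'
#' IC of the lowest common ancestor. `lca_semantics = "depth"` (default) uses
#' the deepest common ancestor from [lca_info()]; `"max_ic"` uses the common
#' ancestor of maximal finite IC.
#'
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param t1,t2 term ids (same aspect).
#' @param lca_semantics `"depth"` or `"max_ic"`.
#' @return Non-negative numeric scalar.
#' @export
sim_resnik <- function(graph, ic, t1, t2, lca_semantics = c("depth", "max_ic")) {
  lca_semantics <- match.arg(lca_semantics)
  if (lca_semantics == "depth") {
    v <- ic_of(ic, lca_info(graph, t1, t2)$lca)
    return(unname(ifelse(is.finite(v), v, 0)))
  }
  v <- ic_of(ic, common_ancestors(graph, t1, t2))
  v <- v[is.finite(v)]
  if (length(v) == 0L) 0 else max(v)
}

#' Lord gene similarity
#'
#' Mean of the Resnik term similarity over the full n x m annotation grid.
#'
#' @inheritParams sim_resnik
#' @param corpus an [annotation_corpus()].
#' @param g1,g2 gene ids.
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @return Non-negative numeric scalar.
#' @export
sim_lord <- function(graph, ic, corpus, g1, g2, aspect,
                     lca_semantics = c("depth", "max_ic")) {
  lca_semantics <- match.arg(lca_semantics)
  t1 <- gene_terms(corpus, g1, graph, aspect)
  t2 <- gene_terms(corpus, g2, graph, aspect)
  mean(vapply(t1, function(a) {
    mean(vapply(t2, function(b) sim_resnik(graph, ic, a, b, lca_semantics),
                numeric(1)))
  }, numeric(1)))
}

# shortest inter-term path length in edges through any common ancestor
min_path_length <- function(graph, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  d1 <- shortest_up_lengths(graph, t1)
  d2 <- shortest_up_lengths(graph, t2)
  min(d1[ca] + d2[ca])
}

#' Al-Mubaid gene similarity
#'
#' Averages the shortest path length (in edges, through any common ancestor)
#' over the n x m annotation grid and converts it with `exp(-alpha * PL)`.
#'
#' @inheritParams sim_intelligo
#' @param alpha decay constant of the distance-to-similarity transform.
#' @return Numeric scalar in `(0, 1]`.
#' @export
sim_mubaid <- function(graph, corpus, g1, g2, aspect, alpha = 0.2) {
  t1 <- gene_terms(corpus, g1, graph, aspect)
  t2 <- gene_terms(corpus, g2, graph, aspect)
  pl <- mean(vapply(t1, function(a) {
    mean(vapply(t2, function(b) min_path_length(graph, a, b), numeric(1)))
  }, numeric(1)))
  exp(-alpha * pl)
}

#' SimGIC (weighted Jaccard) gene similarity
#'
#' Extends each gene's annotations with all their ancestors and returns the
#' ratio of IC sums over the intersection and the union of the two closures.
#' Infinite ICs (unannotated terms) are excluded from both sums; an empty or
#' all-zero union yields 0.
#'
#' @inheritParams sim_lord
#' @return Numeric scalar in `[0, 1]`.
#' @export
sim_simgic <- function(graph, ic, corpus, g1, g2, aspect) {
  closure_of <- function(g) {
    terms <- gene_terms(corpus, g, graph, aspect)
    unique(c(terms, unlist(lapply(terms, function(t) term_ancestors(graph, t)),
                           use.names = FALSE)))
  }
  c1 <- closure_of(g1)
  c2 <- closure_of(g2)
  ic_sum <- function(terms) {
    v <- ic_of(ic, terms)
    sum(v[is.finite(v)])
  }
  num <- ic_sum(intersect(c1, c2))
  den <- ic_sum(union(c1, c2))
  if (den == 0) 0 else num / den
}
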