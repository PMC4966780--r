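# Independent brute-force oracles working directly off the edge list by
# exhaustive recursion/enumeration; no shared code with the package's
# Dijkstra / topological-order / memoised machinery.

o_parents <- function(graph, t) sort(graph$edges$parent[graph$edges$child == t])

o_ancestors <- function(graph, t) {
  out <- character()
  for (p in o_parents(graph, t)) out <- union(out, c(p, o_ancestors(graph, p)))
  sort(out)
}

# all upward paths from -> to as list of character vectors
o_paths <- function(graph, from, to) {
  if (from == to) return(list(from))
  out <- list()
  for (p in o_parents(graph, from)) {
    for (tail in o_paths(graph, p, to)) out <- c(out, list(c(from, tail)))
  }
  out
}

o_comanc <- function(graph, t1, t2) {
  sort(intersect(c(t1, o_ancestors(graph, t1)), c(t2, o_ancestors(graph, t2))))
}

o_dca <- function(graph, t1, t2) {
  ca <- o_comanc(graph, t1, t2)
  keep <- vapply(ca, function(x) {
    ch <- graph$edges$child[graph$edges$parent == x]
    !any(ch %in% ca)
  }, logical(1))
  ca[keep]
}

o_contrib <- function(ic, node, root) {
  v <- unname(ic$ic[[node]])
  if (node == root || !is.finite(v) || v == 0) 0 else 1 / v
}

o_iic <- function(path, ic, root) {
  sum(vapply(path, o_contrib, numeric(1), ic = ic, root = root))
}

# exhaustive argmin/argmax of IIC over enumerated paths with the package's
# deterministic tie-break conventions (length, then lexicographic)
o_select_path <- function(paths, ic, root, maximise = FALSE, prefer_longer = FALSE) {
  stopifnot(length(paths) > 0L)
  iics <- vapply(paths, o_iic, numeric(1), ic = ic, root = root)
  lens <- vapply(paths, length, integer(1)) - 1L
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  best <- 1L
  for (k in seq_along(paths)[-1L]) {
    b <- if (maximise) {
      iics[k] > iics[best] + 1e-9 ||
        (iics[k] >= iics[best] - 1e-9 &&
           (if (lens[k] != lens[best]) {
             if (prefer_longer) lens[k] > lens[best] else lens[k] < lens[best]
           } else keys[k] < keys[best]))
    } else {
      iics[k] < iics[best] - 1e-9 ||
        (iics[k] <= iics[best] + 1e-9 &&
           (if (lens[k] != lens[best]) {
             if (prefer_longer) lens[k] > lens[best] else lens[k] < lens[best]
           } else keys[k] < keys[best]))
    }
    if (b) best <- k
  }
  list(path = paths[[best]], iic = iics[best], length = lens[best])
}

o_root <- function(graph, t) {
  asp <- graph$terms$aspect[match(t, graph$terms$id)]
  ids <- graph$terms$id[graph$terms$aspect == asp]
  ids[!ids %in% graph$edges$child]
}

o_wsp <- function(graph, ic, from, to) {
  root <- o_root(graph, from)
  o_select_path(o_paths(graph, from, to), ic, root)
}

o_wlp <- function(graph, ic, from) {
  root <- o_root(graph, from)
  sel <- o_select_path(o_paths(graph, from, root), ic, root,
                       maximise = TRUE, prefer_longer = TRUE)
  sel$weighted <- sel$iic * sel$length
  sel
}

o_distance_via <- function(graph, ic, t1, t2, x) {
  root <- o_root(graph, t1)
  s1 <- o_wsp(graph, ic, t1, x)
  s2 <- o_wsp(graph, ic, t2, x)
  wsp <- (s1$iic + s2$iic - o_contrib(ic, x, root)) * (s1$length + s2$length)
  wlp <- o_wlp(graph, ic, x)$weighted
  if (wlp == 0) Inf else wsp / wlp
}

o_term_distance <- function(graph, ic, t1, t2) {
  if (t1 == t2) return(0)
  root <- o_root(graph, t1)
  dca <- o_dca(graph, t1, t2)
  if (identical(unname(dca), root)) return(Inf)
  min(vapply(dca, function(x) o_distance_via(graph, ic, t1, t2, x), numeric(1)))
}

o_depth <- function(graph, x) {
  root <- o_root(graph, x)
  max(vapply(o_paths(graph, x, root), length, integer(1))) - 1L
}

o_lca <- function(graph, t1, t2) {
  ca <- o_comanc(graph, t1, t2)
  depths <- vapply(ca, o_depth, integer(1), graph = graph)
  ca[depths == max(depths)][1L]
}

o_min_up <- function(graph, t, x) {
  min(vapply(o_paths(graph, t, x), length, integer(1))) - 1L
}

o_min_spl <- function(graph, t1, t2, x) {
  o_min_up(graph, t1, x) + o_min_up(graph, t2, x)
}

# Wang: S_t(x) as brute-force max path product of edge weights
o_wang_s <- function(graph, t, x, w_is_a = 0.8, w_part_of = 0.6) {
  w_of <- c(is_a = w_is_a, part_of = w_part_of)
  edge_w <- function(u, v) {
    rel <- graph$edges$relation[graph$edges$child == u & graph$edges$parent == v]
    max(w_of[rel])
  }
  max(vapply(o_paths(graph, t, x), function(p) {
    if (length(p) == 1L) return(1)
    prod(vapply(seq_len(length(p) - 1L), function(i) edge_w(p[i], p[i + 1L]),
                numeric(1)))
  }, numeric(1)))
}

o_wang_term_sim <- function(graph, t1, t2, w_is_a = 0.8, w_part_of = 0.6) {
  sv <- function(t) {
    closure <- c(t, o_ancestors(graph, t))
    sum(vapply(closure, function(x) o_wang_s(graph, t, x, w_is_a, w_part_of),
               numeric(1)))
  }
  ca <- o_comanc(graph, t1, t2)
  num <- sum(vapply(ca, function(x) {
    o_wang_s(graph, t1, x, w_is_a, w_part_of) +
      o_wang_s(graph, t2, x, w_is_a, w_part_of)
  }, numeric(1)))
  num / (sv(t1) + sv(t2))
}

o_mubaid_pl <- function(graph, t1, t2) {
  ca <- o_comanc(graph, t1, t2)
  min(vapply(ca, function(x) o_min_spl(graph, t1, t2, x), numeric(1)))
}

# triple-loop empirical distance covariance / correlation
o_dcov2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  dx <- function(k, l) sqrt(sum((x[k, ] - x[l, ])^2))
  dy <- function(k, l) sqrt(sum((y[k, ] - y[l, ])^2))
  s1 <- 0; sx <- 0; sy <- 0
  for (k in 1:n) for (l in 1:n) {
    s1 <- s1 + dx(k, l) * dy(k, l)
    sx <- sx + dx(k, l)
    sy <- sy + dy(k, l)
  }
  s3 <- 0
  for (k in 1:n) for (l in 1:n) for (m in 1:n) {
    s3 <- s3 + dx(k, l) * dy(k, m)
  }
  s1 / n^2 + (sx / n^2) * (sy / n^2) - 2 * s3 / n^3
}

o_dcor <- function(x, y) {
  vxy <- max(o_dcov2(x, y), 0)
  vxx <- max(o_dcov2(x, x), 0)
  vyy <- max(o_dcov2(y, y), 0)
  if (vxx == 0 || vyy == 0) 0 else sqrt(vxy) / (sqrt(sqrt(vxx)) * sqrt(sqrt(vyy)))
}

# double-centered-distance-matrix formulation (independent algebraic route)
o_dcov2_centered <- function(x, y) {
  A <- as.matrix(stats::dist(as.matrix(x)))
  B <- as.matrix(stats::dist(as.matrix(y)))
  n <- nrow(A)
  ctr <- function(M) M - outer(rowMeans(M), rep(1, n)) -
    outer(rep(1, n), colMeans(M)) + mean(M)
  mean(ctr(A) * ctr(B))
}

# gene-level oracle implementations of the five baseline measures,
# built entirely on the enumeration primitives above

o_gene_terms <- function(corpus, g) {
  sort(unique(corpus$annotations$term[corpus$annotations$gene == g]))
}

o_ifa <- function(graph, corpus, t) {
  genes <- unique(corpus$annotations$gene)
  hit <- vapply(genes, function(g) {
    terms <- o_gene_terms(corpus, g)
    t %in% unique(c(terms, unlist(lapply(terms, o_ancestors, graph = graph))))
  }, logical(1))
  if (!any(hit)) return(0)
  log(corpus$total_genes / sum(hit))
}

o_intelligo <- function(graph, corpus, g1, g2) {
  t1 <- o_gene_terms(corpus, g1)
  t2 <- o_gene_terms(corpus, g2)
  a <- vapply(t1, o_ifa, numeric(1), graph = graph, corpus = corpus)
  b <- vapply(t2, o_ifa, numeric(1), graph = graph, corpus = corpus)
  basis <- function(ti, tj) {
    if (ti == tj) return(1)
    lca <- o_lca(graph, ti, tj)
    d <- o_depth(graph, lca)
    spl <- o_min_spl(graph, ti, tj, lca)
    if (d == 0 && spl == 0) 1 else 2 * d / (spl + 2 * d)
  }
  dot <- function(ta, ca, tb, cb) {
    s <- 0
    for (i in seq_along(ta)) for (j in seq_along(tb)) {
      s <- s + ca[i] * cb[j] * basis(ta[i], tb[j])
    }
    s
  }
  d11 <- dot(t1, a, t1, a); d22 <- dot(t2, b, t2, b)
  if (d11 <= 0 || d22 <= 0) return(0)
  min(1, max(0, dot(t1, a, t2, b) / (sqrt(d11) * sqrt(d22))))
}

o_wang_gene <- function(graph, corpus, g1, g2) {
  t1 <- o_gene_terms(corpus, g1)
  t2 <- o_gene_terms(corpus, g2)
  S <- outer(seq_along(t1), seq_along(t2),
             Vectorize(function(i, j) o_wang_term_sim(graph, t1[i], t2[j])))
  S <- matrix(S, length(t1), length(t2))
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / (length(t1) + length(t2))
}

o_resnik <- function(graph, ic, t1, t2) {
  v <- unname(ic$ic[[o_lca(graph, t1, t2)]])
  if (is.finite(v)) v else 0
}

o_lord <- function(graph, ic, corpus, g1, g2) {
  t1 <- o_gene_terms(corpus, g1)
  t2 <- o_gene_terms(corpus, g2)
  mean(vapply(t1, function(a) mean(vapply(t2, function(b) o_resnik(graph, ic, a, b),
                                          numeric(1))), numeric(1)))
}

o_mubaid_gene <- function(graph, corpus, g1, g2, alpha = 0.2) {
  t1 <- o_gene_terms(corpus, g1)
  t2 <- o_gene_terms(corpus, g2)
  pl <- mean(vapply(t1, function(a) mean(vapply(t2, function(b) o_mubaid_pl(graph, a, b),
                                                numeric(1))), numeric(1)))
  exp(-alpha * pl)
}

o_simgic_gene <- function(graph, ic, corpus, g1, g2) {
  closure <- function(g) {
    terms <- o_gene_terms(corpus, g)
    unique(c(terms, unlist(lapply(terms, o_ancestors, graph = graph))))
  }
  c1 <- closure(g1); c2 <- closure(g2)
  s <- function(ts) { v <- unname(ic$ic[ts]); sum(v[is.finite(v)]) }
  den <- s(union(c1, c2))
  if (den == 0) 0 else s(intersect(c1, c2)) / den
}
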