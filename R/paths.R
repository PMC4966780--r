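# Inverse-information-content (IIC) path machinery: a path is scored by the
# sum of 1/IC over its nodes (aspect root excluded), and weighted by its
# length in edges. The shortest path minimises IIC (Dijkstra with the node
# weights pushed onto incoming edges); the longest path to the root maximises
# IIC (dynamic programming over a topological order).

# 1/IC contribution of single nodes: 0 for the aspect root, IC == 0 (a term
# annotating every gene) and IC == +Inf (unannotated terms)
inv_ic_contrib <- function(ic, nodes, root) {
  v <- ic_of(ic, nodes)
  contrib <- ifelse(is.finite(v) & v > 0, 1 / v, 0)
  contrib[nodes == root] <- 0
  unname(contrib)
}

#' Inverse information content of a path
#'
#' Sum of 1/IC over the path's nodes, excluding the aspect root and any node
#' with IC 0 or +Inf (both contribute nothing).
#'
#' @param path character vector of term ids along the path.
#' @param ic an [ic_table()] covering the path's nodes.
#' @param root the aspect-root term id to exclude.
#' @return Non-negative numeric scalar.
#' @export
path_iic <- function(path, ic, root) {
  sum(inv_ic_contrib(ic, path, root))
}

new_weighted_path <- function(path, iic, root_unused = NULL) {
  len <- length(path) - 1L
  structure(list(path = path, iic = iic, length = len, weighted = iic * len),
            class = "weighted_path")
}

#' @export
print.weighted_path <- function(x, ...) {
  cat("weighted_path:", paste(x$path, collapse = " -> "),
      "\n  iic =", x$iic, " length =", x$length, " weighted =", x$weighted, "\n")
  invisible(x)
}

# three-level path comparison used for deterministic selection:
# primary score (IIC), then length, then lexicographic node sequence
path_key <- function(path) paste(path, collapse = "\r")

better_path <- function(iic_a, len_a, key_a, iic_b, len_b, key_b,
                        maximise = FALSE, prefer_longer = FALSE, tol = 1e-9) {
  if (maximise) {
    if (iic_a > iic_b + tol) return(TRUE)
    if (iic_a < iic_b - tol) return(FALSE)
  } else {
    if (iic_a < iic_b - tol) return(TRUE)
    if (iic_a > iic_b + tol) return(FALSE)
  }
  if (len_a != len_b) {
    return(if (prefer_longer) len_a > len_b else len_a < len_b)
  }
  key_a < key_b
}

#' IIC-weighted shortest path between a term and one of its ancestors
#'
#' Among all upward paths `from -> ... -> to`, selects the one minimising the
#' IIC sum (so paths through high-IC, i.e. specific, terms are preferred).
#' Ties are broken toward the shorter path, then by lexicographic node order,
#' so the selection is deterministic. The returned `weighted` value is
#' IIC x length-in-edges.
#'
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param from a term id.
#' @param to a term in `from`'s ancestor closure (or `from` itself).
#' @return A `weighted_path` with fields `path`, `iic`, `length`, `weighted`.
#' @export
weighted_shortest_path <- function(graph, ic, from, to) {
  assert_term(graph, from)
  assert_term(graph, to)
  root <- aspect_root(graph, from)
  closure <- c(from, term_ancestors(graph, from))
  if (!to %in% closure) stop(to, " is not an ancestor of ", from)

  # restrict the search to nodes that can still reach `to`
  nodes <- closure[vapply(closure, function(v) {
    v == to || to %in% term_ancestors(graph, v)
  }, logical(1))]
  contrib <- stats::setNames(inv_ic_contrib(ic, nodes, root), nodes)

  iic <- stats::setNames(rep(Inf, length(nodes)), nodes)
  len <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)

  iic[[from]] <- contrib[[from]]
  len[[from]] <- 0L
  paths[[from]] <- from

  repeat {
    open <- names(done)[!done & is.finite(iic)]
    if (length(open) == 0L) break
    u <- open[[1L]]
    for (v in open[-1L]) {
      if (better_path(iic[[v]], len[[v]], path_key(paths[[v]]),
                      iic[[u]], len[[u]], path_key(paths[[u]]))) u <- v
    }
    done[[u]] <- TRUE
    if (u == to) break
    for (p in graph$parents[[u]]) {
      if (!p %in% nodes || done[[p]]) next
      cand_iic <- iic[[u]] + contrib[[p]]
      cand_len <- len[[u]] + 1L
      cand_path <- c(paths[[u]], p)
      if (is.na(len[[p]]) ||
          better_path(cand_iic, cand_len, path_key(cand_path),
                      iic[[p]], len[[p]], path_key(paths[[p]]))) {
        iic[[p]] <- cand_iic
        len[[p]] <- cand_len
        paths[[p]] <- cand_path
      }
    }
  }
  if (!done[[to]]) stop("no upward path from ", from, " to ", to)
  new_weighted_path(paths[[to]], iic[[to]])
}

# deterministic topological order of an ancestor closure: every node after
# all of its in-closure children, ties resolved lexicographically
closure_topo_order <- function(graph, closure) {
  remaining <- csort(closure)
  n_pending <- stats::setNames(vapply(remaining, function(v) {
    sum(term_children(graph, v) %in% closure)
  }, integer(1)), remaining)
  order <- character()
  while (length(remaining)) {
    ready <- remaining[n_pending[remaining] == 0L]
    if (length(ready) == 0L) stop("cycle detected in ancestor closure")
    u <- ready[[1L]]  # lexicographically smallest (remaining is sorted)
    order <- c(order, u)
    remaining <- setdiff(remaining, u)
    ps <- intersect(graph$parents[[u]], remaining)
    n_pending[ps] <- n_pending[ps] - 1L
  }
  order
}

#' IIC-weighted longest path from a term to its aspect root
#'
#' Among all upward paths from `from` to the aspect root, selects the one
#' maximising the IIC sum, by dynamic programming over a topological order of
#' the ancestor closure. Ties are broken toward the longer path, then by
#' lexicographic node order. The root is excluded from the IIC sum but its
#' edge counts toward the length.
#'
#' @inheritParams weighted_shortest_path
#' @return A `weighted_path` ending at the aspect root.
#' @export
weighted_longest_path <- function(graph, ic, from) {
  assert_term(graph, from)
  root <- aspect_root(graph, from)
  closure <- c(from, term_ancestors(graph, from))
  if (!root %in% closure) stop(from, " is disconnected from the aspect root ", root)
  contrib <- stats::setNames(inv_ic_contrib(ic, closure, root), closure)

  # closure children of a node v are exactly the nodes u in the closure with
  # an edge u -> v; the topological order guarantees u is processed first
  best <- new.env(parent = emptyenv())
  for (v in closure_topo_order(graph, closure)) {
    if (v == from) {
      best[[v]] <- list(iic = contrib[[v]], len = 0L, path = v)
      next
    }
    ch <- intersect(term_children(graph, v), closure)
    cand <- NULL
    for (u in ch) {
      bu <- best[[u]]
      if (is.null(bu)) next  # closure node not reachable from `from` via u
      c_iic <- bu$iic + contrib[[v]]
      c_len <- bu$len + 1L
      c_path <- c(bu$path, v)
      if (is.null(cand) ||
          better_path(c_iic, c_len, path_key(c_path),
                      cand$iic, cand$len, path_key(cand$path),
                      maximise = TRUE, prefer_longer = TRUE)) {
        cand <- list(iic = c_iic, len = c_len, path = c_path)
      }
    }
    if (!is.null(cand)) best[[v]] <- cand
  }
  b <- best[[root]]
  if (is.null(b)) stop("no path from ", from, " to root ", root)
  new_weighted_path(b$path, b$iic)
}
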