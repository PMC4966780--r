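# Ontology graph container and topology primitives.
#
# A GO aspect is modelled as a rooted DAG (rDAG): terms are nodes, hierarchical
# relations (is_a, part_of) are directed child -> parent edges, and each aspect
# has a single root term with no parents.

# locale-stable sort (radix = C collation, reproducible across machines)
csort <- function(x) sort(unique(as.character(x)), method = "radix")

new_cache <- function() new.env(parent = emptyenv())

#' Construct an ontology graph
#'
#' Builds the rooted-DAG container used by every similarity measure in the
#' package: a set of terms, typed child-to-parent edges (`is_a`, `part_of`),
#' and one root term per aspect (`BP`, `MF`, `CC`). The constructor validates
#' that edges connect known terms of the same aspect, that the relation graph
#' is acyclic, and that each aspect has exactly one parentless term (its root).
#'
#' @param terms data.frame with columns `id`, `name`, `aspect`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`relation` in `is_a`/`part_of`); may have zero rows.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges = NULL) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "aspect") %in% names(terms)))
  terms <- data.frame(
    id = as.character(terms$id),
    name = as.character(terms$name),
    aspect = as.character(terms$aspect),
    stringsAsFactors = FALSE
  )
  if (nrow(terms) == 0L) stop("empty ontology: no terms")
  if (any(!nzchar(terms$id))) stop("term ids must be non-empty")
  if (anyDuplicated(terms$id)) stop("duplicate term ids: ",
                                    paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("child", "parent", "relation") %in% names(edges)))
  edges <- data.frame(
    child = as.character(edges$child),
    parent = as.character(edges$parent),
    relation = as.character(edges$relation),
    stringsAsFactors = FALSE
  )
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) stop("unsupported relation(s): ", paste(bad_rel, collapse = ", "))
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown)) stop("edges reference unknown terms: ", paste(unknown, collapse = ", "))

  aspect_of_id <- stats::setNames(terms$aspect, terms$id)
  cross <- aspect_of_id[edges$child] != aspect_of_id[edges$parent]
  if (any(cross)) stop("edges must connect terms of the same aspect (",
                       sum(cross), " cross-aspect edge(s))")
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE, vertices = terms$id)
    if (!igraph::is_dag(g)) stop("relation graph contains a cycle")
  }

  parents <- lapply(split(edges$parent, factor(edges$child, levels = terms$id)),
                    function(p) csort(p))
  children <- lapply(split(edges$child, factor(edges$parent, levels = terms$id)),
                     function(ch) csort(ch))

  # relation lookup keyed "child\rparent" (multiple relations collapse to one key)
  edge_rel <- split(edges$relation, paste(edges$child, edges$parent, sep = "\r"))

  roots <- character()
  for (a in csort(terms$aspect)) {
    ids <- terms$id[terms$aspect == a]
    parentless <- ids[vapply(ids, function(t) length(parents[[t]]) == 0L, logical(1))]
    if (length(parentless) != 1L) {
      stop("aspect ", a, " must have exactly one root, found ",
           length(parentless), ": ", paste(parentless, collapse = ", "))
    }
    roots[[a]] <- parentless
  }

  structure(
    list(terms = terms, edges = edges, parents = parents, children = children,
         edge_rel = edge_rel, roots = roots, cache = new_cache()),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges\n")
  for (a in names(x$roots)) {
    cat("  aspect", a, ":", sum(x$terms$aspect == a), "terms, root", x$roots[[a]], "\n")
  }
  invisible(x)
}

assert_term <- function(graph, term) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  invisible(term)
}

term_aspect <- function(graph, term) {
  assert_term(graph, term)
  graph$terms$aspect[match(term, graph$terms$id)]
}

#' Root term of an aspect
#'
#' @param graph an [ontology_graph()].
#' @param term a term id; the root of this term's aspect is returned.
#' @return The aspect root's term id.
#' @export
aspect_root <- function(graph, term) {
  unname(graph$roots[[term_aspect(graph, term)]])
}

#' All ancestors of a term
#'
#' Every term reachable by repeatedly following child-to-parent edges
#' (is_a and part_of are traversed identically). The term itself is excluded;
#' the aspect root has no ancestors. Results are memoised on the graph.
#'
#' @inheritParams aspect_root
#' @return Sorted character vector of ancestor term ids.
#' @export
term_ancestors <- function(graph, term) {
  assert_term(graph, term)
  key <- paste0("anc\r", term)
  got <- graph$cache[[key]]
  if (!is.null(got)) return(got)
  seen <- character()
  queue <- graph$parents[[term]]
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, graph$parents[[v]])
  }
  out <- csort(seen)
  graph$cache[[key]] <- out
  out
}

#' Immediate children of a term
#'
#' @inheritParams aspect_root
#' @return Sorted character vector of child term ids (empty for leaves).
#' @export
term_children <- function(graph, term) {
  assert_term(graph, term)
  ch <- graph$children[[term]]
  if (is.null(ch)) character() else ch
}

#' Common ancestors of two terms
#'
#' The intersection of the two terms' ancestor closures, with each term
#' counted as its own ancestor (so identical terms and ancestor-descendant
#' pairs behave naturally).
#'
#' @param graph an [ontology_graph()].
#' @param t1,t2 term ids from the same aspect.
#' @return Sorted character vector of common-ancestor term ids.
#' @export
common_ancestors <- function(graph, t1, t2) {
  if (term_aspect(graph, t1) != term_aspect(graph, t2)) {
    stop("aspect mismatch: ", t1, " and ", t2, " are in different aspects")
  }
  csort(intersect(c(t1, term_ancestors(graph, t1)),
                  c(t2, term_ancestors(graph, t2))))
}

#' Disjunctive common ancestors of two terms
#'
#' The minimal elements of the common-ancestor set under the ancestor partial
#' order: a common ancestor x is disjunctive when no immediate child of x is
#' itself a common ancestor. The result is an antichain (no member is an
#' ancestor of another member) and is never empty for same-aspect terms in a
#' rooted DAG.
#'
#' @inheritParams common_ancestors
#' @return Sorted character vector of disjunctive common ancestor ids.
#' @export
disjunctive_common_ancestors <- function(graph, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  if (length(ca) == 0L) stop("no common ancestors for ", t1, " and ", t2)
  keep <- vapply(ca, function(x) !any(term_children(graph, x) %in% ca), logical(1))
  ca[keep]
}

#' Enumerate all upward paths between a term and one of its ancestors
#'
#' Exhaustive path enumeration, intended as an oracle on small graphs (path
#' counts grow exponentially); refuses graphs larger than `max_nodes` and
#' directs callers to [weighted_shortest_path()] / [weighted_longest_path()].
#'
#' @param graph an [ontology_graph()].
#' @param from a term id.
#' @param to a term id in `from`'s ancestor closure (or `from` itself).
#' @param max_nodes refuse graphs with more terms than this.
#' @return A list of character vectors, each an upward path `from -> ... -> to`
#'   (a single zero-length path when `from == to`).
#' @export
enumerate_paths <- function(graph, from, to, max_nodes = 25L) {
  assert_term(graph, from)
  assert_term(graph, to)
  if (nrow(graph$terms) > max_nodes) {
    stop("graph has ", nrow(graph$terms), " > ", max_nodes,
         " terms; use weighted_shortest_path()/weighted_longest_path() instead")
  }
  if (!(to == from || to %in% term_ancestors(graph, from))) {
    stop(to, " is not an ancestor of ", from)
  }
  paths <- list()
  walk <- function(node, acc) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (p in graph$parents[[node]]) walk(p, c(acc, p))
    invisible()
  }
  walk(from, from)
  paths
}

# longest root->x path length in edges, memoised (depth in the LCA sense)
term_depth <- function(graph, term) {
  assert_term(graph, term)
  key <- paste0("depth\r", term)
  got <- graph$cache[[key]]
  if (!is.null(got)) return(got)
  ps <- graph$parents[[term]]
  d <- if (length(ps) == 0L) 0L else 1L + max(vapply(ps, function(p) term_depth(graph, p), integer(1)))
  graph$cache[[key]] <- d
  d
}

# shortest upward edge-count distances from `term` to every node of its
# ancestor closure (named integer, includes term itself at 0), memoised
shortest_up_lengths <- function(graph, term) {
  assert_term(graph, term)
  key <- paste0("spl\r", term)
  got <- graph$cache[[key]]
  if (!is.null(got)) return(got)
  dist <- stats::setNames(0L, term)
  frontier <- term
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- csort(unlist(lapply(frontier, function(v) graph$parents[[v]]), use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  graph$cache[[key]] <- dist
  dist
}
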