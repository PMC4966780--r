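# Minimal OBO 1.2 reader/writer covering the subset used for GO releases:
# [Term] stanzas with id / name / namespace / is_a / relationship / is_obsolete.

OBO_NAMESPACE_TO_ASPECT <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC"
)
ASPECT_TO_OBO_NAMESPACE <- stats::setNames(names(OBO_NAMESPACE_TO_ASPECT),
                                           OBO_NAMESPACE_TO_ASPECT)

strip_obo_comment <- function(x) sub("\\s*!.*$", "", x)

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas into an [ontology_graph()]. `is_a:` lines become
#' `is_a` edges and `relationship: part_of` lines become `part_of` edges;
#' both are traversed identically by the similarity measures. Obsolete terms
#' are excluded together with any edge touching them. Non-hierarchical
#' relationship types (`regulates`, ...) and cross-aspect edges are dropped
#' with a message giving the count.
#'
#' @param file path to an OBO file (or a connection).
#' @param aspect optional aspect filter (`"BP"`, `"MF"` or `"CC"`): only that
#'   aspect's terms and edges are retained.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(file, aspect = NULL) {
  lines <- readLines(file, warn = FALSE)
  stanza_start <- grep("^\\[", lines)
  if (length(stanza_start) == 0L) stop("empty ontology: no stanzas in OBO input")
  stanza_end <- c(stanza_start[-1L] - 1L, length(lines))

  ids <- names <- aspects <- character()
  e_child <- e_parent <- e_rel <- character()
  n_other_rel <- 0L

  for (k in seq_along(stanza_start)) {
    if (lines[stanza_start[k]] != "[Term]") next
    body_idx <- seq(stanza_start[k] + 1L, stanza_end[k])
    body <- lines[body_idx]
    keep <- nzchar(body) & !startsWith(body, "!")
    body <- body[keep]
    body_idx <- body_idx[keep]
    if (length(body) == 0L) next
    split_at <- regexpr(": ", body, fixed = TRUE)
    if (any(split_at < 0L)) {
      stop("malformed OBO stanza: no 'key: value' at line ",
           body_idx[which(split_at < 0L)[1L]])
    }
    keys <- substr(body, 1L, split_at - 1L)
    vals <- substring(body, split_at + 2L)

    if (any(keys == "is_obsolete" & trimws(strip_obo_comment(vals)) == "true")) next
    id <- trimws(strip_obo_comment(vals[keys == "id"]))
    if (length(id) != 1L || !nzchar(id)) {
      stop("malformed OBO stanza near line ", stanza_start[k], ": missing id")
    }
    nm <- trimws(strip_obo_comment(vals[keys == "name"]))
    nm <- if (length(nm)) nm[1L] else id
    ns <- trimws(strip_obo_comment(vals[keys == "namespace"]))
    asp <- if (length(ns)) {
      if (ns[1L] %in% names(OBO_NAMESPACE_TO_ASPECT)) OBO_NAMESPACE_TO_ASPECT[[ns[1L]]] else ns[1L]
    } else "BP"

    ids <- c(ids, id); names <- c(names, nm); aspects <- c(aspects, asp)

    for (v in vals[keys == "is_a"]) {
      e_child <- c(e_child, id)
      e_parent <- c(e_parent, trimws(strip_obo_comment(v)))
      e_rel <- c(e_rel, "is_a")
    }
    for (v in vals[keys == "relationship"]) {
      parts <- strsplit(trimws(strip_obo_comment(v)), "\\s+")[[1L]]
      if (length(parts) < 2L) stop("malformed relationship line in stanza for ", id)
      if (parts[1L] == "part_of") {
        e_child <- c(e_child, id)
        e_parent <- c(e_parent, parts[2L])
        e_rel <- c(e_rel, "part_of")
      } else {
        n_other_rel <- n_other_rel + 1L
      }
    }
  }

  if (n_other_rel > 0L) {
    message("read_obo: dropped ", n_other_rel, " non-hierarchical relationship(s)")
  }
  terms <- data.frame(id = ids, name = names, aspect = aspects, stringsAsFactors = FALSE)
  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel,
                      stringsAsFactors = FALSE)

  # drop edges to obsolete/unknown terms, then cross-aspect edges
  known <- edges$child %in% terms$id & edges$parent %in% terms$id
  if (any(!known)) {
    message("read_obo: dropped ", sum(!known), " edge(s) to obsolete or undeclared terms")
    edges <- edges[known, , drop = FALSE]
  }
  asp_of <- stats::setNames(terms$aspect, terms$id)
  cross <- asp_of[edges$child] != asp_of[edges$parent]
  if (any(cross)) {
    message("read_obo: dropped ", sum(cross), " cross-aspect edge(s)")
    edges <- edges[!cross, , drop = FALSE]
  }
  if (!is.null(aspect)) {
    terms <- terms[terms$aspect == aspect, , drop = FALSE]
    edges <- edges[edges$child %in% terms$id & edges$parent %in% terms$id, , drop = FALSE]
    if (nrow(terms) == 0L) stop("empty ontology after filtering to aspect ", aspect)
  }
  ontology_graph(terms, edges)
}

#' Write an ontology graph as OBO 1.2
#'
#' Inverse of [read_obo()] on the supported subset; round-tripping preserves
#' the node and edge multisets.
#'
#' @param graph an [ontology_graph()].
#' @param file output path.
#' @export
write_obo <- function(graph, file) {
  out <- c("format-version: 1.2", "")
  for (id in csort(graph$terms$id)) {
    i <- match(id, graph$terms$id)
    asp <- graph$terms$aspect[i]
    ns <- if (asp %in% names(ASPECT_TO_OBO_NAMESPACE)) ASPECT_TO_OBO_NAMESPACE[[asp]] else asp
    stanza <- c("[Term]", paste0("id: ", id),
                paste0("name: ", graph$terms$name[i]),
                paste0("namespace: ", ns))
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    if (nrow(e)) {
      e <- e[order(e$parent, e$relation, method = "radix"), , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        stanza <- c(stanza, if (e$relation[j] == "is_a") {
          paste0("is_a: ", e$parent[j])
        } else {
          paste0("relationship: part_of ", e$parent[j])
        })
      }
    }
    out <- c(out, stanza, "")
  }
  writeLines(out, file)
  invisible(file)
}
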