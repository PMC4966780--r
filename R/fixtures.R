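# Deterministic fixtures and random generators: a stylized GO BP
# metabolic-process fragment with reference IC values, random rooted DAGs,
# random annotation corpora, and clustered correlated (r, s) samples.

#' Stylized metabolic-process fixture with reference IC values
#'
#' A small fragment of the GO biological-process graph around the term pair
#' GO:0044260 (cellular macromolecule metabolic process) and GO:0006139
#' (nucleobase-containing compound metabolic process), whose two disjunctive
#' common ancestors are GO:0071704 (organic substance metabolic process) and
#' GO:0044237 (cellular metabolic process). The topology is the minimal DAG
#' consistent with the reference path structure: a unique combined path
#' through GO:0071704 (5 nodes, 4 edges) and a unique root path for it, and
#' two path alternatives on each leg of the GO:0044237 branch so that the
#' IIC-based selection is exercised. IC values are injected (3-decimal
#' reference values), not computed from a corpus.
#'
#' The `reference` field carries externally tabulated 3-decimal values for
#' this fragment: the two per-ancestor candidate distances and the resulting
#' similarity, used as regression anchors for the branch-selection and the
#' distance-to-similarity mapping.
#'
#' @return A list with `graph` ([ontology_graph()]), `ic` ([ic_table()]),
#'   `leaves` (the term pair), `disjunctive` (its two disjunctive common
#'   ancestors) and `reference` (candidate distances and similarity).
#' @export
metabolism_fixture <- function() {
  terms <- data.frame(
    id = c("GO:0008150", "GO:0008152", "GO:0009987",
           "GO:0071704", "GO:0044237",
           "GO:0043170", "GO:0044238", "GO:0034641", "GO:0044262",
           "GO:0044260", "GO:0006139"),
    name = c("biological_process", "metabolic process", "cellular process",
             "organic substance metabolic process", "cellular metabolic process",
             "macromolecule metabolic process", "primary metabolic process",
             "cellular nitrogen compound metabolic process",
             "cellular carbohydrate metabolic process",
             "cellular macromolecule metabolic process",
             "nucleobase-containing compound metabolic process"),
    aspect = "BP",
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child = c("GO:0008152", "GO:0009987",
              "GO:0071704", "GO:0044237", "GO:0044237",
              "GO:0043170", "GO:0044238", "GO:0034641", "GO:0044262",
              "GO:0044260", "GO:0044260", "GO:0044260",
              "GO:0006139", "GO:0006139"),
    parent = c("GO:0008150", "GO:0008150",
               "GO:0008152", "GO:0008152", "GO:0009987",
               "GO:0071704", "GO:0071704", "GO:0044237", "GO:0044237",
               "GO:0043170", "GO:0034641", "GO:0044262",
               "GO:0044238", "GO:0044237"),
    relation = "is_a",
    stringsAsFactors = FALSE
  )
  ic <- ic_table(c(
    "GO:0008150" = 0,
    "GO:0008152" = 1.098,
    "GO:0009987" = 0.407,
    "GO:0071704" = 1.255,
    "GO:0044237" = 1.329,
    "GO:0043170" = 2.086,
    "GO:0044238" = 1.479,
    "GO:0034641" = 1.999,
    "GO:0044262" = 1.700,
    "GO:0044260" = 2.158,
    "GO:0006139" = 1.617
  ))
  list(
    graph = ontology_graph(terms, edges),
    ic = ic,
    leaves = c("GO:0044260", "GO:0006139"),
    disjunctive = c("GO:0044237", "GO:0071704"),
    reference = list(
      candidate_distance = c("GO:0071704" = 2.75, "GO:0044237" = 1.076),
      similarity = 0.477
    )
  )
}

#' Random rooted DAG
#'
#' Node 1 is the aspect root; every later node (in topological order) draws
#' 1..`max_parents` parents uniformly among the earlier nodes, with relation
#' `is_a` (80%) or `part_of` (20%). Generation is a pure function of
#' (`n_terms`, `max_parents`, `seed`): the same spec yields an identical edge
#' list.
#'
#' @param n_terms number of terms (>= 1).
#' @param max_parents cap on parents per node.
#' @param seed RNG seed.
#' @param aspect aspect label for all terms.
#' @return An [ontology_graph()].
#' @export
random_rdag <- function(n_terms, max_parents = 3L, seed = 1L, aspect = "BP") {
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (max_parents < 1L) stop("max_parents must be >= 1")
  ids <- sprintf("T%04d", seq_len(n_terms))
  withr::with_seed(seed, {
    child <- parent <- rel <- character()
    if (n_terms >= 2L) {
      for (i in 2:n_terms) {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        ps <- ids[seq_len(i - 1L)][sample.int(i - 1L, k)]
        child <- c(child, rep(ids[i], k))
        parent <- c(parent, ps)
        rel <- c(rel, sample(c("is_a", "part_of"), k, replace = TRUE,
                             prob = c(0.8, 0.2)))
      }
    }
    ontology_graph(
      data.frame(id = ids, name = paste("synthetic term", ids), aspect = aspect,
                 stringsAsFactors = FALSE),
      data.frame(child = child, parent = parent, relation = rel,
                 stringsAsFactors = FALSE)
    )
  })
}

#' Random annotation corpus over a graph
#'
#' Each synthetic gene is annotated to k terms drawn uniformly without
#' replacement, with k itself uniform on 1..`k_max` (capped by the number of
#' terms), and an evidence code drawn from a small mixed set. Deterministic
#' under `seed`.
#'
#' @param graph an [ontology_graph()].
#' @param n_genes number of genes (>= 1).
#' @param k_max largest annotation count per gene.
#' @param seed RNG seed.
#' @return An [annotation_corpus()] with `total_genes = n_genes`.
#' @export
random_corpus <- function(graph, n_genes = 10L, k_max = 10L, seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  terms <- graph$terms$id
  codes <- c("EXP", "IDA", "ISS", "IEA")
  withr::with_seed(seed, {
    ann <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      k <- sample.int(min(k_max, length(terms)), 1L)
      data.frame(gene = sprintf("g%04d", i),
                 term = terms[sample.int(length(terms), k)],
                 evidence = sample(codes, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    annotation_corpus(ann, total_genes = n_genes, graph = graph)
  })
}

#' Clustered bivariate sample with a target within-cluster correlation
#'
#' Gaussian (r, s) pairs in `n_clusters` well-separated clusters, each with
#' the same within-cluster Pearson correlation; used to test grouped
#' correlation recovery.
#'
#' @param n number of pairs.
#' @param within_cluster_r target correlation in `[-1, 1]`.
#' @param n_clusters number of clusters (1 <= n_clusters <= n).
#' @param seed RNG seed.
#' @param cluster_spread distance between successive cluster centres.
#' @return data.frame with columns `r`, `s`, `cluster`.
#' @export
correlated_pairs <- function(n, within_cluster_r, n_clusters = 4L, seed = 1L,
                             cluster_spread = 6) {
  if (abs(within_cluster_r) > 1) stop("within_cluster_r must be in [-1, 1]")
  if (n_clusters < 1L || n_clusters > n) stop("need n >= n_clusters >= 1")
  withr::with_seed(seed, {
    cl <- sample.int(n_clusters, n, replace = TRUE)
    x <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    y <- within_cluster_r * x + sqrt(1 - within_cluster_r^2) * eps
    data.frame(r = x + cluster_spread * cl,
               s = y + cluster_spread * cl,
               cluster = cl)
  })
}
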