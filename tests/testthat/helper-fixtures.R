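# small hand-built graphs used across tests

# chain C -> B -> A (A is root)
chain_graph <- function() {
  ontology_graph(
    data.frame(id = c("A", "B", "C"), name = c("a", "b", "c"), aspect = "BP"),
    data.frame(child = c("B", "C"), parent = c("A", "B"), relation = "is_a")
  )
}

# diamond D -> {B, C} -> A
diamond_graph <- function(rel_b = "is_a", rel_c = "is_a") {
  ontology_graph(
    data.frame(id = c("A", "B", "C", "D"), name = c("a", "b", "c", "d"), aspect = "BP"),
    data.frame(child = c("B", "C", "D", "D"),
               parent = c("A", "A", "B", "C"),
               relation = c("is_a", "is_a", rel_b, rel_c))
  )
}

# root A with two unrelated leaves B and C
fork_graph <- function() {
  ontology_graph(
    data.frame(id = c("A", "B", "C"), name = c("a", "b", "c"), aspect = "BP"),
    data.frame(child = c("B", "C"), parent = c("A", "A"), relation = "is_a")
  )
}

make_ic <- function(...) ic_table(c(...))

# tiny corpus builder: list(gene = c(terms...))
make_corpus <- function(gene_term_list, total_genes = NULL) {
  df <- do.call(rbind, lapply(names(gene_term_list), function(g) {
    data.frame(gene = g, term = gene_term_list[[g]], evidence = "EXP",
               stringsAsFactors = FALSE)
  }))
  annotation_corpus(df, total_genes = total_genes)
}
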