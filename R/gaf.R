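# Annotation corpus container and GAF 2.x reader/writer.

GAF_ASPECT_LETTER <- c(P = "BP", F = "MF", C = "CC")

#' Construct an annotation corpus
#'
#' A corpus maps gene identifiers to their GO annotations (term + evidence
#' code) and records the gene-universe size `total_genes` (the paper's G_Tot)
#' used as the information-content denominator.
#'
#' @param annotations data.frame with columns `gene`, `term`, `evidence`.
#' @param total_genes gene-universe size; defaults to the number of distinct
#'   annotated genes. Must be at least that number.
#' @param graph optional [ontology_graph()]; annotations to terms absent from
#'   the graph are dropped with a warning giving the count.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(annotations, total_genes = NULL, graph = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "term", "evidence") %in% names(annotations)))
  ann <- data.frame(gene = as.character(annotations$gene),
                    term = as.character(annotations$term),
                    evidence = as.character(annotations$evidence),
                    stringsAsFactors = FALSE)
  if (!is.null(graph)) {
    known <- ann$term %in% graph$terms$id
    if (any(!known)) {
      warning("dropped ", sum(!known), " annotation(s) to terms absent from the graph")
      ann <- ann[known, , drop = FALSE]
    }
  }
  if (nrow(ann) == 0L) stop("no annotations")
  ann <- unique(ann)
  ann <- ann[order(ann$gene, ann$term, ann$evidence, method = "radix"), , drop = FALSE]
  rownames(ann) <- NULL
  n_genes <- length(unique(ann$gene))
  if (is.null(total_genes)) total_genes <- n_genes
  if (total_genes < n_genes) {
    stop("total_genes (", total_genes, ") is smaller than the number of annotated genes (",
         n_genes, ")")
  }
  structure(list(annotations = ann, total_genes = as.numeric(total_genes)),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation_corpus:", nrow(x$annotations), "annotations,",
      length(unique(x$annotations$gene)), "genes (universe:", x$total_genes, ")\n")
  invisible(x)
}

#' Genes present in a corpus
#' @param corpus an [annotation_corpus()].
#' @return Sorted character vector of gene ids.
#' @export
corpus_genes <- function(corpus) csort(corpus$annotations$gene)

#' Annotation terms of one gene
#'
#' @param corpus an [annotation_corpus()].
#' @param gene a gene id present in the corpus.
#' @param graph optional [ontology_graph()] for aspect filtering.
#' @param aspect optional aspect; requires `graph`.
#' @return Sorted character vector of term ids annotating `gene`. Raises an
#'   error for genes absent from the corpus, or annotated but with no
#'   annotation in the requested aspect.
#' @export
gene_terms <- function(corpus, gene, graph = NULL, aspect = NULL) {
  ann <- corpus$annotations
  terms <- unique(ann$term[ann$gene == gene])
  if (length(terms) == 0L) stop("gene not in corpus: ", gene)
  if (!is.null(aspect)) {
    if (is.null(graph)) stop("aspect filtering requires `graph`")
    asp <- stats::setNames(graph$terms$aspect, graph$terms$id)
    terms <- terms[!is.na(asp[terms]) & asp[terms] == aspect]
    if (length(terms) == 0L) stop("gene ", gene, " is unannotated in aspect ", aspect)
  }
  csort(terms)
}

#' Read a GAF 2.x gene-association file
#'
#' Parses tab-separated GAF rows (comment lines start with `!`): gene id from
#' column 2, GO id from column 5, evidence code from column 7, aspect letter
#' from column 9. Rows with a `NOT` qualifier (column 4) are excluded, as is
#' every row outside the requested aspect or (when `evidence` is given)
#' outside the evidence-code filter. Rows referencing terms absent from the
#' graph are dropped, counted, and reported in a warning.
#'
#' @param file path to a GAF file.
#' @param graph the companion [ontology_graph()].
#' @param aspect aspect to retain (`"BP"`, `"MF"`, `"CC"`).
#' @param evidence optional character vector of evidence codes to keep;
#'   default keeps all codes.
#' @param aliases optional 2-column data.frame (or named character vector)
#'   mapping gene aliases to canonical ids, applied to column 2.
#' @return An [annotation_corpus()] restricted to `aspect`.
#' @export
read_gaf <- function(file, graph, aspect, evidence = NULL, aliases = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) stop("no annotations in GAF input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 9L
  if (any(short)) stop("malformed GAF row(s) with fewer than 9 columns: ",
                       sum(short), " row(s)")
  gene <- vapply(fields, `[[`, character(1), 2L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  ev <- vapply(fields, `[[`, character(1), 7L)
  asp_letter <- vapply(fields, `[[`, character(1), 9L)

  if (!is.null(aliases)) {
    if (is.data.frame(aliases)) {
      aliases <- stats::setNames(as.character(aliases[[2L]]), as.character(aliases[[1L]]))
    }
    hit <- gene %in% names(aliases)
    gene[hit] <- unname(aliases[gene[hit]])
  }

  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  keep <- keep & !is.na(GAF_ASPECT_LETTER[asp_letter]) & GAF_ASPECT_LETTER[asp_letter] == aspect
  if (!is.null(evidence)) keep <- keep & ev %in% evidence
  if (!any(keep)) stop("no annotations after filtering (aspect ", aspect, ")")

  annotation_corpus(
    data.frame(gene = gene[keep], term = term[keep], evidence = ev[keep],
               stringsAsFactors = FALSE),
    graph = graph
  )
}

#' Write an annotation corpus as GAF 2.2
#'
#' @param corpus an [annotation_corpus()].
#' @param graph the companion [ontology_graph()] (supplies aspect letters).
#' @param file output path.
#' @export
write_gaf <- function(corpus, graph, file) {
  asp <- stats::setNames(graph$terms$aspect, graph$terms$id)
  letter <- stats::setNames(names(GAF_ASPECT_LETTER), GAF_ASPECT_LETTER)
  ann <- corpus$annotations
  rows <- vapply(seq_len(nrow(ann)), function(i) {
    paste(c("SYNT", ann$gene[i], ann$gene[i], "", ann$term[i], "SYNT:0000001",
            ann$evidence[i], "", letter[[asp[[ann$term[i]]]]], ann$gene[i], "",
            "protein", "taxon:0000", "20260101", "SYNT", "", ""),
          collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.2", rows), file)
  invisible(file)
}
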