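# Information content: IC(t) = -log(G_t / G_Tot), with annotation counts
# propagated to ancestors so that IC is monotone non-decreasing with depth.

#' Construct an information-content table
#'
#' @param ic named numeric vector, term id -> IC (non-negative; `Inf` marks
#'   terms with no annotated gene).
#' @param total_genes the gene-universe size behind the table (may be `NA`
#'   for externally supplied IC values).
#' @return An object of class `ic_table`.
#' @export
ic_table <- function(ic, total_genes = NA_real_) {
  stopifnot(is.numeric(ic), !is.null(names(ic)), all(nzchar(names(ic))))
  if (any(ic < 0, na.rm = TRUE)) stop("IC values must be non-negative")
  structure(list(ic = ic, total_genes = as.numeric(total_genes)), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table:", length(x$ic), "terms;",
      sum(is.finite(x$ic)), "finite, range [",
      round(min(x$ic[is.finite(x$ic)]), 3), ",",
      round(max(x$ic[is.finite(x$ic)]), 3), "]\n")
  invisible(x)
}

ic_of <- function(ic, terms) {
  v <- ic$ic[terms]
  if (anyNA(v)) stop("term(s) missing from IC table: ",
                     paste(terms[is.na(v)], collapse = ", "))
  v
}

#' Compute per-term information content from an annotation corpus
#'
#' IC(t) = -log(G_t / G_Tot) where G_t is the number of genes annotated to t.
#' With `propagate = TRUE` (the default, and the convention assumed by all
#' measures here) a gene annotated to t also counts for every ancestor of t,
#' which makes IC monotone along edges (child >= parent) and gives the aspect
#' root IC 0 whenever the gene universe equals the annotated genes. Terms with
#' no annotated gene get the `+Inf` sentinel (they contribute nothing to
#' inverse-IC path weights but remain traversable).
#'
#' @param corpus an [annotation_corpus()].
#' @param graph the companion [ontology_graph()].
#' @param log_base logarithm base, > 1; natural log by default.
#' @param propagate propagate annotations to ancestors before counting.
#' @return An [ic_table()] covering every term of the graph.
#' @export
compute_ic <- function(corpus, graph, log_base = exp(1), propagate = TRUE) {
  stopifnot(inherits(corpus, "annotation_corpus"), inherits(graph, "ontology_graph"))
  if (!is.finite(log_base) || log_base <= 1) stop("log_base must be > 1")
  g_tot <- corpus$total_genes
  if (is.na(g_tot) || g_tot <= 0) stop("corpus gene universe (G_Tot) must be positive")

  ann <- corpus$annotations
  ann <- ann[ann$term %in% graph$terms$id, , drop = FALSE]
  if (nrow(ann) == 0L) stop("corpus has no annotations to terms of the graph")

  counts <- stats::setNames(numeric(nrow(graph$terms)), graph$terms$id)
  for (terms_g in split(ann$term, ann$gene)) {
    terms_g <- unique(terms_g)
    if (propagate) {
      terms_g <- unique(c(terms_g, unlist(lapply(terms_g, function(t) term_ancestors(graph, t)),
                                          use.names = FALSE)))
    }
    counts[terms_g] <- counts[terms_g] + 1
  }
  ic <- ifelse(counts > 0, -log(counts / g_tot) / log(log_base), Inf)
  ic[ic < 0] <- 0  # guard against -0 from counts == g_tot
  ic_table(stats::setNames(as.numeric(ic), names(counts)), total_genes = g_tot)
}

#' Write / read an IC table as 2-column TSV
#'
#' The TSV has columns `term` and `ic` (`Inf` spelled literally) plus a
#' `! total_genes:` header comment, so computed tables can be archived and
#' re-used reproducibly.
#'
#' @param ic an [ic_table()].
#' @param file path.
#' @return `read_ic_table` returns an [ic_table()].
#' @export
write_ic_table <- function(ic, file) {
  ids <- csort(names(ic$ic))
  writeLines(c(paste0("! total_genes: ", ic$total_genes),
               "term\tic",
               paste(ids, format(ic$ic[ids], digits = 17, trim = TRUE), sep = "\t")),
             file)
  invisible(file)
}

#' @rdname write_ic_table
#' @export
read_ic_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  tot <- NA_real_
  header <- grep("^! total_genes:", lines, value = TRUE)
  if (length(header)) {
    tot_str <- trimws(sub("^! total_genes:\\s*", "", header[1L]))
    if (!tot_str %in% c("NA", "NaN", "")) tot <- as.numeric(tot_str)
  }
  lines <- lines[!startsWith(lines, "!")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"), stringsAsFactors = FALSE)
  ic_table(stats::setNames(as.numeric(df$ic), df$term), total_genes = tot)
}
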