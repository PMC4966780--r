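# Batch entry points behind the command-line interface. Each run_* function
# loads the ontology/annotations once, executes the requested computation and
# writes deterministic TSV output (similarities at 6 decimals).

#' Build a run configuration
#'
#' Bundles and validates the inputs shared by the batch entry points.
#'
#' @param obo path to an OBO ontology file.
#' @param gaf path to a GAF annotation file (optional for term-level runs).
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @param measure one of `"topoicsim"`, `"intelligo"`, `"wang"`, `"lord"`,
#'   `"mubaid"`, `"simgic"`.
#' @param aggregator `"rcmax"`, `"avg"` or `"bma"` (TopoICSim only).
#' @param evidence optional character vector of evidence codes to keep.
#' @param log_base IC logarithm base.
#' @param seed RNG seed for stochastic subcommands.
#' @param on_missing `"fail"` or `"skip"` for genes without usable annotations.
#' @param ic_file optional IC table TSV overriding the corpus-computed ICs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(obo, gaf = NULL, aspect = "BP", measure = "topoicsim",
                       aggregator = "rcmax", evidence = NULL, log_base = exp(1),
                       seed = 1L, on_missing = c("fail", "skip"), ic_file = NULL) {
  aspect <- match.arg(aspect, c("BP", "MF", "CC"))
  measure <- match.arg(measure, c("topoicsim", "intelligo", "wang", "lord",
                                  "mubaid", "simgic"))
  aggregator <- match.arg(aggregator, c("rcmax", "avg", "bma"))
  on_missing <- match.arg(on_missing)
  for (f in c(obo, gaf, ic_file)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(obo = obo, gaf = gaf, aspect = aspect, measure = measure,
                 aggregator = aggregator, evidence = evidence,
                 log_base = log_base, seed = as.integer(seed),
                 on_missing = on_missing, ic_file = ic_file),
            class = "run_config")
}

load_run_inputs <- function(config) {
  graph <- read_obo(config$obo, aspect = config$aspect)
  corpus <- if (!is.null(config$gaf)) {
    read_gaf(config$gaf, graph, aspect = config$aspect, evidence = config$evidence)
  }
  ic <- if (!is.null(config$ic_file)) {
    read_ic_table(config$ic_file)
  } else if (!is.null(corpus)) {
    compute_ic(corpus, graph, log_base = config$log_base)
  } else {
    stop("either a GAF file or an IC table is required")
  }
  list(graph = graph, corpus = corpus, ic = ic)
}

write_tsv <- function(df, file) {
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}

fmt6 <- function(x) formatC(x, digits = 6, format = "f")

#' Batch gene-pair similarity
#'
#' Reads a 2-column TSV of gene-id pairs (no header) and writes one row per
#' pair: gene1, gene2, similarity (6 decimals), n_terms1, n_terms2. Output
#' row order follows the input; reruns on identical input are byte-identical.
#'
#' @param config a [run_config()] (must include a GAF).
#' @param pairs_file path to the gene-pair TSV.
#' @param out optional output TSV path.
#' @return The result data.frame, invisibly when `out` is given.
#' @export
run_gene_sim <- function(config, pairs_file, out = NULL) {
  if (!file.exists(pairs_file)) stop("input file not found: ", pairs_file)
  inputs <- load_run_inputs(config)
  if (is.null(inputs$corpus)) stop("gene similarity requires a GAF file")
  pairs <- utils::read.delim(pairs_file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("pairs file must have two tab-separated columns")
  f <- measure_function(inputs$graph, inputs$ic, inputs$corpus, config$aspect,
                        config$measure, config$aggregator)
  n_terms_of <- function(g) {
    tryCatch(length(gene_terms(inputs$corpus, g, inputs$graph, config$aspect)),
             error = function(e) 0L)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- as.character(pairs[i, 1L])
    g2 <- as.character(pairs[i, 2L])
    sim <- tryCatch(f(g1, g2), error = function(e) {
      if (config$on_missing == "skip") {
        warning("skipping pair (", g1, ", ", g2, "): ", conditionMessage(e))
        return(NA_real_)
      }
      stop(e)
    })
    data.frame(gene1 = g1, gene2 = g2, similarity = sim,
               n_terms1 = n_terms_of(g1), n_terms2 = n_terms_of(g2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[!is.na(res$similarity), , drop = FALSE]
  out_df <- res
  out_df$similarity <- fmt6(out_df$similarity)
  write_tsv(out_df, out)
  invisible(res)
}

#' Batch gene-set evaluation
#'
#' Reads a 2-column TSV (set label, gene id; no header) and writes per-set
#' IntraSet/DP/IDP plus the InterSet matrix. With a single set, DP and IDP
#' are reported as NA.
#'
#' @param config a [run_config()] (must include a GAF).
#' @param sets_file path to the gene-set TSV.
#' @param out optional output prefix; writes `<out>_sets.tsv` and
#'   `<out>_interset.tsv`.
#' @return The [eval_gene_sets()] report, invisibly.
#' @export
run_set_eval <- function(config, sets_file, out = NULL) {
  if (!file.exists(sets_file)) stop("input file not found: ", sets_file)
  inputs <- load_run_inputs(config)
  if (is.null(inputs$corpus)) stop("set evaluation requires a GAF file")
  df <- tryCatch(utils::read.delim(sets_file, header = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("empty or malformed gene-set file: ",
                                          sets_file, call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed gene-set file")
  sets <- split(as.character(df[[2L]]), as.character(df[[1L]]))
  report <- eval_gene_sets(inputs$graph, inputs$ic, inputs$corpus, sets,
                           config$aspect, measure = config$measure,
                           aggregator = config$aggregator,
                           on_missing = config$on_missing)
  if (!is.null(out)) {
    write_tsv(data.frame(set = names(report$intraset),
                         intraset = fmt6(report$intraset),
                         dp = fmt6(report$dp), idp = fmt6(report$idp),
                         stringsAsFactors = FALSE),
              paste0(out, "_sets.tsv"))
    im <- data.frame(set = rownames(report$interset),
                     apply(report$interset, 2L, fmt6),
                     stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv(im, paste0(out, "_interset.tsv"))
  }
  invisible(report)
}

#' Batch annotation-length-bias audit
#'
#' Runs [length_bias_audit()] with the configured measure over the configured
#' ontology/corpus and writes per-size mean scores plus the Spearman summary.
#'
#' @param config a [run_config()].
#' @param sizes integer group sizes.
#' @param n_pairs random pairs per size.
#' @param out optional output TSV path.
#' @return The audit result list, invisibly.
#' @export
run_bias_audit <- function(config, sizes = 1:10, n_pairs = 100L, out = NULL) {
  inputs <- load_run_inputs(config)
  measure <- if (config$measure == "topoicsim") NULL else {
    stop("the bias audit currently supports measure = 'topoicsim' only")
  }
  res <- length_bias_audit(inputs$graph, inputs$ic, measure = measure,
                           sizes = sizes, n_pairs = n_pairs, seed = config$seed)
  if (!is.null(out)) {
    df <- res$per_size
    df$mean_score <- fmt6(df$mean_score)
    df$spearman_r <- fmt6(res$spearman_r)
    df$p_value <- fmt6(res$p_value)
    write_tsv(df, out)
  }
  invisible(res)
}
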