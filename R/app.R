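## High-level estimation pipeline tying the modules together; the shell
## interface in inst/cli/mpest.R is a thin wrapper over these functions.

#' Estimate the species tree from rooted gene trees
#'
#' The full pipeline: optionally (re)root every gene tree by a known
#' outgroup, build the triple count table, and maximize the pseudo
#' likelihood over topology and internal branch lengths. Exhaustive search
#' is used automatically for small taxon sets (N <= 6); otherwise NNI hill
#' climbing with restarts (10 by default, 25 for N > 20).
#'
#' @param gene_trees a list of rooted \code{"phylo"} objects, or a file
#'   path of newick trees.
#' @param outgroup optional outgroup label: each gene tree is rerooted by
#'   it and genes missing the outgroup are skipped with a warning. When
#'   omitted, input trees are taken as already rooted.
#' @param taxa optional taxon set; defaults to the union over gene trees.
#' @param restarts hill-climbing restarts; default depends on N.
#' @param seed integer seed for the stochastic search.
#' @return a list of class \code{"mpest_estimate"}: \code{fit} (the
#'   \code{"mpest_fit"}), \code{search} (the \code{"mpest_search"}),
#'   \code{counts}, \code{n_genes_used}, \code{n_genes_skipped}.
#' @examples
#' gts <- lapply(c("((a,b),c);", "((a,b),c);", "((a,c),b);"), read_newick)
#' est <- estimate_species_tree(gts, seed = 1)
#' est$fit$logPL
#' @export
estimate_species_tree <- function(gene_trees, outgroup = NULL, taxa = NULL,
                                  restarts = NULL, seed = 1L) {
  if (is.character(gene_trees) && length(gene_trees) == 1L)
    gene_trees <- read_gene_trees(gene_trees)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  skipped <- 0L
  if (!is.null(outgroup)) {
    keep <- vapply(gene_trees, function(g) outgroup %in% g$tip.label, TRUE)
    skipped <- sum(!keep)
    if (skipped)
      warning(skipped, " gene tree(s) lack the outgroup '", outgroup,
              "' and were skipped", call. = FALSE)
    gene_trees <- lapply(gene_trees[keep], root_by_outgroup, outgroup)
    if (!length(gene_trees))
      stop("no gene tree contains the outgroup", call. = FALSE)
  }
  counts <- count_triples(gene_trees, taxa = taxa)
  N <- length(attr(counts, "taxa"))
  if (is.null(restarts)) restarts <- if (N <= 20L) 10L else 25L
  search <- if (N <= 6L) exhaustive_search(counts)
            else hill_climb(counts, restarts = restarts, seed = seed)
  structure(list(fit = search$fit, search = search, counts = counts,
                 n_genes_used = length(gene_trees),
                 n_genes_skipped = skipped, seed = seed),
            class = "mpest_estimate")
}

#' @export
print.mpest_estimate <- function(x, ...) {
  cat("MP-EST species-tree estimate\n")
  cat("  genes used:", x$n_genes_used,
      if (x$n_genes_skipped) paste0("(", x$n_genes_skipped, " skipped)"),
      "\n")
  cat("  taxa:", length(attr(x$counts, "taxa")),
      " trios:", nrow(x$counts), "\n")
  print(x$search)
  invisible(x)
}

#' Run the estimation pipeline with file input/output and a run log
#'
#' @param genetrees path to a newick file of rooted gene trees.
#' @param outgroup optional outgroup label (see
#'   [estimate_species_tree()]).
#' @param out optional path for the fitted species tree (newick; sentinel
#'   branches carry length 99).
#' @param dump_counts optional path for a TSV dump of the triple count
#'   table.
#' @param restarts,seed search parameters.
#' @param log a function receiving log lines (default \code{message}).
#' @return the \code{"mpest_estimate"}, invisibly.
#' @export
run_estimate <- function(genetrees, outgroup = NULL, out = NULL,
                         dump_counts = NULL, restarts = NULL, seed = 1L,
                         log = message) {
  gts <- read_gene_trees(genetrees)
  est <- estimate_species_tree(gts, outgroup = outgroup,
                               restarts = restarts, seed = seed)
  counts <- est$counts
  taxa <- attr(counts, "taxa")
  log(sprintf("seed: %d", seed))
  log(sprintf("N = %d taxa, M = %d gene trees used (%d skipped)",
              length(taxa), est$n_genes_used, est$n_genes_skipped))
  log(sprintf("per-trio coverage: min %g, max %g",
              min(counts$M), max(counts$M)))
  log(sprintf("counts checksum: %.6f", sum(counts$x1 * 1 + counts$x2 * 2 +
                                             counts$x3 * 3)))
  log(sprintf("search: %s, %d topologies scored, best log-PL %.6f",
              est$search$method, est$search$n_evaluated, est$fit$logPL))
  sent <- which(est$fit$sentinel)
  for (i in sent)
    log(sprintf("inestimable branch (sentinel 99): {%s}",
                est$fit$edge_clades[i]))
  for (i in which(!est$fit$sentinel & est$fit$T == 0))
    log(sprintf("zero-length branch (polytomy-consistent): {%s}",
                est$fit$edge_clades[i]))
  if (!is.null(dump_counts)) write_triple_counts(counts, dump_counts)
  if (!is.null(out)) writeLines(write_newick(est$fit$tree), out)
  invisible(est)
}
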