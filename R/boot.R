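## Gene-level nonparametric bootstrap: genes are resampled with
## replacement, the species tree is re-estimated per replicate, and the
## replicate topologies are summarized by a majority-rule-extended
## consensus whose clade frequencies are the support values. Site-level
## resampling within genes requires re-estimating gene trees from
## sequences with an external ML program; supply such externally produced
## per-replicate gene-tree files via `replicate_trees` to use the
## two-level scheme.

#' Draw gene-level bootstrap replicates
#'
#' @param gene_trees a list of rooted \code{"phylo"} objects (M genes).
#' @param B number of replicates.
#' @param seed integer seed; replicate index lists are reproducible.
#' @return a list of class \code{"bootstrap_run"} with \code{indices}
#'   (B integer vectors of length M), \code{gene_trees}, \code{seed}.
#' @export
gene_bootstrap <- function(gene_trees, B, seed = 1L) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  M <- length(gene_trees)
  if (M < 1L) stop("need at least one gene tree", call. = FALSE)
  if (B < 1L) stop("need at least one replicate", call. = FALSE)
  idx <- with_local_seed(seed, {
    lapply(seq_len(B), function(b) sample.int(M, M, replace = TRUE))
  })
  structure(list(indices = idx, gene_trees = gene_trees, seed = seed,
                 estimates = NULL),
            class = "bootstrap_run")
}

#' Estimate the species tree for every bootstrap replicate
#'
#' @param run a [gene_bootstrap()] result.
#' @param taxa optional taxon set (defaults to the union over genes).
#' @param restarts hill-climbing restarts per replicate (ignored when the
#'   taxon set is small enough for exhaustive search).
#' @return the run with \code{estimates} filled: one \code{"phylo"} per
#'   replicate.
#' @export
bootstrap_estimates <- function(run, taxa = NULL, restarts = 10L) {
  stopifnot(inherits(run, "bootstrap_run"))
  run$estimates <- lapply(seq_along(run$indices), function(b) {
    reps <- run$gene_trees[run$indices[[b]]]
    counts <- count_triples(reps, taxa = taxa)
    res <- if (length(attr(counts, "taxa")) <= 6L) exhaustive_search(counts)
           else hill_climb(counts, restarts = restarts,
                           seed = (run$seed + 7919L * b) %% 2147483647L)
    res$fit$tree
  })
  run
}

#' Consensus support tree from a bootstrap run
#'
#' Majority-rule-extended consensus of the replicate species-tree
#' topologies; clade frequencies over replicates become the support values
#' (internal-node labels). Branch lengths are not summarized here: report
#' lengths from the full-data fit alongside these supports.
#'
#' @param run a \code{"bootstrap_run"}; estimates are computed first if
#'   absent.
#' @param threshold consensus inclusion threshold in \code{[0.5, 1]}.
#' @param ... passed to [bootstrap_estimates()] when estimates are missing.
#' @return a \code{"phylo"} whose \code{node.label} carries supports.
#' @export
bootstrap_support <- function(run, threshold = 0.5, ...) {
  stopifnot(inherits(run, "bootstrap_run"))
  if (is.null(run$estimates)) run <- bootstrap_estimates(run, ...)
  majority_consensus(run$estimates, threshold = threshold, extended = TRUE)
}
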