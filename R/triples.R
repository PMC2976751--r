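## Rooted-triple extraction and the triple count table, the sufficient
## statistic of the pseudo-likelihood. For a sorted trio (a, b, c) the three
## resolutions are stored in the canonical slot order
##   slot 1: ab|c    slot 2: ac|b    slot 3: bc|a
## so the table layout is stable across runs and serializations.

trio_slot <- function(trio, cherry) {
  ## trio sorted; cherry = the 2 labels forming the cherry
  if (setequal(cherry, trio[c(1L, 2L)])) return(1L)
  if (setequal(cherry, trio[c(1L, 3L)])) return(2L)
  3L
}

slot_name <- function(trio, slot) {
  pair <- switch(slot, trio[c(1L, 2L)], trio[c(1L, 3L)], trio[c(2L, 3L)])
  paste0(paste(pair, collapse = ","), "|", setdiff(trio, pair))
}

## clade membership matrix of a tree over `taxa` (clades x taxa, logical),
## internal non-root nodes only
clade_membership <- function(tree, taxa) {
  cl <- tree_clades(tree)
  m <- matrix(FALSE, length(cl), length(taxa))
  for (i in seq_along(cl)) m[i, match(cl[[i]], taxa)] <- TRUE
  m
}

#' Resolution of one rooted triple in a gene tree
#'
#' The induced rooted topology on a 3-taxon subset: the cherry is the pair
#' whose most recent common ancestor excludes the third taxon;
#' \code{"unresolved"} when the induced subtree is a tritomy.
#'
#' @param gene_tree a rooted \code{"phylo"} object.
#' @param trio character vector of three leaf labels of \code{gene_tree}.
#' @return a string \code{"x,y|z"} naming the cherry pair and the odd
#'   taxon out, or \code{"unresolved"}.
#' @examples
#' resolve_triple(read_newick("((a,b),c);"), c("a", "b", "c"))
#' @export
resolve_triple <- function(gene_tree, trio) {
  trio <- sort(unique(trio))
  if (length(trio) != 3L) stop("trio must contain three distinct labels",
                               call. = FALSE)
  miss <- setdiff(trio, gene_tree$tip.label)
  if (length(miss))
    stop("label(s) not in gene tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- clade_membership(gene_tree, trio)
  s <- rowSums(m)
  w <- which(s == 2L)
  if (!length(w)) return("unresolved")
  cherry <- trio[m[w[1L], ]]
  slot_name(trio, trio_slot(trio, cherry))
}

#' Triple count table from a collection of gene trees
#'
#' For every 3-subset of \code{taxa}, accumulates over the gene trees the
#' weights of the three possible rooted-triple resolutions: a resolved
#' triple adds 1 to its slot, an unresolved (polytomic) triple adds 1/3 to
#' each of the three slots, and gene trees missing any member of the trio
#' contribute nothing to that trio (random missingness is assumed). The
#' per-trio effective gene count is \code{M = x1 + x2 + x3}.
#'
#' Each species must be represented by at most one leaf per gene tree;
#' multiple alleles per species are rejected.
#'
#' @param gene_trees a list of rooted \code{"phylo"} objects.
#' @param taxa the species set; defaults to the union of all leaf labels.
#' @return a \code{data.frame} of class \code{"triple_counts"} with columns
#'   \code{a, b, c} (the sorted trio), \code{x1, x2, x3} (weights in the
#'   canonical slot order \code{ab|c, ac|b, bc|a}) and \code{M}.
#' @export
count_triples <- function(gene_trees, taxa = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) stop("need at least one gene tree", call. = FALSE)
  labs <- lapply(gene_trees, `[[`, "tip.label")
  if (is.null(taxa)) taxa <- sort(unique(unlist(labs)))
  taxa <- sort(taxa)
  N <- length(taxa)
  for (i in seq_along(labs)) {
    if (anyDuplicated(labs[[i]]))
      stop("gene tree ", i, " samples multiple alleles of ",
           paste(unique(labs[[i]][duplicated(labs[[i]])]), collapse = ", "),
           "; a single lineage per species is required", call. = FALSE)
    extra <- setdiff(labs[[i]], taxa)
    if (length(extra))
      stop("gene tree ", i, " has leaves outside the taxon set: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  if (N < 3L) stop("need at least three taxa", call. = FALSE)
  trios <- utils::combn(N, 3L)              # columns are sorted index trios
  ntr <- ncol(trios)
  x <- matrix(0, ntr, 3L)
  for (g in gene_trees) {
    idx <- match(g$tip.label, taxa)
    pres <- logical(N); pres[idx] <- TRUE
    cl <- tree_clades(g)
    cm <- matrix(FALSE, length(cl), N)
    for (i in seq_along(cl)) cm[i, match(cl[[i]], taxa)] <- TRUE
    for (j in seq_len(ntr)) {
      t3 <- trios[, j]
      if (!all(pres[t3])) next
      s <- cm[, t3[1L]] + cm[, t3[2L]] + cm[, t3[3L]]
      w <- which(s == 2L)
      if (!length(w)) {
        x[j, ] <- x[j, ] + 1 / 3
      } else {
        pair_in <- cm[w[1L], t3]
        slot <- if (pair_in[1L] && pair_in[2L]) 1L
                else if (pair_in[1L] && pair_in[3L]) 2L else 3L
        x[j, slot] <- x[j, slot] + 1
      }
    }
  }
  out <- data.frame(a = taxa[trios[1L, ]], b = taxa[trios[2L, ]],
                    c = taxa[trios[3L, ]],
                    x1 = x[, 1L], x2 = x[, 2L], x3 = x[, 3L],
                    M = rowSums(x), stringsAsFactors = FALSE)
  attr(out, "taxa") <- taxa
  class(out) <- c("triple_counts", "data.frame")
  out
}

#' Build a triple count table from explicit weights
#'
#' @param df data.frame with columns \code{a, b, c, x1, x2, x3} (trio
#'   labels need not be pre-sorted; slots are permuted to the canonical
#'   order when sorting the labels).
#' @return a \code{"triple_counts"} table covering all 3-subsets of the
#'   taxa appearing in \code{df}; trios absent from \code{df} get zero
#'   weights.
#' @export
as_triple_counts <- function(df) {
  need <- c("a", "b", "c", "x1", "x2", "x3")
  if (!all(need %in% names(df)))
    stop("df must have columns ", paste(need, collapse = ", "), call. = FALSE)
  taxa <- sort(unique(c(df$a, df$b, df$c)))
  N <- length(taxa)
  trios <- utils::combn(N, 3L)
  key <- function(a, b, c) paste(a, b, c, sep = "\t")
  out <- data.frame(a = taxa[trios[1L, ]], b = taxa[trios[2L, ]],
                    c = taxa[trios[3L, ]], x1 = 0, x2 = 0, x3 = 0,
                    stringsAsFactors = FALSE)
  rk <- key(out$a, out$b, out$c)
  for (i in seq_len(nrow(df))) {
    labs <- c(df$a[i], df$b[i], df$c[i])
    if (anyDuplicated(labs)) stop("trio with duplicated labels", call. = FALSE)
    ord <- order(labs)
    srt <- labs[ord]
    ## slot h of the input row is the resolution pairing labs[-h]'s
    ## complement... map by cherry pair
    xs <- c(df$x1[i], df$x2[i], df$x3[i])
    row <- match(key(srt[1L], srt[2L], srt[3L]), rk)
    for (h in 1:3) {
      pair <- switch(h, labs[c(1L, 2L)], labs[c(1L, 3L)], labs[c(2L, 3L)])
      out[row, 3L + trio_slot(srt, pair)] <-
        out[row, 3L + trio_slot(srt, pair)] + xs[h]
    }
  }
  out$M <- out$x1 + out$x2 + out$x3
  attr(out, "taxa") <- taxa
  class(out) <- c("triple_counts", "data.frame")
  out
}

#' Write a triple count table as TSV
#'
#' Columns: \code{trio} (slash-separated sorted labels), \code{x1},
#' \code{x2}, \code{x3}, \code{M}.
#'
#' @param counts a \code{"triple_counts"} table.
#' @param path output file path.
#' @export
write_triple_counts <- function(counts, path) {
  df <- data.frame(trio = paste(counts$a, counts$b, counts$c, sep = "/"),
                   x1 = counts$x1, x2 = counts$x2, x3 = counts$x3,
                   M = counts$M)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
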