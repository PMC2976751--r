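## The core of the method: every 3-subset of species contributes a
## multinomial term in which the probability that a gene-tree triple
## matches the species-tree triple with internal branch B (coalescent
## units) is 1 - (2/3) e^{-B}, and each mismatching resolution has
## probability (1/3) e^{-B}. The branch B of a species-tree triple is the
## sum of the internal species-tree edges on the path from the cherry's
## MRCA to the trio's MRCA, which couples the C(N,3) terms through the
## N - 2 internal edge lengths T.

#' Sentinel length marking an inestimable internal branch
#'
#' An internal branch whose every relevant gene-tree triple matches the
#' species tree has unbounded pseudo-likelihood in its length; its length
#' is reported as the conventional sentinel value 99 rather than a number.
#' @export
SENTINEL_LENGTH <- 99

## internal (non-root, non-tip) node ids, i.e. the children of the N-2
## internal edges of a rooted binary tree; deterministic order
internal_edge_nodes <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  sort(setdiff(tree$edge[, 2L], seq_len(n)))
}

parent_vec <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  p <- rep(NA_integer_, nn)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  p <- parent_vec(tree)
  d <- rep(NA_integer_, length(p))
  d[n + 1L] <- 0L
  ## walk down in preorder
  pr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pr$edge)))
    d[pr$edge[i, 2L]] <- d[pr$edge[i, 1L]] + 1L
  d
}

#' Decompose a species tree into rooted triples and their branch sums
#'
#' For each 3-subset of the species tree's leaves, records the species-tree
#' resolution of the trio and the set of internal edges whose lengths sum
#' to the triple's internal branch length B: exactly the internal edges on
#' the path from the MRCA of the cherry pair up to (excluding) the MRCA of
#' the whole trio.
#'
#' @param tree a rooted binary \code{"phylo"} object with \code{N >= 3}
#'   leaves.
#' @return a list with elements \code{taxa}, \code{trios} (data.frame
#'   \code{a,b,c} plus \code{slot}, the canonical slot of the species-tree
#'   resolution), \code{A} (0/1 incidence matrix, trios x internal edges),
#'   and \code{edge_nodes} (the child node id of each internal edge, fixing
#'   the column order).
#' @export
decompose_triples <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 3L) stop("species tree must have at least 3 leaves", call. = FALSE)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("species tree must be rooted and binary", call. = FALSE)
  taxa <- sort(tree$tip.label)
  tipid <- match(taxa, tree$tip.label)
  mm <- ape::mrca(tree)                     # tip x tip mrca node ids
  dep <- node_depths(tree)
  par <- parent_vec(tree)
  enodes <- internal_edge_nodes(tree)
  nedge <- length(enodes)
  trios <- utils::combn(length(taxa), 3L)
  ntr <- ncol(trios)
  A <- matrix(0L, ntr, nedge)
  slot <- integer(ntr)
  for (j in seq_len(ntr)) {
    t3 <- trios[, j]
    ids <- tipid[t3]
    m12 <- mm[ids[1L], ids[2L]]
    m13 <- mm[ids[1L], ids[3L]]
    m23 <- mm[ids[2L], ids[3L]]
    ms <- c(m12, m13, m23)
    sl <- which.max(dep[ms])                # deepest pairwise MRCA = cherry
    slot[j] <- sl
    top <- ms[-sl][1L]                      # trio MRCA (other two coincide)
    v <- ms[sl]
    while (v != top) {
      A[j, match(v, enodes)] <- 1L
      v <- par[v]
    }
  }
  list(taxa = taxa,
       trios = data.frame(a = taxa[trios[1L, ]], b = taxa[trios[2L, ]],
                          c = taxa[trios[3L, ]], slot = slot,
                          stringsAsFactors = FALSE),
       A = A, edge_nodes = enodes)
}

## align a triple_counts table with a decomposition; returns per-trio
## matching count x1 and mismatch total; errors on uncovered trios
align_counts <- function(decomp, counts) {
  if (!inherits(counts, "triple_counts"))
    stop("counts must be a 'triple_counts' table", call. = FALSE)
  if (!setequal(attr(counts, "taxa"), decomp$taxa))
    stop("counts and species tree are over different taxon sets",
         call. = FALSE)
  ck <- paste(counts$a, counts$b, counts$c, sep = "\t")
  dk <- paste(decomp$trios$a, decomp$trios$b, decomp$trios$c, sep = "\t")
  rows <- match(dk, ck)
  if (anyNA(rows)) stop("counts table is missing trios", call. = FALSE)
  X <- as.matrix(counts[rows, c("x1", "x2", "x3")])
  M <- counts$M[rows]
  bad <- which(M <= 0)
  if (length(bad))
    stop("no gene tree covers trio(s): ",
         paste(dk[bad[seq_len(min(5L, length(bad)))]], collapse = "; "),
         call. = FALSE)
  xm <- X[cbind(seq_len(nrow(X)), decomp$trios$slot)]
  list(xmatch = xm, xother = M - xm, M = M)
}

pl_value <- function(Tlen, decomp, al) {
  B <- as.numeric(decomp$A %*% Tlen)
  p <- 1 - (2 / 3) * exp(-B)
  term1 <- ifelse(al$xmatch > 0, al$xmatch * log(p), 0)
  sum(term1 + al$xother * (log(1 / 3) - B))
}

pl_grad <- function(Tlen, decomp, al) {
  B <- as.numeric(decomp$A %*% Tlen)
  e <- (2 / 3) * exp(-B)
  g <- al$xmatch * e / (1 - e) - al$xother
  as.numeric(crossprod(decomp$A, g))
}

#' Log pseudo-likelihood of a species tree given triple counts
#'
#' Evaluates \eqn{\sum_j [x_{j1} \log(1 - (2/3) e^{-B_j}) +
#' (x_{j2}+x_{j3}) \log((1/3) e^{-B_j})]} over all trios j of the species
#' tree, where \eqn{x_{j1}} is the weight of the resolution matching the
#' species tree and \eqn{B_j} the triple's internal branch length. The
#' multinomial coefficient is omitted throughout: it does not depend on the
#' species tree and has no effect on maximization.
#'
#' @param tree a rooted binary species tree; internal edge lengths are
#'   taken from \code{tree$edge.length} unless \code{T} is given.
#' @param counts a \code{"triple_counts"} table covering every trio of the
#'   tree with positive effective count.
#' @param T optional vector of internal branch lengths (coalescent units),
#'   ordered as \code{decompose_triples(tree)$edge_nodes}.
#' @return the log pseudo-likelihood (a non-positive number when all
#'   weights are non-negative and every trio has \code{M >= 1}).
#' @export
log_pseudo_likelihood <- function(tree, counts, T = NULL) {
  decomp <- decompose_triples(tree)
  if (is.null(T)) {
    if (is.null(tree$edge.length))
      stop("tree has no edge lengths and T was not supplied", call. = FALSE)
    len <- rep(NA_real_, ape::Ntip(tree) + tree$Nnode)
    len[tree$edge[, 2L]] <- tree$edge.length
    T <- len[decomp$edge_nodes]
  }
  if (length(T) != length(decomp$edge_nodes))
    stop("T must have one length per internal edge (N-2 values)",
         call. = FALSE)
  if (anyNA(T) || any(!is.finite(T)))
    stop("all internal branch lengths must be finite", call. = FALSE)
  if (any(T < 0)) stop("negative branch length", call. = FALSE)
  al <- align_counts(decomp, counts)
  pl_value(T, decomp, al)
}

#' Closed-form branch-length estimate for a single triple
#'
#' Inverts the matching-triple probability \eqn{1 - (2/3)e^{-B}}: given
#' the weight \code{x} of the most frequent resolution out of \code{M}
#' informative gene trees, the maximum-likelihood branch length is
#' \eqn{\hat B = -\log\{3(1 - x/M)/2\}}. Values of \code{x} at or below
#' \code{M/3} clamp to 0 (a star triple); \code{x = M} means the length is
#' unbounded and the sentinel 99 is returned.
#'
#' @param x weight of the most frequent resolution (may be fractional).
#' @param M effective gene count for the trio, \code{> 0}.
#' @return branch length in coalescent units, or \code{SENTINEL_LENGTH}.
#' @examples
#' triple_mle(4, 6)   # -log(1/2) = 0.693
#' triple_mle(2, 6)   # exactly M/3 -> 0
#' @export
triple_mle <- function(x, M) {
  if (M <= 0) stop("M must be positive", call. = FALSE)
  if (x < 0 || x > M) stop("x must lie in [0, M]", call. = FALSE)
  if (x == M) return(SENTINEL_LENGTH)
  b <- -log(3 * (1 - x / M) / 2)
  max(b, 0)
}

#' Maximize the pseudo-likelihood over branch lengths for a fixed topology
#'
#' Finds the internal branch lengths T (coalescent units) maximizing the
#' log pseudo-likelihood of \code{topology} given \code{counts}. The
#' objective is concave in T, so the box-constrained quasi-Newton ascent
#' used here (warm-started from pooled per-edge closed-form estimates)
#' reaches the global maximum. Edges whose every contributing trio fully
#' matches the species tree have unbounded length and are reported with the
#' sentinel 99, as is any edge whose optimum reaches the box bound
#' \code{t_cap}.
#'
#' @param topology a rooted binary \code{"phylo"} over the taxa of
#'   \code{counts}.
#' @param counts a \code{"triple_counts"} table covering all trios.
#' @param t_cap optimizer box bound in coalescent units; \eqn{e^{-10}}
#'   is far below any resolvable triple-frequency signal.
#' @return an object of class \code{"mpest_fit"}: list with \code{tree}
#'   (the topology with internal edge lengths set; sentinel edges carry
#'   99 and external edges 0), \code{T}, \code{sentinel} (logical per
#'   internal edge), \code{logPL}, \code{edge_clades} (the clade under
#'   each internal edge, for reporting).
#' @export
optimize_branch_lengths <- function(topology, counts, t_cap = 10) {
  decomp <- decompose_triples(topology)
  al <- align_counts(decomp, counts)
  nedge <- ncol(decomp$A)
  ## an edge is structurally inestimable iff all trios through it match fully
  full <- al$xmatch >= al$M - 1e-9
  inest <- vapply(seq_len(nedge), function(i) {
    js <- which(decomp$A[, i] == 1L)
    all(full[js])
  }, TRUE)
  Tlen <- numeric(nedge)
  ## pooled closed-form warm start per edge
  for (i in seq_len(nedge)) {
    js <- which(decomp$A[, i] == 1L)
    b0 <- triple_mle(sum(al$xmatch[js]), sum(al$M[js]))
    Tlen[i] <- if (b0 >= SENTINEL_LENGTH) t_cap else min(max(b0, 0.01), 5)
  }
  Tlen[inest] <- t_cap
  free <- which(!inest)
  if (length(free)) {
    fn <- function(tf) {
      Tlen[free] <- tf
      -pl_value(Tlen, decomp, al)
    }
    gr <- function(tf) {
      Tlen[free] <- tf
      -pl_grad(Tlen, decomp, al)[free]
    }
    opt <- stats::optim(Tlen[free], fn, gr, method = "L-BFGS-B",
                        lower = 0, upper = t_cap,
                        control = list(factr = 10, pgtol = 1e-12,
                                       maxit = 500L))
    Tlen[free] <- opt$par
  }
  logPL <- pl_value(Tlen, decomp, al)
  sentinel <- inest | Tlen >= t_cap - 1e-6
  Treport <- ifelse(sentinel, SENTINEL_LENGTH, Tlen)
  tr <- topology
  lens <- rep(0, nrow(tr$edge))
  lens[match(decomp$edge_nodes, tr$edge[, 2L])] <- Treport
  tr$edge.length <- lens
  attr(tr, "units") <- "coalescent"
  sets <- node_leafsets(topology)
  structure(list(tree = tr, T = Treport, sentinel = sentinel,
                 logPL = logPL,
                 edge_clades = vapply(sets[decomp$edge_nodes], paste, "",
                                      collapse = ","),
                 t_cap = t_cap),
            class = "mpest_fit")
}

#' @export
print.mpest_fit <- function(x, ...) {
  cat("Species tree fit (maximum pseudo-likelihood)\n")
  cat("  log pseudo-likelihood:", format(x$logPL, digits = 10), "\n")
  cat("  internal branch lengths (coalescent units):\n")
  for (i in seq_along(x$T)) {
    tag <- if (x$sentinel[i]) "  [inestimable: sentinel 99]"
           else if (x$T[i] == 0) "  [zero length: polytomy-consistent]"
           else ""
    cat(sprintf("    {%s}: %s%s\n", x$edge_clades[i],
                format(x$T[i], digits = 6), tag))
  }
  cat("  newick:", write_newick(x$tree), "\n")
  invisible(x)
}
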