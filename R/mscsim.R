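## Multispecies-coalescent simulation. Within each branch (ancestral
## population) of the species tree, every pair of extant gene lineages
## coalesces at rate 1 per coalescent time unit; lineages that fail to
## coalesce before the branch ends enter the parent branch, and the root
## population runs until a single lineage remains. With one sampled allele
## per species, nothing can happen on terminal branches, so only internal
## branch durations matter.

## evaluate expr under a local seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Convert a mutation-unit branch length to coalescent units
#'
#' A branch of length \eqn{\tau} expected mutations per site over a
#' population of size \eqn{\theta = 4N\mu} spans \eqn{T = 2\tau/\theta}
#' coalescent units.
#'
#' @param tau branch length in mutation units, \code{>= 0}.
#' @param theta population-scaled mutation parameter, \code{> 0}.
#' @return branch length in coalescent units.
#' @examples
#' to_coalescent_units(0.01, 0.01)   # 2 coalescent units
#' @export
to_coalescent_units <- function(tau, theta) {
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  if (any(tau < 0)) stop("tau must be non-negative", call. = FALSE)
  2 * tau / theta
}

## precompute traversal info for repeated simulation from one species tree
msc_prep <- function(species_tree) {
  tr <- species_tree
  if (!ape::is.rooted(tr)) stop("species tree must be rooted", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("species tree needs branch lengths (coalescent units)",
         call. = FALSE)
  if (any(tr$edge.length >= SENTINEL_LENGTH - 1e-9))
    stop("species tree has sentinel (inestimable) branch lengths; ",
         "these are not simulable", call. = FALSE)
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("species tree branch lengths must be finite and non-negative",
         call. = FALSE)
  n <- ape::Ntip(tr)
  nn <- n + tr$Nnode
  dur <- rep(Inf, nn)                       # branch above each node
  dur[tr$edge[, 2L]] <- tr$edge.length
  depth <- rep(0, nn)
  pr <- ape::reorder.phylo(tr, "cladewise")
  for (i in seq_len(nrow(pr$edge)))
    depth[pr$edge[i, 2L]] <- depth[pr$edge[i, 1L]] + pr$edge.length[i]
  height <- max(depth[seq_len(n)]) - depth
  po <- ape::reorder.phylo(tr, "postorder")
  internal_po <- unique(po$edge[, 1L])      # parents in postorder: children first
  list(tree = tr, n = n, children = node_children(tr), dur = dur,
       height = height, internal_po = internal_po,
       labels = tr$tip.label)
}

## one gene: returns merge records (tip-index sets x, y and absolute time)
msc_sim_raw <- function(prep) {
  n <- prep$n
  surv <- vector("list", n + length(prep$internal_po) + 1L)
  merges_x <- vector("list", n - 1L)
  merges_y <- vector("list", n - 1L)
  times <- numeric(n - 1L)
  nm <- 0L
  for (v in prep$internal_po) {
    pool <- list()
    for (c in prep$children[[v]]) {
      if (c <= n) pool[[length(pool) + 1L]] <- c
      else pool <- c(pool, surv[[c]])
    }
    L <- prep$dur[v]
    t <- 0
    k <- length(pool)
    while (k >= 2L) {
      t <- t + stats::rexp(1L, k * (k - 1L) / 2)
      if (t > L) break
      pick <- sample.int(k, 2L)
      i <- pick[1L]; j <- pick[2L]
      nm <- nm + 1L
      merges_x[[nm]] <- pool[[i]]
      merges_y[[nm]] <- pool[[j]]
      times[nm] <- prep$height[v] + t
      pool[[min(i, j)]] <- c(pool[[i]], pool[[j]])
      pool[[max(i, j)]] <- NULL
      k <- k - 1L
    }
    surv[[v]] <- pool
  }
  list(x = merges_x, y = merges_y, t = times)
}

merges_to_phylo <- function(prep, m) {
  n <- prep$n
  nm <- n - 1L
  node_of <- integer(n)                     # current node id per tip cluster
  node_of[seq_len(n)] <- seq_len(n)
  h <- c(prep$height[seq_len(n)], numeric(nm))
  edge <- matrix(0L, 2L * nm, 2L)
  elen <- numeric(2L * nm)
  ne <- 0L
  for (i in seq_len(nm)) {
    a <- node_of[m$x[[i]][1L]]
    b <- node_of[m$y[[i]][1L]]
    new <- n + i
    ne <- ne + 1L; edge[ne, ] <- c(new, a); elen[ne] <- m$t[i] - h[a]
    ne <- ne + 1L; edge[ne, ] <- c(new, b); elen[ne] <- m$t[i] - h[b]
    h[new] <- m$t[i]
    node_of[c(m$x[[i]], m$y[[i]])] <- new
  }
  ## renumber so the root is n+1 (ape convention): internal node n+i was
  ## created i-th, so the last one (root) must become n+1
  remap <- c(seq_len(n), rev(seq_len(nm)) + n)
  edge[, 1L] <- remap[edge[, 1L]]
  edge[, 2L] <- remap[edge[, 2L]]
  tr <- list(edge = edge, edge.length = elen, Nnode = nm,
             tip.label = prep$labels)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "units") <- "coalescent"
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One allele per species; branch lengths of \code{species_tree} are in
#' coalescent units (use [to_coalescent_units()] first if starting from
#' mutation units and population sizes). Returned gene trees carry
#' coalescent-unit node times as branch lengths.
#'
#' @param species_tree a rooted species tree with finite, non-negative
#'   branch lengths in coalescent units.
#' @param n number of gene trees.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @return a \code{"multiPhylo"} list of rooted gene trees.
#' @export
simulate_gene_trees <- function(species_tree, n = 1L, seed = NULL) {
  prep <- msc_prep(species_tree)
  with_local_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) out[[i]] <- merges_to_phylo(prep, msc_sim_raw(prep))
    class(out) <- "multiPhylo"
    out
  })
}

## tip-pair first-join times from a merge record
pair_join_times <- function(n, m) {
  tt <- matrix(Inf, n, n)
  for (i in seq_along(m$t)) {
    tt[m$x[[i]], m$y[[i]]] <- m$t[i]
    tt[m$y[[i]], m$x[[i]]] <- m$t[i]
  }
  tt
}

#' Simulate a triple count table directly from a species tree
#'
#' Equivalent to \code{count_triples(simulate_gene_trees(...))} but
#' accumulates the table during simulation without materializing the gene
#' trees, which is the path to use for large M.
#'
#' @inheritParams simulate_gene_trees
#' @param M number of gene trees.
#' @return a \code{"triple_counts"} table.
#' @export
simulate_triple_counts <- function(species_tree, M, seed = NULL) {
  prep <- msc_prep(species_tree)
  taxa <- sort(prep$labels)
  ord <- match(taxa, prep$labels)           # taxa index -> tip index
  N <- length(taxa)
  trios <- utils::combn(N, 3L)
  ntr <- ncol(trios)
  x <- matrix(0, ntr, 3L)
  i1 <- ord[trios[1L, ]]; i2 <- ord[trios[2L, ]]; i3 <- ord[trios[3L, ]]
  with_local_seed(seed, {
    for (g in seq_len(M)) {
      tt <- pair_join_times(prep$n, msc_sim_raw(prep))
      t12 <- tt[cbind(i1, i2)]
      t13 <- tt[cbind(i1, i3)]
      t23 <- tt[cbind(i2, i3)]
      slot <- ifelse(t12 < t13 & t12 < t23, 1L,
                     ifelse(t13 < t23, 2L, 3L))
      x[cbind(seq_len(ntr), slot)] <- x[cbind(seq_len(ntr), slot)] + 1
    }
  })
  out <- data.frame(a = taxa[trios[1L, ]], b = taxa[trios[2L, ]],
                    c = taxa[trios[3L, ]],
                    x1 = x[, 1L], x2 = x[, 2L], x3 = x[, 3L],
                    M = rowSums(x), stringsAsFactors = FALSE)
  attr(out, "taxa") <- taxa
  class(out) <- c("triple_counts", "data.frame")
  out
}

#' Gene-tree topology frequencies under the multispecies coalescent
#'
#' Simulates M gene trees and tallies canonical topology keys, without
#' materializing \code{"phylo"} objects. Useful for locating the modal
#' (most probable) gene-tree topology, e.g. inside the anomaly zone where
#' it differs from the species tree.
#'
#' @inheritParams simulate_triple_counts
#' @return a named integer vector of counts, sorted decreasing; names are
#'   canonical newick topology keys.
#' @export
simulate_topology_frequencies <- function(species_tree, M, seed = NULL) {
  prep <- msc_prep(species_tree)
  n <- prep$n
  tally <- new.env(parent = emptyenv())
  with_local_seed(seed, {
    for (g in seq_len(M)) {
      m <- msc_sim_raw(prep)
      ord <- order(m$t)
      lab <- prep$labels
      key <- character(n)
      key[seq_len(n)] <- lab
      cl <- as.list(seq_len(n))
      cur <- integer(n); cur[seq_len(n)] <- seq_len(n)
      labs <- as.list(lab)
      mins <- lab
      for (i in ord) {
        a <- cur[m$x[[i]][1L]]; b <- cur[m$y[[i]][1L]]
        if (mins[[a]] > mins[[b]]) { tmp <- a; a <- b; b <- tmp }
        newlab <- paste0("(", labs[[a]], ",", labs[[b]], ")")
        labs[[a]] <- newlab
        mins[[a]] <- min(mins[[a]], mins[[b]])
        cur[c(m$x[[i]], m$y[[i]])] <- a
      }
      k <- paste0(labs[[a]], ";")
      cnt <- tally[[k]]
      tally[[k]] <- if (is.null(cnt)) 1L else cnt + 1L
    }
  })
  keys <- ls(tally)
  cnts <- vapply(keys, function(k) tally[[k]], 1L)
  sort(cnts, decreasing = TRUE)
}

#' HGT model configuration
#'
#' Horizontal gene transfer is modeled at the rooted-triple level: for a
#' species-tree triple AB|C, transfers between A and C or between B and C
#' below the A-B divergence can overturn the triple. Transfer events occur
#' as a Poisson process at rate \code{lambda} per gene per generation over
#' the divergence time \code{L} generations, so the probability that at
#' least one topology-changing transfer hits a gene is
#' \eqn{1 - e^{-2\lambda L}}.
#'
#' @param lambda HGT rate per gene per generation, \code{>= 0}.
#' @param L species divergence time in generations, \code{> 0}.
#' @return a list of class \code{"hgt_config"}.
#' @export
hgt_config <- function(lambda, L) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  structure(list(lambda = lambda, L = L), class = "hgt_config")
}

#' Matching-triple probability under coalescent plus HGT
#'
#' @param B triple internal branch length, coalescent units.
#' @param config an [hgt_config()].
#' @return \eqn{e^{-2\lambda L} - (2/3) e^{-B}}; an error if the model
#'   leaves no matching probability (large \eqn{\lambda} or small B), a
#'   regime the triple-level model does not cover.
#' @export
hgt_match_probability <- function(B, config) {
  stopifnot(inherits(config, "hgt_config"))
  p <- exp(-2 * config$lambda * config$L) - (2 / 3) * exp(-B)
  if (p < 0)
    stop("HGT rate too large for branch length B: matching probability ",
         "would be negative", call. = FALSE)
  p
}

#' Simulate triple counts for one trio under coalescent plus HGT
#'
#' Draws M gene-tree triples where the probability of matching the
#' species-tree resolution is \eqn{e^{-2\lambda L} - (2/3) e^{-B}} and the
#' complementary mass is split equally between the two mismatching
#' resolutions (the two transfer routes, A-C and B-C, are symmetric).
#'
#' @param B triple internal branch length, coalescent units.
#' @param config an [hgt_config()]; \code{lambda = 0} recovers the pure
#'   coalescent triple law \eqn{1 - (2/3)e^{-B}}.
#' @param M number of gene trees.
#' @param seed optional integer seed.
#' @return an integer vector \code{c(x1, x2, x3)} with \code{x1} the count
#'   matching the species tree.
#' @export
simulate_triple_counts_hgt <- function(B, config, M, seed = NULL) {
  p <- hgt_match_probability(B, config)
  probs <- c(p, (1 - p) / 2, (1 - p) / 2)
  with_local_seed(seed, {
    x <- as.integer(stats::rmultinom(1L, M, probs))
  })
  names(x) <- c("x1", "x2", "x3")
  x
}

#' Random species tree from a birth-death process, with population sizes
#'
#' Draws an ultrametric species tree (mutation-unit branch lengths)
#' conditioned on \code{n_taxa} surviving tips, then assigns an i.i.d.
#' uniform population size \eqn{\theta} to every branch. Convert to
#' coalescent units with [species_tree_coalescent()].
#'
#' @param n_taxa number of tips, \code{>= 3}.
#' @param birth_rate,death_rate birth-death rates, \code{birth > death >= 0}.
#' @param theta_range range of the uniform \eqn{\theta} draw per branch.
#' @param seed optional integer seed.
#' @return a list with \code{tree} (ultrametric \code{"phylo"}, mutation
#'   units) and \code{theta} (one value per edge, in \code{tree$edge}
#'   order).
#' @export
random_species_tree <- function(n_taxa, birth_rate = 10, death_rate = 0.1,
                                theta_range = c(0.005, 0.01), seed = NULL) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3", call. = FALSE)
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0", call. = FALSE)
  with_local_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = birth_rate, death = death_rate)
    tr$tip.label <- paste0("s", seq_len(n_taxa))
    theta <- stats::runif(nrow(tr$edge), theta_range[1L], theta_range[2L])
    attr(tr, "units") <- "mutation"
    list(tree = tr, theta = theta)
  })
}

#' Convert a mutation-unit species tree to coalescent units
#'
#' Each branch length \eqn{\tau} is replaced by \eqn{2\tau/\theta} using
#' that branch's population size.
#'
#' @param st a list as returned by [random_species_tree()], or a
#'   \code{"phylo"} plus a scalar/per-edge \code{theta}.
#' @param theta per-edge (in \code{edge} order) or scalar population size;
#'   ignored when \code{st} already carries one.
#' @return a \code{"phylo"} with coalescent-unit branch lengths.
#' @export
species_tree_coalescent <- function(st, theta = NULL) {
  if (is.list(st) && !inherits(st, "phylo")) {
    theta <- st$theta
    st <- st$tree
  }
  if (is.null(theta)) stop("theta required", call. = FALSE)
  out <- st
  out$edge.length <- to_coalescent_units(st$edge.length, theta)
  attr(out, "units") <- "coalescent"
  out
}
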