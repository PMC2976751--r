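## Topology search over rooted binary trees: exhaustive enumeration for
## small N, steepest-ascent NNI hill climbing with restarts otherwise.
## Internally trees are handled as nested lists (leaf = label, internal
## node = list of two children), which makes leaf insertion and NNI
## rearrangement cheap; conversion to/from "phylo" happens at the edges.

struct_key <- function(s) {
  if (is.character(s)) return(s)
  kids <- vapply(s, struct_key, "")
  kids <- kids[order(vapply(s, struct_min, ""))]
  paste0("(", paste(kids, collapse = ","), ")")
}

struct_min <- function(s) {
  if (is.character(s)) return(s)
  min(vapply(s, struct_min, ""))
}

struct_to_phylo <- function(s) {
  ape::read.tree(text = paste0(struct_key(s), ";"))
}

phylo_to_struct <- function(tree) {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("need a rooted binary tree", call. = FALSE)
  ch <- node_children(tree)
  n <- ape::Ntip(tree)
  rec <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    lapply(ch[[v]], rec)
  }
  rec(n + 1L)
}

## every way to attach `leaf` to a subtree of s (including above the root)
attach_leaf <- function(s, leaf) {
  out <- list(list(s, leaf))
  if (!is.character(s)) {
    for (i in 1:2) {
      for (v in attach_leaf(s[[i]], leaf)) {
        s2 <- s
        s2[[i]] <- v
        out[[length(out) + 1L]] <- s2
      }
    }
  }
  out
}

#' Enumerate all rooted binary labeled topologies
#'
#' Generates each of the (2N-3)!! rooted binary topologies on the given
#' taxa exactly once, by sequential leaf insertion. Guarded to
#' \code{3 <= N <= 7} (10395 topologies at N = 7) because the count grows
#' as a double factorial.
#'
#' @param taxa character vector of distinct leaf labels.
#' @return a list of \code{"phylo"} objects.
#' @examples
#' length(enumerate_rooted_topologies(c("A", "B", "C", "D")))  # 15
#' @export
enumerate_rooted_topologies <- function(taxa) {
  taxa <- sort(unique(taxa))
  N <- length(taxa)
  if (N < 3L || N > 7L)
    stop("enumeration supported for 3 <= N <= 7 taxa", call. = FALSE)
  acc <- list(list(taxa[1L], taxa[2L]))
  for (i in 3:N) {
    acc <- unlist(lapply(acc, attach_leaf, leaf = taxa[i]), recursive = FALSE)
  }
  lapply(acc, struct_to_phylo)
}

## uniformly random rooted binary topology (sequential uniform attachment)
random_rooted_topology <- function(taxa) {
  taxa <- sort(unique(taxa))
  s <- list(taxa[1L], taxa[2L])
  for (i in seq_along(taxa)[-(1:2)]) {
    opts <- attach_leaf(s, taxa[i])
    s <- opts[[sample.int(length(opts), 1L)]]
  }
  struct_to_phylo(s)
}

nni_struct <- function(s) {
  out <- list()
  if (is.character(s)) return(out)
  c1 <- s[[1]]; c2 <- s[[2]]
  if (!is.character(c1)) {       # edge s -> c1; exchange a child with c2
    out[[length(out) + 1L]] <- list(list(c1[[1]], c2), c1[[2]])
    out[[length(out) + 1L]] <- list(list(c1[[2]], c2), c1[[1]])
  }
  if (!is.character(c2)) {
    out[[length(out) + 1L]] <- list(list(c2[[1]], c1), c2[[2]])
    out[[length(out) + 1L]] <- list(list(c2[[2]], c1), c2[[1]])
  }
  for (v in nni_struct(c1)) out[[length(out) + 1L]] <- list(v, c2)
  for (v in nni_struct(c2)) out[[length(out) + 1L]] <- list(c1, v)
  out
}

#' Nearest-neighbor-interchange neighborhood of a rooted topology
#'
#' For each internal edge, the two topologies obtained by exchanging one
#' child subtree of the edge's lower endpoint with the subtree's "uncle"
#' (the sibling of the lower endpoint). Every neighbor is at rooted RF
#' distance exactly 2 from the input; duplicates are removed.
#'
#' @param tree a rooted binary \code{"phylo"} with \code{N >= 4} leaves
#'   (the neighborhood is empty below that).
#' @return a list of \code{"phylo"} objects.
#' @export
nni_neighbors <- function(tree) {
  if (ape::Ntip(tree) < 4L) return(list())
  nb <- nni_struct(phylo_to_struct(tree))
  keys <- vapply(nb, struct_key, "")
  nb <- nb[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  nb <- nb[order(keys)]
  lapply(nb, struct_to_phylo)
}

new_search_result <- function(fit, n_evaluated, method, trajectories = NULL,
                              seed = NULL) {
  structure(list(fit = fit, logPL = fit$logPL, n_evaluated = n_evaluated,
                 method = method, trajectories = trajectories, seed = seed),
            class = "mpest_search")
}

#' @export
print.mpest_search <- function(x, ...) {
  cat("Species-tree search (", x$method, "), ", x$n_evaluated,
      " topologies scored\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' Exhaustive maximum pseudo-likelihood search
#'
#' Scores every rooted binary topology on the taxa of \code{counts} with
#' [optimize_branch_lengths()] and returns the best; deterministic (ties
#' broken by canonical newick order, which the enumeration respects).
#'
#' @param counts a \code{"triple_counts"} table; at most 7 taxa.
#' @param t_cap optimizer box bound (see [optimize_branch_lengths()]).
#' @return an object of class \code{"mpest_search"}.
#' @export
exhaustive_search <- function(counts, t_cap = 10) {
  taxa <- attr(counts, "taxa")
  tops <- enumerate_rooted_topologies(taxa)
  best <- NULL; best_key <- ""
  for (tp in tops) {
    fit <- optimize_branch_lengths(tp, counts, t_cap = t_cap)
    key <- topology_key(tp)
    if (is.null(best) || fit$logPL > best$logPL + 1e-9 ||
        (abs(fit$logPL - best$logPL) <= 1e-9 && key < best_key)) {
      best <- fit; best_key <- key
    }
  }
  new_search_result(best, length(tops), "exhaustive")
}

## data-driven start: greedily join the cluster pair with the highest
## average pooled cherry frequency s(A,B) = mean_c x(AB|c) / M
greedy_start_tree <- function(counts) {
  taxa <- attr(counts, "taxa")
  N <- length(taxa)
  S <- matrix(0, N, N); Cnt <- matrix(0, N, N)
  for (r in seq_len(nrow(counts))) {
    if (counts$M[r] <= 0) next
    ia <- match(counts$a[r], taxa); ib <- match(counts$b[r], taxa)
    ic <- match(counts$c[r], taxa)
    f <- c(counts$x1[r], counts$x2[r], counts$x3[r]) / counts$M[r]
    pr <- list(c(ia, ib), c(ia, ic), c(ib, ic))
    for (h in 1:3) {
      i <- pr[[h]][1L]; j <- pr[[h]][2L]
      S[i, j] <- S[i, j] + f[h]; S[j, i] <- S[i, j]
      Cnt[i, j] <- Cnt[i, j] + 1; Cnt[j, i] <- Cnt[i, j]
    }
  }
  S <- ifelse(Cnt > 0, S / pmax(Cnt, 1), 0)
  clusters <- as.list(taxa)
  structs <- as.list(taxa)
  idx <- lapply(seq_len(N), identity)
  while (length(structs) > 1L) {
    k <- length(structs)
    best <- c(-Inf, 1L, 2L)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      sc <- mean(S[idx[[i]], idx[[j]]])
      if (sc > best[1L] + 1e-12) best <- c(sc, i, j)
    }
    i <- best[2L]; j <- best[3L]
    merged <- list(structs[[i]], structs[[j]])
    mi <- c(idx[[i]], idx[[j]])
    keepm <- setdiff(seq_len(k), c(i, j))
    structs <- c(structs[keepm], list(merged))
    idx <- c(idx[keepm], list(mi))
  }
  struct_to_phylo(structs[[1L]])
}

#' NNI hill-climbing search for the maximum pseudo-likelihood tree
#'
#' Steepest-ascent hill climbing: from each start topology, repeatedly
#' move to the best-scoring NNI neighbor while the optimized log
#' pseudo-likelihood strictly improves (by more than 1e-9); ties between
#' equal-scoring neighbors are broken by canonical newick order. The first
#' restart starts from a data-driven greedy triple-agreement tree, the
#' rest from uniformly random rooted topologies; the best local optimum
#' across restarts is returned. Fully reproducible from \code{seed}.
#'
#' @param counts a \code{"triple_counts"} table.
#' @param restarts number of hill-climbing starts (>= 1).
#' @param seed integer seed for the random restarts.
#' @param t_cap optimizer box bound.
#' @return an object of class \code{"mpest_search"} whose
#'   \code{trajectories} element records each restart's (topology, score)
#'   path.
#' @export
hill_climb <- function(counts, restarts = 10L, seed = 1L, t_cap = 10) {
  stopifnot(restarts >= 1L)
  taxa <- attr(counts, "taxa")
  cache <- new.env(parent = emptyenv())
  nev <- 0L
  score <- function(tp) {
    key <- topology_key(tp)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- optimize_branch_lengths(tp, counts, t_cap = t_cap)
    nev <<- nev + 1L
    cache[[key]] <- fit
    fit
  }
  best <- NULL; best_key <- ""
  trajectories <- vector("list", restarts)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (r in seq_len(restarts)) {
    cur <- if (r == 1L) greedy_start_tree(counts)
           else random_rooted_topology(taxa)
    cur_fit <- score(cur)
    traj <- list(list(topology = topology_key(cur), logPL = cur_fit$logPL))
    repeat {
      nb <- nni_neighbors(cur)
      if (!length(nb)) break
      fits <- lapply(nb, score)
      sc <- vapply(fits, `[[`, 0, "logPL")
      keys <- vapply(nb, topology_key, "")
      ord <- order(-sc, keys)
      if (sc[ord[1L]] > cur_fit$logPL + 1e-9) {
        cur <- nb[[ord[1L]]]
        cur_fit <- fits[[ord[1L]]]
        traj[[length(traj) + 1L]] <-
          list(topology = keys[ord[1L]], logPL = cur_fit$logPL)
      } else break
    }
    trajectories[[r]] <- traj
    ck <- topology_key(cur)
    if (is.null(best) || cur_fit$logPL > best$logPL + 1e-9 ||
        (abs(cur_fit$logPL - best$logPL) <= 1e-9 && ck < best_key)) {
      best <- cur_fit; best_key <- ck
    }
  }
  new_search_result(best, nev, "nni-hill-climb", trajectories, seed)
}
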