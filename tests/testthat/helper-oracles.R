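## Independent oracles used across the suite. These deliberately avoid the
## package's own decomposition/evaluation code paths.

## Log pseudo-likelihood computed term by term: the triple branch length
## B comes from ape::keep.tip (which sums collapsed edges on the induced
## 3-taxon subtree) and the matching slot from the induced cherry.
oracle_logPL <- function(species_tree, counts) {
  total <- 0
  for (r in seq_len(nrow(counts))) {
    trio <- c(counts$a[r], counts$b[r], counts$c[r])
    ind <- ape::keep.tip(species_tree, trio)
    inode <- setdiff(ind$edge[, 2], seq_len(3))
    B <- ind$edge.length[match(inode, ind$edge[, 2])]
    res <- resolve_triple(ind, trio)
    slot <- match(res, vapply(1:3, function(h) {
      pair <- switch(h, trio[c(1, 2)], trio[c(1, 3)], trio[c(2, 3)])
      paste0(paste(sort(pair), collapse = ","), "|", setdiff(trio, pair))
    }, ""))
    x <- unname(unlist(counts[r, c("x1", "x2", "x3")]))
    xm <- x[slot]
    total <- total +
      (if (xm > 0) xm * log(1 - (2 / 3) * exp(-B)) else 0) +
      (sum(x) - xm) * (log(1 / 3) - B)
  }
  total
}

## brute-force clade frequency tally over a list of trees
oracle_clade_freq <- function(trees) {
  keys <- unlist(lapply(trees, function(t)
    vapply(tree_clades(t), paste, "", collapse = "\t")))
  table(keys) / length(trees)
}

## random rooted binary tree with branch lengths, for round-trip and
## metric property checks
random_tree <- function(n, lengths = TRUE) {
  t <- ape::rtree(n, rooted = TRUE)
  t$tip.label <- paste0("t", seq_len(n))
  if (!lengths) t$edge.length <- NULL
  t
}

## direct per-gene evaluation of the per-population coalescent density for
## the three demonstration gene trees on species tree ((A:X,B:X):W,C:Y):
## each gene's factors are written out explicitly, then multiplied.
oracle_ry_loglik <- function(X, W, theta1, theta2) {
  Y <- X + W
  g1 <- log(2 / theta2) - 2 * (0.01 - X) / theta2 +
    log(2 / theta1) - 2 * (0.02 - Y) / theta1
  g2 <- -2 * W / theta2 +
    log(2 / theta1) - 6 * (0.015 - Y) / theta1 +
    log(2 / theta1) - 2 * (0.025 - 0.015) / theta1
  g3 <- -2 * W / theta2 +
    log(2 / theta1) - 6 * (0.02 - Y) / theta1 +
    log(2 / theta1) - 2 * (0.03 - 0.02) / theta1
  g1 + g2 + g3
}
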