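worked_example_counts <- function() {
  as_triple_counts(data.frame(
    a = c("A", "A", "A", "B"), b = c("B", "B", "C", "C"),
    c = c("C", "D", "D", "D"),
    x1 = c(2, 2, 2, 1), x2 = c(1, 1, 0, 1), x3 = c(0, 0, 1, 1)))
}
worked_example_topology <- function() read_newick("((A,B),(C,D));")

test_that("triple decomposition follows the cherry-to-trio path", {
  ## balanced 4-taxon tree: T1 above {A,B}, T2 above {C,D}
  d <- decompose_triples(worked_example_topology())
  expect_equal(nrow(d$trios), 4L)
  sets <- mpest:::node_leafsets(worked_example_topology())
  lab <- vapply(sets[d$edge_nodes], paste, "", collapse = ",")
  iT1 <- which(lab == "A,B"); iT2 <- which(lab == "C,D")
  get_edges <- function(a, b, c) d$A[d$trios$a == a & d$trios$b == b &
                                       d$trios$c == c, ]
  expect_equal(which(get_edges("A", "B", "C") == 1), iT1)
  expect_equal(which(get_edges("A", "B", "D") == 1), iT1)
  expect_equal(which(get_edges("A", "C", "D") == 1), iT2)
  expect_equal(which(get_edges("B", "C", "D") == 1), iT2)

  ## 3-taxon: single trio, single edge
  d3 <- decompose_triples(read_newick("((A,B),C);"))
  expect_equal(dim(d3$A), c(1L, 1L))
  expect_equal(d3$A[1, 1], 1L)

  expect_error(decompose_triples(read_newick("(a,b,c,d);")),
               "rooted and binary")
})

test_that("caterpillar decomposition sums all edges on the path", {
  cat5 <- read_newick("((((A,B),C),D),E);")
  d <- decompose_triples(cat5)
  r <- which(d$trios$a == "A" & d$trios$b == "B" & d$trios$c == "E")
  expect_equal(sum(d$A[r, ]), 3L)            # B(AB|E) = T1 + T2 + T3
  ## oracle: every trio's B equals the induced-subtree internal edge length
  T <- c(0.3, 0.5, 0.7)
  names(T) <- NULL
  sp <- cat5
  lens <- rep(0, nrow(sp$edge))
  lens[match(d$edge_nodes, sp$edge[, 2])] <- T
  sp$edge.length <- lens
  B <- as.numeric(d$A %*% T)
  for (r in seq_len(nrow(d$trios))) {
    trio <- unlist(d$trios[r, c("a", "b", "c")], use.names = FALSE)
    ind <- ape::keep.tip(sp, trio)
    inode <- setdiff(ind$edge[, 2], 1:3)
    expect_equal(B[r], ind$edge.length[match(inode, ind$edge[, 2])],
                 tolerance = 1e-12)
  }
  ## every internal edge appears in at least one trio
  expect_true(all(colSums(d$A) >= 1))
})

test_that("log pseudo-likelihood matches the worked example and star limit", {
  cnt <- worked_example_counts()
  top <- worked_example_topology()
  expect_equal(log_pseudo_likelihood(top, cnt, T = c(log(2), 0)),
               -11.797, tolerance = 5e-4)
  ## all T = 0: every factor is 1/3 per gene per trio
  expect_equal(log_pseudo_likelihood(top, cnt, T = c(0, 0)),
               sum(cnt$M) * log(1 / 3), tolerance = 1e-12)
  expect_error(log_pseudo_likelihood(top, cnt, T = c(-0.1, 0)), "negative")
})

test_that("log pseudo-likelihood equals a naive per-factor oracle", {
  set.seed(21)
  for (rep in 1:5) {
    topo <- mpest:::random_rooted_topology(paste0("s", 1:5))
    d <- decompose_triples(topo)
    T <- runif(3, 0, 2)
    gts <- replicate(30, mpest:::random_rooted_topology(paste0("s", 1:5)),
                     simplify = FALSE)
    cnt <- count_triples(gts)
    sp <- topo
    lens <- rep(0, nrow(sp$edge))
    lens[match(d$edge_nodes, sp$edge[, 2])] <- T
    sp$edge.length <- lens
    expect_equal(log_pseudo_likelihood(topo, cnt, T = T),
                 oracle_logPL(sp, cnt), tolerance = 1e-10)
  }
})

test_that("closed-form triple branch estimate behaves per theory", {
  expect_equal(triple_mle(4, 6), log(2), tolerance = 1e-12)
  expect_equal(triple_mle(2, 6), 0)
  expect_equal(triple_mle(1, 6), 0)          # clamped below the star point
  expect_identical(triple_mle(6, 6), SENTINEL_LENGTH)
  expect_error(triple_mle(7, 6), "x must")
  expect_error(triple_mle(1, 0), "M must")
  ## strictly increasing on (M/3, M)
  xs <- seq(2.01, 5.99, length.out = 50)
  bs <- vapply(xs, triple_mle, 0, M = 6)
  expect_true(all(diff(bs) > 0))
})

test_that("branch-length optimization reproduces the worked example", {
  fit <- optimize_branch_lengths(worked_example_topology(),
                                 worked_example_counts())
  expect_equal(fit$T[order(fit$edge_clades)], c(0.693, 0),
               tolerance = 5e-4)
  expect_equal(fit$logPL, -11.797, tolerance = 5e-4)
  expect_false(any(fit$sentinel))
})

test_that("single-edge problems match the closed form exactly", {
  cnt <- as_triple_counts(data.frame(a = "a", b = "b", c = "c",
                                     x1 = 37, x2 = 10, x3 = 3))
  fit <- optimize_branch_lengths(read_newick("((a,b),c);"), cnt)
  expect_equal(fit$T, triple_mle(37, 50), tolerance = 1e-6)
  expect_equal(fit$logPL, log_pseudo_likelihood(read_newick("((a,b),c);"),
                                                cnt, T = fit$T))
})

test_that("disjoint-edge problems match pooled closed-form estimates", {
  ## balanced 4-taxon topology: T1 and T2 share no trio
  cnt <- as_triple_counts(data.frame(
    a = c("A", "A", "A", "B"), b = c("B", "B", "C", "C"),
    c = c("C", "D", "D", "D"),
    x1 = c(30, 28, 10, 12), x2 = c(10, 8, 22, 20), x3 = c(10, 14, 18, 18)))
  fit <- optimize_branch_lengths(worked_example_topology(), cnt)
  o <- order(fit$edge_clades)                # {A,B} then {C,D}
  expect_equal(fit$T[o][1], triple_mle(30 + 28, 100), tolerance = 1e-5)
  ## T2 pools the cd|a and cd|b slots (x3 of the sorted trios)
  expect_equal(fit$T[o][2], triple_mle(18 + 18, 100), tolerance = 1e-5)
})

test_that("fully matching counts yield sentinel branches", {
  gts <- rep(list(read_newick("(((a,b),c),d);")), 5)
  fit <- optimize_branch_lengths(read_newick("(((a,b),c),d);"),
                                 count_triples(gts))
  expect_true(all(fit$sentinel))
  expect_true(all(fit$T == SENTINEL_LENGTH))
  lens <- fit$tree$edge.length
  expect_true(all(lens[match(internal <- setdiff(fit$tree$edge[, 2], 1:4),
                             fit$tree$edge[, 2])] == SENTINEL_LENGTH))
})

test_that("estimation refuses tables with uncovered trios", {
  gts <- list(read_newick("((a,b),c);"), read_newick("((a,b),d);"))
  cnt <- count_triples(gts, taxa = c("a", "b", "c", "d"))
  expect_error(optimize_branch_lengths(read_newick("((a,b),(c,d));"), cnt),
               "no gene tree covers")
})

test_that("the log pseudo-likelihood is concave along random segments", {
  set.seed(33)
  topo <- mpest:::random_rooted_topology(paste0("s", 1:5))
  gts <- replicate(40, mpest:::random_rooted_topology(paste0("s", 1:5)),
                   simplify = FALSE)
  cnt <- count_triples(gts)
  for (rep in 1:10) {
    T0 <- runif(3, 0, 3); T1 <- runif(3, 0, 3)
    f <- vapply(seq(0, 1, length.out = 9), function(s)
      log_pseudo_likelihood(topo, cnt, T = (1 - s) * T0 + s * T1), 0)
    expect_true(all(diff(f, differences = 2) <= 1e-6))
  }
})
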