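test_that("rooted topology enumeration matches the double factorial", {
  expect_length(enumerate_rooted_topologies(c("a", "b", "c")), 3L)
  expect_length(enumerate_rooted_topologies(LETTERS[1:4]), 15L)
  t5 <- enumerate_rooted_topologies(LETTERS[1:5])
  expect_length(t5, 105L)
  keys <- vapply(t5, topology_key, "")
  expect_false(anyDuplicated(keys) > 0)      # each topology exactly once
  expect_error(enumerate_rooted_topologies(letters[1:8]), "3 <= N <= 7")
})

test_that("NNI neighbors are at rooted RF distance 2 and include inverses", {
  set.seed(13)
  for (rep in 1:4) {
    t <- mpest:::random_rooted_topology(paste0("s", 1:5))
    nb <- nni_neighbors(t)
    expect_length(nb, 2L * (5L - 2L))
    for (v in nb) expect_identical(rf_distance(t, v), 2L)
    ## involution: the original is a neighbor of each neighbor
    for (v in nb)
      expect_true(topology_key(t) %in%
                    vapply(nni_neighbors(v), topology_key, ""))
  }
  expect_length(nni_neighbors(read_newick("((a,b),c);")), 0L)
})

test_that("4-taxon NNI neighborhood equals brute-force RF-2 one-exchange set", {
  t <- read_newick("((A,B),(C,D));")
  nb_keys <- sort(vapply(nni_neighbors(t), topology_key, ""))
  all15 <- enumerate_rooted_topologies(LETTERS[1:4])
  rf2 <- Filter(function(v) rf_distance(t, v) == 2L, all15)
  ## a single exchange moves exactly one clade, so the reachable set is the
  ## RF-2 topologies sharing one of the two original internal clades
  share <- Filter(function(v) {
    length(intersect(mpest:::clade_keys(v), mpest:::clade_keys(t))) == 1L
  }, rf2)
  expect_identical(nb_keys, sort(vapply(share, topology_key, "")))
})

test_that("exhaustive search picks the most frequent triple at N = 3", {
  cnt <- as_triple_counts(data.frame(a = "a", b = "b", c = "c",
                                     x1 = 2, x2 = 1, x3 = 0))
  res <- exhaustive_search(cnt)
  expect_identical(topology_key(res$fit$tree), "((a,b),c);")
  expect_equal(res$fit$T, -log(1 / 2), tolerance = 1e-6)
  expect_equal(res$n_evaluated, 3L)
})

test_that("all-star counts tie and resolve to the canonical smallest", {
  cnt <- as_triple_counts(data.frame(
    a = c("a", "a", "a", "b"), b = c("b", "b", "c", "c"),
    c = c("c", "d", "d", "d"),
    x1 = rep(2, 4), x2 = rep(2, 4), x3 = rep(2, 4)))
  res <- exhaustive_search(cnt)
  keys <- sort(vapply(enumerate_rooted_topologies(letters[1:4]),
                      topology_key, ""))
  expect_identical(topology_key(res$fit$tree), keys[1])
  expect_true(all(res$fit$T == 0))
})

test_that("exhaustive search recovers the generating species tree", {
  sp <- read_newick("((((s1:1,s2:1):0.5,s3:1.5):0.5,s4:2):0.5,s5:2.5);",
                    units = "coalescent")
  cnt <- simulate_triple_counts(sp, 1000, seed = 77)
  res <- exhaustive_search(cnt)
  expect_identical(topology_key(res$fit$tree), topology_key(sp))
})

test_that("hill climbing attains the exhaustive optimum on small instances", {
  sp <- read_newick("((((s1:1,s2:1):0.3,s3:1.3):0.3,s4:1.6):0.3,s5:1.9);",
                    units = "coalescent")
  hits <- 0L
  n_inst <- 10L
  for (i in seq_len(n_inst)) {
    cnt <- simulate_triple_counts(sp, 500, seed = 1000 + i)
    ex <- exhaustive_search(cnt)
    hc <- hill_climb(cnt, restarts = 10L, seed = 2000 + i)
    expect_lte(hc$logPL, ex$logPL + 1e-9)    # exhaustive is an upper bound
    if (abs(hc$logPL - ex$logPL) <= 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, n_inst - 1L)
})

test_that("hill climbing is reproducible from its seed", {
  sp <- read_newick("(((s1:1,s2:1):0.5,s3:1.5):0.5,s4:2);",
                    units = "coalescent")
  cnt <- simulate_triple_counts(sp, 200, seed = 5)
  a <- hill_climb(cnt, restarts = 4L, seed = 99)
  b <- hill_climb(cnt, restarts = 4L, seed = 99)
  expect_identical(topology_key(a$fit$tree), topology_key(b$fit$tree))
  expect_equal(a$logPL, b$logPL)
  expect_identical(lapply(a$trajectories, function(tr)
    vapply(tr, `[[`, "", "topology")),
    lapply(b$trajectories, function(tr) vapply(tr, `[[`, "", "topology")))
})

test_that("a single repeated gene tree is returned with sentinel branches", {
  gts <- rep(list(read_newick("((((a,b),c),d),e);")), 3)
  cnt <- count_triples(gts)
  hc <- hill_climb(cnt, restarts = 3L, seed = 1)
  expect_identical(topology_key(hc$fit$tree), "((((a,b),c),d),e);")
  expect_true(all(hc$fit$sentinel))
})

test_that("search is invariant to taxon relabeling", {
  sp <- read_newick("(((s1:1,s2:1):0.6,s3:1.6):0.6,s4:2.2);",
                    units = "coalescent")
  cnt <- simulate_triple_counts(sp, 400, seed = 8)
  res1 <- exhaustive_search(cnt)
  ## swap label names s1 <-> s4 throughout the table
  map <- c(s1 = "s4", s2 = "s2", s3 = "s3", s4 = "s1")
  df <- data.frame(a = map[cnt$a], b = map[cnt$b], c = map[cnt$c],
                   x1 = cnt$x1, x2 = cnt$x2, x3 = cnt$x3)
  res2 <- exhaustive_search(as_triple_counts(df))
  relabeled <- res1$fit$tree
  relabeled$tip.label <- unname(map[relabeled$tip.label])
  expect_identical(topology_key(res2$fit$tree), topology_key(relabeled))
  expect_equal(res2$logPL, res1$logPL, tolerance = 1e-9)
})
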