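test_that("newick parsing recovers clades and edge lengths", {
  tr <- read_newick("((A,B),C);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  cl <- tree_clades(tr)
  expect_length(cl, 1L)
  expect_equal(cl[[1]], c("A", "B"))

  an <- read_newick("((((A:0.5,B:0.5):0.025,C:0.525):0.025,D:0.55):1,E:1.55);")
  expect_equal(ape::Ntip(an), 5L)
  internal <- setdiff(an$edge[, 2], seq_len(5))
  lens <- an$edge.length[match(internal, an$edge[, 2])]
  expect_setequal(round(lens, 6), c(0.025, 0.025, 1))
})

test_that("malformed newick is rejected with a located error", {
  expect_error(read_newick("((A,B,C);"), "unbalanced")
  expect_error(read_newick("(A,B)),C;"), "position")
  expect_error(read_newick("((A,B),A);"), "duplicate")
  expect_error(read_newick("((A,),B);"), "empty label")
  expect_error(read_newick("(('A',B),C);"), "quoted label|unsupported")
  expect_error(read_newick("((A[x],B),C);"), "unsupported")
})

test_that("write/parse round-trip preserves clade set and length multiset", {
  set.seed(11)
  for (i in 1:10) {
    t1 <- random_tree(sample(4:12, 1))
    t2 <- read_newick(write_newick(t1))
    expect_setequal(vapply(tree_clades(t1), paste, "", collapse = "/"),
                    vapply(tree_clades(t2), paste, "", collapse = "/"))
    expect_equal(sort(t1$edge.length), sort(t2$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("canonical writer is invariant to child order", {
  a <- read_newick("((A,B),C);")
  b <- read_newick("(C,(B,A));")
  expect_identical(write_newick(a), write_newick(b))
  expect_identical(topology_key(a), topology_key(b))
})

test_that("outgroup rooting places the outgroup at the root", {
  t1 <- read_newick("((A,B),C);")
  expect_identical(topology_key(root_by_outgroup(t1, "C")), topology_key(t1))

  ## all three rootings of the single unrooted 3-leaf tree
  t2 <- read_newick("((A,C),B);")
  expect_identical(topology_key(root_by_outgroup(t2, "A")),
                   topology_key(read_newick("(A,(B,C));")))
  expect_identical(topology_key(root_by_outgroup(t2, "C")),
                   topology_key(read_newick("((A,B),C);")))

  expect_error(root_by_outgroup(t1, "opossum"), "not a leaf")
  dup <- t1
  dup$tip.label <- c("A", "A", "C")
  expect_error(root_by_outgroup(dup, "A"), "single outgroup")
})

test_that("rooting a larger tree preserves the induced unrooted topology", {
  t <- read_newick("(((A,B),(C,D)),E);")
  r <- root_by_outgroup(t, "C")
  expect_true("C" %in% t$tip.label)
  ch <- mpest:::node_children(r)[[ape::Ntip(r) + 1L]]
  kid_sets <- lapply(mpest:::node_leafsets(r)[ch], sort)
  expect_true(list("C") %in% kid_sets || any(vapply(kid_sets, function(s)
    identical(s, "C"), TRUE)))
  ## unrooted bipartitions unchanged
  expect_equal(phangorn::RF.dist(ape::unroot(t), ape::unroot(r)), 0)
})

test_that("rooted RF distance is the clade symmetric difference", {
  a <- read_newick("((((A,B),C),D),E);")
  b <- read_newick("(((A,B),(C,D)),E);")
  expect_identical(rf_distance(a, a), 0L)
  expect_identical(rf_distance(a, b), 2L)
  expect_identical(rf_distance(b, a), 2L)
  expect_error(rf_distance(a, read_newick("((A,B),C);")), "leaf sets")
})

test_that("rooted RF agrees with an independent implementation and is a metric", {
  set.seed(42)
  for (i in 1:8) {
    x <- random_tree(10, lengths = FALSE)
    y <- random_tree(10, lengths = FALSE)
    expect_equal(rf_distance(x, y),
                 as.integer(phangorn::RF.dist(x, y, rooted = TRUE)))
  }
  for (i in 1:6) {
    x <- random_tree(8, lengths = FALSE)
    y <- random_tree(8, lengths = FALSE)
    z <- random_tree(8, lengths = FALSE)
    expect_gte(rf_distance(x, y) + rf_distance(y, z), rf_distance(x, z))
    expect_identical(rf_distance(x, y), rf_distance(y, x))
  }
})

test_that("majority consensus reports exact clade frequencies as supports", {
  ten <- rep(list(read_newick("(((A,B),C),D);")), 10)
  cons <- majority_consensus(ten)
  expect_identical(topology_key(cons), topology_key(ten[[1]]))
  expect_true(all(as.numeric(cons$node.label[-1]) == 1))

  mix <- c(rep(list(read_newick("((A,B),C);")), 2),
           list(read_newick("((A,C),B);")))
  cons2 <- majority_consensus(mix, threshold = 0.5)
  expect_identical(topology_key(cons2), topology_key(read_newick("((A,B),C);")))
  sup <- as.numeric(cons2$node.label[cons2$node.label != ""])
  expect_equal(sup, 2 / 3, tolerance = 1e-6)

  ## supports match a brute-force tally on random inputs
  set.seed(7)
  trees <- replicate(9, random_tree(6, lengths = FALSE), simplify = FALSE)
  cons3 <- majority_consensus(trees, extended = TRUE)
  freq <- oracle_clade_freq(trees)
  for (i in seq_along(tree_clades(cons3))) {
    k <- paste(tree_clades(cons3)[[i]], collapse = "\t")
    lab <- cons3$node.label[cons3$node.label != ""][i]
    expect_equal(as.numeric(lab), as.numeric(freq[k]), tolerance = 1e-6)
  }
})

test_that("consensus tie-break is deterministic and plain majority drops ties", {
  tie <- list(read_newick("((A,B),C);"), read_newick("((A,C),B);"))
  plain <- majority_consensus(tie, threshold = 0.5, extended = FALSE)
  expect_length(tree_clades(plain), 0L)      # star: neither clade included
  ext <- majority_consensus(tie, threshold = 0.5, extended = TRUE)
  expect_identical(topology_key(ext), topology_key(read_newick("((A,B),C);")))
  expect_identical(topology_key(majority_consensus(rev(tie))),
                   topology_key(ext))        # order-invariant
  expect_error(majority_consensus(list()), "no input")
})
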