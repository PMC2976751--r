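#' @import ape
#' @importFrom stats optim rexp runif setNames
#' @importFrom utils combn write.table
NULL

## Rooted trees are ape "phylo" objects throughout. A "unit" attribute
## ("none", "coalescent", "mutation", "generations") tags what the edge
## lengths mean; it is informational and preserved by the writers.

#' Parse a single newick string into a rooted tree
#'
#' Strict newick reader for rooted (possibly multifurcating) trees. Unlike
#' permissive readers, malformed input is rejected loudly: unbalanced
#' parentheses, empty or duplicated leaf labels, quoted labels, and
#' bracketed comments are all errors that name the offending position.
#' Internal-node labels after \code{)} are parsed and preserved (they carry
#' consensus supports on output).
#'
#' @param text a single newick statement terminated by \code{;}.
#' @param units optional unit tag for the edge lengths, one of
#'   \code{"none"}, \code{"coalescent"}, \code{"mutation"},
#'   \code{"generations"}.
#' @return an object of class \code{"phylo"}.
#' @examples
#' tr <- read_newick("((A,B),C);")
#' tr$tip.label
#' @export
read_newick <- function(text, units = "none") {
  stopifnot(is.character(text), length(text) == 1L)
  units <- match.arg(units, c("none", "coalescent", "mutation", "generations"))
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(chars %in% c("'", "\"", "[", "]"))
  if (length(bad))
    stop("unsupported newick syntax (quoted label or comment) at position ",
         bad[1], call. = FALSE)
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parenthesis at position ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " '(' left open", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("newick statement must end with ';'", call. = FALSE)
  if (grepl("\\(\\s*[,)]|,\\s*[,)]", text))
    stop("empty label at position ",
         regexpr("\\(\\s*[,)]|,\\s*[,)]", text) + 1L, call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse newick string", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label", call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative edge length in input", call. = FALSE)
  attr(tr, "units") <- units
  tr
}

#' Read a file of newick gene trees
#'
#' @param path path to a file with one newick statement per line.
#' @param units unit tag applied to every tree (see [read_newick()]).
#' @return a list of \code{"phylo"} objects (class \code{"multiPhylo"}).
#' @export
read_gene_trees <- function(path, units = "none") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees in ", path, call. = FALSE)
  out <- lapply(lines, read_newick, units = units)
  class(out) <- "multiPhylo"
  out
}

## children list indexed by node id
node_children <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

## per-node sorted leaf-label vectors, postorder fill
node_leafsets <- function(tree) {
  n <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; c <- po$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  lapply(sets, sort)
}

#' Non-trivial rooted clades of a tree
#'
#' The clade of an internal node is the set of leaf labels below it. The
#' non-trivial clades (everything except singletons and the full leaf set)
#' determine a rooted topology uniquely.
#'
#' @param tree a \code{"phylo"} object.
#' @return a list of sorted character vectors, one per non-root internal
#'   node whose clade is a proper subset of the leaf set.
#' @export
tree_clades <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- node_leafsets(tree)
  ids <- setdiff(seq_len(n + tree$Nnode), seq_len(n))
  out <- sets[ids]
  out[vapply(out, length, 1L) < n]
}

clade_keys <- function(tree) {
  vapply(tree_clades(tree), paste, "", collapse = "\t")
}

#' Robinson-Foulds distance between rooted trees (clade convention)
#'
#' Counts the symmetric difference of the two trees' non-trivial clade
#' sets. This is the rooted-tree convention: clades (subsets below internal
#' nodes), not unrooted bipartitions, are compared, so the value can differ
#' from the unrooted RF distance on the same pair.
#'
#' @param t1,t2 \code{"phylo"} objects over the same leaf set.
#' @return a non-negative integer; 0 iff the rooted topologies are equal.
#' @examples
#' a <- read_newick("((((A,B),C),D),E);")
#' b <- read_newick("(((A,B),(C,D)),E);")
#' rf_distance(a, b)  # 2
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  k1 <- clade_keys(t1); k2 <- clade_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

## smallest descendant label per node, for canonical child ordering
min_desc_label <- function(tree) {
  sets <- node_leafsets(tree)
  vapply(sets, function(s) s[1L], "")
}

write_clade <- function(node, tree, ch, mins, lens, digits, with_lengths,
                        node_label) {
  n <- ape::Ntip(tree)
  if (node <= n) {
    s <- tree$tip.label[node]
  } else {
    kids <- ch[[node]]
    kids <- kids[order(mins[kids])]
    parts <- vapply(kids, write_clade, "", tree = tree, ch = ch, mins = mins,
                    lens = lens, digits = digits, with_lengths = with_lengths,
                    node_label = node_label)
    lab <- node_label(node)
    s <- paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  if (with_lengths && !is.na(lens[node]))
    s <- paste0(s, ":", format(lens[node], digits = digits, trim = TRUE,
                               scientific = FALSE))
  s
}

#' Write a rooted tree as a canonical newick string
#'
#' Children are ordered by their smallest descendant label, so the output
#' is a deterministic function of the topology (child order in the input is
#' never semantically meaningful). Internal-node labels, when present, are
#' written after the closing parenthesis.
#'
#' @param tree a \code{"phylo"} object.
#' @param digits significant digits for edge lengths.
#' @param with_lengths write edge lengths when the tree has them.
#' @return a newick string terminated by \code{;}.
#' @export
write_newick <- function(tree, digits = 10, with_lengths = TRUE) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  ch <- node_children(tree)
  mins <- min_desc_label(tree)
  lens <- rep(NA_real_, nn)
  if (!is.null(tree$edge.length))
    lens[tree$edge[, 2L]] <- tree$edge.length
  with_lengths <- with_lengths && !is.null(tree$edge.length)
  root <- n + 1L
  nl <- function(node) {
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[node - n]
    if (is.na(lab)) "" else lab
  }
  paste0(write_clade(root, tree, ch, mins, lens, digits, with_lengths, nl), ";")
}

#' Canonical topology key of a rooted tree
#'
#' The canonical newick string without branch lengths or node labels; two
#' rooted trees have the same key iff they have the same topology.
#'
#' @param tree a \code{"phylo"} object.
#' @return a character scalar.
#' @export
topology_key <- function(tree) {
  t2 <- tree
  t2$edge.length <- NULL
  t2$node.label <- NULL
  write_newick(t2, with_lengths = FALSE)
}

#' Root a tree by a single outgroup
#'
#' Re-roots \code{tree} so that \code{outgroup} is attached directly to the
#' root as one of its two children; the ingroup clade structure induced by
#' the unrooted version of the input is preserved. Exactly one leaf may
#' carry the outgroup label: multiple species cannot simultaneously be
#' designated as outgroups.
#'
#' @param tree a \code{"phylo"} object.
#' @param outgroup a leaf label present exactly once in \code{tree}.
#' @return a rooted \code{"phylo"} object.
#' @export
root_by_outgroup <- function(tree, outgroup) {
  stopifnot(is.character(outgroup), length(outgroup) == 1L)
  hits <- sum(tree$tip.label == outgroup)
  if (hits == 0L)
    stop("outgroup '", outgroup, "' is not a leaf of the tree", call. = FALSE)
  if (hits > 1L)
    stop("outgroup label '", outgroup, "' appears ", hits,
         " times; a single outgroup leaf is required", call. = FALSE)
  units <- attr(tree, "units")
  ur <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L)
    ape::unroot(tree) else tree
  out <- ape::root(ur, outgroup = outgroup, resolve.root = TRUE)
  out <- ape::collapse.singles(out)
  attr(out, "units") <- units
  out
}

clades_compatible <- function(a, b) {
  ov <- length(intersect(a, b))
  ov == 0L || ov == length(a) || ov == length(b)
}

#' Majority-rule (extended) consensus of rooted trees
#'
#' Tallies clade frequencies across the input trees. Clades with frequency
#' strictly greater than \code{threshold} enter the consensus with their
#' frequency as support. With \code{extended = TRUE} (majority-rule
#' extension), remaining clades are then considered greedily in order of
#' decreasing frequency and added whenever compatible with the clades
#' already accepted; equal-frequency candidates are ordered by their sorted
#' leaf-label tuple, which makes the construction deterministic.
#'
#' @param trees a list of rooted \code{"phylo"} objects on a common leaf set.
#' @param threshold inclusion threshold, in \code{[0.5, 1]}.
#' @param extended use the greedy majority-rule extension.
#' @return a \code{"phylo"} object whose \code{node.label} holds clade
#'   support proportions (the root is unlabeled).
#' @export
majority_consensus <- function(trees, threshold = 0.5, extended = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no input trees", call. = FALSE)
  if (threshold < 0.5 || threshold > 1)
    stop("threshold must be in [0.5, 1]", call. = FALSE)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, taxa))
      stop("trees have differing leaf sets", call. = FALSE)
  B <- length(trees)
  tallies <- new.env(parent = emptyenv())
  for (t in trees) {
    for (k in clade_keys(t)) {
      cur <- tallies[[k]]
      tallies[[k]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  keys <- ls(tallies)
  if (!length(keys)) {                      # every input is a star tree
    star <- ape::read.tree(text = paste0("(", paste(taxa, collapse = ","), ");"))
    return(star)
  }
  freq <- vapply(keys, function(k) tallies[[k]], 1L) / B
  ord <- order(-freq, keys)                 # freq desc, label tuple asc
  keys <- keys[ord]; freq <- freq[ord]
  sets <- strsplit(keys, "\t", fixed = TRUE)
  keep <- logical(length(keys))
  accepted <- list()
  for (i in seq_along(keys)) {
    if (freq[i] > threshold) {
      keep[i] <- TRUE
      accepted[[length(accepted) + 1L]] <- sets[[i]]
    } else if (extended) {
      ok <- all(vapply(accepted, clades_compatible, TRUE, b = sets[[i]]))
      if (ok) {
        keep[i] <- TRUE
        accepted[[length(accepted) + 1L]] <- sets[[i]]
      }
    }
  }
  build_tree_from_clades(taxa, sets[keep], freq[keep])
}

## assemble a phylo from mutually compatible clades (root clade implicit)
build_tree_from_clades <- function(taxa, clades, supports) {
  stopifnot(length(clades) == length(supports))
  sizes <- vapply(clades, length, 1L)
  ord <- order(sizes)                       # children resolved before parents
  clades <- clades[ord]; supports <- supports[ord]
  labels <- as.list(taxa)                   # current subtree strings
  members <- as.list(taxa)                  # leaf content of each open subtree
  for (i in seq_along(clades)) {
    cl <- clades[[i]]
    inside <- vapply(members, function(m) all(m %in% cl), TRUE)
    parts <- unlist(labels[inside])
    parts <- parts[order(vapply(members[inside], function(m) sort(m)[1L], ""))]
    lab <- paste0("(", paste(parts, collapse = ","), ")",
                  format(supports[i], digits = 6, trim = TRUE))
    labels <- c(labels[!inside], list(lab))
    members <- c(members[!inside], list(sort(unlist(members[inside]))))
  }
  parts <- unlist(labels)
  parts <- parts[order(vapply(members, function(m) sort(m)[1L], ""))]
  txt <- paste0("(", paste(parts, collapse = ","), ");")
  ape::read.tree(text = txt)
}
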