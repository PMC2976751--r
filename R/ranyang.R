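## Per-population coalescent likelihood in the Rannala-Yang
## parameterization (mutation-unit times tau, population sizes theta).
## This module is evaluation-only: the package's estimation path never
## maximizes this likelihood, because its joint maximum over (topology,
## tau, theta) does not exist -- a fact made executable by
## mle_nonexistence_path(), which follows a parameter path along which the
## likelihood grows without bound.

#' One gene's record in one ancestral population
#'
#' A population (species-tree branch) of duration \code{tau} that a gene
#' enters with \code{m} lineages and leaves with \code{n}: the \code{m-n}
#' coalescent waiting times \code{t} are ordered chronologically, so
#' \code{t[h]} is the interval during which \code{m - h + 1} lineages are
#' present. The root population has \code{tau = Inf} and must end with
#' \code{n = 1}.
#'
#' @param m entering lineage count.
#' @param n leaving lineage count, \code{1 <= n <= m}.
#' @param t coalescent interval times (mutation units), length \code{m-n}.
#' @param tau population duration (mutation units); \code{Inf} for the
#'   root population.
#' @return a list of class \code{"population_record"}.
#' @export
population_record <- function(m, n, t = numeric(0), tau) {
  if (!(m >= n && n >= 1L)) stop("need m >= n >= 1", call. = FALSE)
  if (length(t) != m - n)
    stop("need exactly m - n interval times", call. = FALSE)
  if (any(t < 0)) stop("interval times must be >= 0", call. = FALSE)
  if (is.infinite(tau) && n != 1L)
    stop("the root population must coalesce to a single lineage",
         call. = FALSE)
  if (is.finite(tau) && sum(t) > tau + 1e-12)
    stop("coalescent intervals exceed the population duration",
         call. = FALSE)
  structure(list(m = as.integer(m), n = as.integer(n), t = t, tau = tau),
            class = "population_record")
}

#' Sufficient statistics of a population's likelihood
#'
#' The per-population likelihood \eqn{(2/\theta)^a e^{-b/\theta}} depends
#' on the gene trees only through \eqn{a = \sum_k (m_k - n_k)} (total
#' coalescence count) and the weighted time sum
#' \eqn{b = \sum_k [ n_k(n_k-1)(\tau - \sum_j t_{kj}) +
#' \sum_j j(j-1) t_{kj} ]}, where j runs over the lineage counts during
#' each interval.
#'
#' @param records a list of [population_record()]s for one population
#'   (one per gene).
#' @return a list with integer \code{a} and non-negative \code{b}.
#' @export
sufficient_stats <- function(records) {
  if (inherits(records, "population_record")) records <- list(records)
  a <- 0L
  b <- 0
  for (r in records) {
    stopifnot(inherits(r, "population_record"))
    a <- a + (r$m - r$n)
    resid <- if (r$n > 1L) r$n * (r$n - 1L) * (r$tau - sum(r$t)) else 0
    js <- if (r$m > r$n) r$m:(r$n + 1L) else integer(0)  # chronological
    b <- b + resid + sum(js * (js - 1L) * r$t)
  }
  list(a = a, b = b)
}

#' Log-likelihood of a population given its sufficient statistics
#'
#' @param stats a list with \code{a} and \code{b} (see
#'   [sufficient_stats()]).
#' @param theta population size parameter, \code{> 0}.
#' @return \eqn{a \log(2/\theta) - b/\theta}.
#' @export
population_log_likelihood <- function(stats, theta) {
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  stats$a * log(2 / theta) - stats$b / theta
}

## The three fixed 3-taxon gene trees of the nonexistence demonstration:
## per gene, the first coalescing pair, its time, and the root time
## (mutation units). Heights: gene 1 joins a,b at 0.01 and c at 0.02;
## gene 2 joins a,c at 0.015 and b at 0.025; gene 3 joins a,b at 0.02 and
## c at 0.03.
ry_demo_data <- function() {
  list(list(pair = c("A", "B"), t1 = 0.010, t2 = 0.020),
       list(pair = c("A", "C"), t1 = 0.015, t2 = 0.025),
       list(pair = c("A", "B"), t1 = 0.020, t2 = 0.030))
}

#' The three gene trees of the MLE-nonexistence demonstration
#'
#' @return a \code{"multiPhylo"} of three ultrametric 3-taxon gene trees
#'   with mutation-unit branch lengths.
#' @export
ry_demo_gene_trees <- function() {
  txt <- c("((A:0.01,B:0.01):0.01,C:0.02);",
           "((A:0.015,C:0.015):0.01,B:0.025);",
           "((A:0.02,B:0.02):0.01,C:0.03);")
  out <- lapply(txt, read_newick, units = "mutation")
  class(out) <- "multiPhylo"
  out
}

## Decompose the demo gene trees over the species tree ((A:X,B:X):W,C:Y),
## Y = X + W: returns records for the A-B ancestral population and the
## root population.
ry_demo_records <- function(X, W) {
  Y <- X + W
  ab <- list(); root <- list()
  for (g in ry_demo_data()) {
    if (setequal(g$pair, c("A", "B")) && g$t1 < Y) {
      if (g$t1 < X)
        stop("gene coalescence at ", g$t1,
             " predates species divergence X = ", X, call. = FALSE)
      ab[[length(ab) + 1L]] <- population_record(2L, 1L, g$t1 - X, tau = W)
      root[[length(root) + 1L]] <-
        population_record(2L, 1L, g$t2 - Y, tau = Inf)
    } else {
      ## a and b fail to coalesce below the root (or the first event
      ## involves c): two lineages survive the A-B population
      if (g$t1 < Y)
        stop("gene coalescence involving C at ", g$t1,
             " predates the root Y = ", Y, call. = FALSE)
      ab[[length(ab) + 1L]] <- population_record(2L, 2L, tau = W)
      root[[length(root) + 1L]] <-
        population_record(3L, 1L, c(g$t1 - Y, g$t2 - g$t1), tau = Inf)
    }
  }
  list(ab = ab, root = root)
}

#' Likelihood path demonstrating that the joint MLE does not exist
#'
#' Follows the degenerate corner of parameter space for the three fixed
#' demonstration gene trees and the species tree ((A:X, B:X):W, C:Y),
#' Y = X + W: as the path parameter s decreases to 0, the A-B divergence
#' time X rises toward the earliest A-B gene coalescence (0.01), the
#' internal branch W shrinks to 0, and the A-B population size is tied to
#' \eqn{\theta_2 = 0.01 - X + 2W}, which drives that population's
#' likelihood term \eqn{(2/\theta_2) e^{-2}} to infinity while the root
#' population's term stays bounded (its time sum is bounded because
#' Y < 0.015). Hence no joint maximizer over (topology, tau, theta)
#' exists.
#'
#' @param s path parameter(s) in \code{(0, 1]}; smaller s is closer to the
#'   degenerate corner.
#' @param delta_x,delta_w path step scales: \code{X = 0.01 - delta_x * s},
#'   \code{W = delta_w * s}; \code{delta_w > delta_x} keeps Y above 0.01.
#' @param theta1 fixed root population size.
#' @return a data.frame with columns \code{s, X, W, Y, theta2,
#'   logL_ab, logL_root, logL} (total log-likelihood), one row per s.
#' @export
mle_nonexistence_path <- function(s, delta_x = 0.002, delta_w = 0.004,
                                  theta1 = 0.01) {
  stopifnot(all(s > 0), all(s <= 1))
  if (delta_x <= 0 || delta_w <= delta_x)
    stop("need 0 < delta_x < delta_w", call. = FALSE)
  out <- lapply(s, function(si) {
    X <- 0.01 - delta_x * si
    W <- delta_w * si
    Y <- X + W
    if (X >= 0.01 || W <= 0 || Y >= 0.015)
      stop("path point violates X < 0.01 < Y < 0.015, W > 0", call. = FALSE)
    theta2 <- 0.01 - X + 2 * W
    rec <- ry_demo_records(X, W)
    l_ab <- population_log_likelihood(sufficient_stats(rec$ab), theta2)
    l_root <- population_log_likelihood(sufficient_stats(rec$root), theta1)
    data.frame(s = si, X = X, W = W, Y = Y, theta2 = theta2,
               logL_ab = l_ab, logL_root = l_root, logL = l_ab + l_root)
  })
  do.call(rbind, out)
}
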