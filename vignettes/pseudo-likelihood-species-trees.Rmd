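---
title: "Species-tree estimation by rooted-triple pseudo-likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-tree estimation by rooted-triple pseudo-likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpest)
```

## The model

A rooted species tree on $N$ species has $N-2$ internal branches with
lengths $T_i$ measured in coalescent units ($T = 2\tau/\theta$, about one
unit per $2N_e$ generations). Under the multispecies coalescent, gene
lineages entering an ancestral population coalesce pairwise at rate 1 per
coalescent unit; lineages that fail to coalesce pass to the parent
population. With one sampled allele per species the terminal branches host
a single lineage each, which is why external branch lengths are not
estimable from gene-tree topologies and why the package never reports them.

For any three species the species tree induces a rooted triple, say
$AB|C$, whose internal branch length $B_j$ is the sum of the species-tree
internal edges between the MRCA of the cherry and the MRCA of the trio. A
gene tree shows the matching resolution $ab|c$ with probability
$1-\tfrac{2}{3}e^{-B_j}$ and each mismatching resolution with probability
$\tfrac{1}{3}e^{-B_j}$. Counting resolutions across $M$ gene trees gives,
per trio, a multinomial weight vector $(x_{j1}, x_{j2}, x_{j3})$; the
pseudo-likelihood multiplies these multinomials over all
$\binom{N}{3}$ trios as if they were independent (they are not — trios
share coalescent history — hence *pseudo*), dropping the multinomial
coefficient, which does not involve the species tree:

$$\log\Phi(S) = \sum_j \Big[ x_{j1}\,\log\big(1-\tfrac{2}{3}e^{-B_j}\big)
 + (x_{j2}+x_{j3})\big(\log\tfrac{1}{3} - B_j\big) \Big].$$

The estimate maximizes $\log\Phi$ jointly over topology and the $T_i$.
Dependence among trios costs efficiency, not consistency: as
$M\to\infty$ the triple frequencies converge to their expectations, which
identify the species tree (topology and internal branch lengths), and the
probability of recovering the true topology converges to 1 at rate
$O(M^{-1})$. The test suite exercises both properties empirically.

### Why not the full likelihood

The per-population coalescent density in the mutation-unit
parameterization factors, per population, into
$(2/\theta)^a e^{-b/\theta}$ with sufficient statistics $a$ (coalescence
count) and $b$ (a weighted time sum) — `sufficient_stats()` and
`population_log_likelihood()`. Its joint supremum over branch lengths and
population sizes is infinite: pushing a species divergence up against the
earliest gene coalescence while shrinking the intervening branch sends
$a=1$, $b\to 0$, and with $\theta$ tied to $b$ the factor
$(2/\theta)e^{-b/\theta}$ grows without bound while every other
population's factor stays bounded. `mle_nonexistence_path()` walks exactly
this corner for three fixed 3-taxon gene trees and returns the
monotonically diverging log-likelihood. The path's root-population time
sum is $0.29 - 14Y$ by direct summation of the per-gene factors (the
package derives it from the sufficient statistics; an independent
per-gene oracle in the tests confirms it). On the log scale the divergence
is logarithmic in the path parameter, so tests assert monotone growth and
a likelihood exceeding $10^6$, not an astronomically large log value that
double precision cannot reach before $\theta$ underflows.

## Estimation pipeline and numerical choices

`count_triples()` builds the sufficient statistic: one row per trio with
weights in a canonical slot order (taxa sorted; slots $ab|c$, $ac|b$,
$bc|a$). A resolved gene-tree triple adds 1 to its slot; an unresolved
(polytomic) one adds 1/3 to each slot; a gene missing any trio member
contributes nothing to that row, so each row keeps its own effective count
$M_j$ — the random-missingness generalization of a single global $M$. A
trio covered by no gene is a hard error: the package refuses to guess.

`optimize_branch_lengths()` maximizes $\log\Phi$ for a fixed topology.
The objective is concave in $T$ (each term is a composition of a concave
increasing function with an affine map; the tests verify non-positive
second differences along random segments), so a box-constrained
quasi-Newton ascent (L-BFGS-B, analytic gradient) from a warm start finds
the global maximum; the warm start is the pooled closed form per edge
$-\log\{\tfrac{3}{2}(1-\sum x_{j1}/\sum M_j)\}$, clamped to
$[0.01, 5]$. The box is $[0, T_{\text{cap}}]$ with
$T_{\text{cap}} = 10$: $e^{-10} \approx 4.5\times 10^{-5}$ is far below
any resolvable triple-frequency signal, so the cap only absorbs
near-degenerate data. Two situations produce the sentinel value 99 instead
of a length: every trio through the edge matches the species tree fully
(the supremum is at infinity — the classical "99" convention), or the
optimum lands on the cap. A fitted length of exactly 0 is reported as a
zero-length branch and logged as polytomy-consistent: the triple
frequencies sit at the star point 1/3, and the method can legitimately
estimate polytomies this way.

`exhaustive_search()` scores all $(2N-3)!!$ rooted topologies for
$N \le 6$ (the package enumerates up to $N = 7$; the search switches to
heuristics above 6). `hill_climb()` performs steepest-ascent NNI from a
data-driven start (greedy joining by pooled cherry frequency) plus
uniformly random restarts, accepting only strict improvements
($> 10^{-9}$) and breaking score ties by canonical newick order, which
makes every run reproducible from its seed. Equal-scoring distinct
topologies do occur — e.g. when a fitted branch is 0, collapsing it makes
several binary resolutions exactly tie — and the canonical-order rule
picks the same one every time. Conformance is defined by reaching the
global optimum (verified against exhaustive search on 5-taxon instances),
not by any particular search trajectory.

Robinson–Foulds distances use the *rooted clade* convention — the
symmetric difference of the sets of non-trivial clades — because rooted
trees are compared throughout; unrooted bipartition RF can differ on the
same pair. Consensus trees use majority rule with strictly-greater
inclusion and, in the extended variant, greedy addition of compatible
lower-frequency clades ordered by frequency and then lexicographically by
leaf tuple; the lexicographic step is our determinism substitute for
CONSENSE's unspecified tie handling.

## What the simulator emulates

`simulate_gene_trees()` implements the standard multispecies coalescent
per branch (exponential waiting times at rate $k(k-1)/2$, uniform pair
choice, root population run to completion), one allele per species, and
records coalescent-unit node times. `simulate_triple_counts()` and
`simulate_topology_frequencies()` run the identical process but accumulate
triple resolutions or topology tallies directly — with the same seed they
reproduce `count_triples()` on materialized trees exactly, which a test
asserts. Default study conditions follow the simulations the method was
designed around: birth–death species trees (`random_species_tree()`, birth
10, death 0.1, conditioned on the number of surviving tips — the
conditioning scheme is ours, via `ape::rphylo`), per-branch population
sizes $\theta \sim U(0.005, 0.01)$, and the anomalous five-taxon tree
`((((A:0.5,B:0.5):0.025,C:0.525):0.025,D:0.55):1,E:1.55)` whose most
probable gene tree `(((A,B),(C,D)),E)` differs from it by rooted RF 2.

The HGT model is deliberately triple-level: transfer events between the
outgroup species of a triple and either cherry member arrive as a Poisson
process with mean $2\lambda L$, flipping the matching probability to
$e^{-2\lambda L} - \tfrac{2}{3}e^{-B}$; the complementary mass splits
equally between the two mismatching resolutions because the two transfer
routes are symmetric. When the expression is negative (strong transfer,
short branch) the model simply does not apply and the package raises an
error rather than truncating. Whole-gene-tree transfer editing is out of
scope.

What passing simulations do *not* show: gene trees here are known without
error, whereas real gene trees are estimated from finite alignments; the
gene-level bootstrap (`gene_bootstrap()`, `bootstrap_support()`) quantifies
only the between-gene sampling variance, not within-gene reconstruction
error. The two-level scheme (site resampling within genes) requires an
external ML program to re-estimate gene trees; supply such per-replicate
estimates to a `bootstrap_run` directly if you have them. Supports
annotate the consensus topology; branch lengths should be read from the
full-data fit.

## Problem sizes used in validation

The suite validates the triple-frequency law at $M = 10^4$ per branch
length (three binomial standard errors), the HGT law at $M = 10^5$, the
anomaly-zone modal topology over $2\times 10^5$ simulated gene trees, and
consistency with 50 seeds (topology recovery at $M = 10$ vs $10^3$), 20
seeds (branch RMSE at $M = 10^2$ vs $2\times 10^3$; anomalous-tree
recovery at $M = 10^2$ vs $5\times 10^3$). These sizes give comfortable
separation for every monotone comparison while keeping the full suite
around two minutes on one core.

## Known limitations

- One allele per species; multiple alleles are rejected, not pooled.
- External branch lengths and $\theta$, $\tau$ are never estimated.
- The pseudo-likelihood ignores correlation among trios, so its curvature
  must not be used for confidence intervals; use the bootstrap.
- Search above $N = 6$ is heuristic; NNI with restarts has no optimality
  guarantee, though it matched exhaustive search on all tested instances.
- Newick input is strict by design: quoted labels and comments are errors.
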