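---
title: "Reduced Google matrix analysis: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced Google matrix analysis: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regomax)
```

This vignette is the package's own account of the science it implements:
the Google-matrix model of a directed citation network, the reduced Google
matrix of a node subset and its decomposition, the derived quantities
(hidden links, PageRank sensitivity, friend networks, ranked-list
overlaps), the synthetic generator that stands in for a full-size network,
and the numerical and design choices that were genuinely open.

## The Google matrix model

A directed network of $N$ nodes with binary adjacency $A_{ij} = 1$ when
node $j$ cites node $i$ (columns index sources, so the operator acts on
probability column vectors) defines the stochastic matrix
$S_{ij} = A_{ij}/k_{\mathrm{out}}(j)$, with dangling columns
($k_{\mathrm{out}} = 0$) set uniform to $1/N$, and the Google matrix

$$ G = \alpha S + (1 - \alpha) \tfrac{1}{N}, $$

a column-stochastic operator describing a random surfer who follows a
random outgoing link with probability $\alpha$ and teleports uniformly
otherwise.  Self-loops are excluded from the network model itself:
self-citations carry no information here and would distort the column
normalisation.  Duplicate links collapse to one (the adjacency is binary).

The PageRank vector is the unit-eigenvalue right eigenvector $GP = P$,
normalised to $\sum_j P(j) = 1$; damping makes $G$ primitive, so $P$ is
unique and strictly positive.  Nodes sorted by decreasing $P$ receive rank
indices $K = 1, 2, \dots$  CheiRank $P^*$ is the PageRank of the
link-inverted network ($A^*_{ij} = A_{ji}$) and measures outgoing
communicativity.  The damping factor defaults to the standard
$\alpha = 0.85$; rankings of interest are insensitive to it over roughly
$0.5 \le \alpha \le 0.95$, a property the test suite exercises on a
hub-dominated synthetic network.

**Representation.** The rank-one teleportation term and the uniform
dangling columns are held implicitly (sparse link part + dangling index
set).  Every operation — matrix–vector products, block extraction, the
dense realisation — behaves exactly as if the dense $G$ existed; this is a
storage contract only, with no semantic effect.

**PageRank numerics.** Power iteration from the uniform vector,
renormalised each step, stopping when the L1 change drops below `tol`
(default $10^{-12}$, `max_iter` 1000, non-convergence is an error carrying
the last residual).  The iterate is a probability vector at every step, so
probability is conserved by construction.  Rank ties are broken by
ascending node index — the choice is arbitrary but must be deterministic
for reproducible rank tables.

## The reduced Google matrix and its decomposition

For a subset of $N_r$ nodes ("r") embedded in the remaining
$N_s = N - N_r$ nodes ("s"), partition
$G = \begin{pmatrix} G_{rr} & G_{rs} \\ G_{sr} & G_{ss} \end{pmatrix}$.
The reduced Google matrix

$$ G_R = G_{rr} + G_{rs} (I - G_{ss})^{-1} G_{sr} $$

sums the direct block and every pathway of every length through the
complement ($ (I-G_{ss})^{-1} = \sum_{l \ge 0} G_{ss}^l $).  $G_R$ is
column-stochastic, and its PageRank equals the global PageRank restricted
to the subset and renormalised — the defining contract, which the tests
verify to $10^{-9}$ against an independently computed global PageRank.

The resolvent is split along the leading eigenvalue $\lambda_c$ of
$G_{ss}$.  With right/left leading eigenvectors $\psi_R, \psi_L$
(normalised $\sum \psi_R = 1$, $\psi_L \cdot \psi_R = 1$), projector
$P_c = \psi_R \psi_L^T$, $Q_c = I - P_c$ and
$\bar G_{ss} = Q_c G_{ss} Q_c = G_{ss} - \lambda_c P_c$:

$$ G_{pr} = \frac{G_{rs} P_c G_{sr}}{1 - \lambda_c}, \qquad
   G_{qr} = G_{rs} Q_c (I - \bar G_{ss})^{-1} Q_c G_{sr}, $$

so $G_R = G_{rr} + G_{pr} + G_{qr}$ exactly.  $G_{pr}$ is dominated by the
leading mode of the complement and essentially restates the PageRank
weights; $G_{qr}$ carries the genuinely indirect structure.  Its diagonal
part $G_{qrd}$ collects self-returning pathways; the off-diagonal part
$G_{qrnd}$ describes indirect interactions between distinct subset nodes
(entries can be negative, since the leading-mode contribution is
subtracted).  Component weights $W_X = \sum_{ij}(G_X)_{ij}/N_r$ satisfy
$W_R = 1$ and $W_{pr} + W_{rr} + W_{qr} = 1$.

**Two evaluation routes.** `method = "direct"` computes $G_R$ by one dense
linear solve on the complement (exact at the problem sizes this package
targets); `method = "spectral"` assembles it from the three components.
Both objects carry the full decomposition — the spectral machinery is
needed in either case because the hidden-link analysis consumes
$G_{qrnd}$ — so direct-vs-spectral agreement (typically $10^{-13}$,
tested at $10^{-10}$) is a genuine internal cross-check, not a tautology.
The deflated resolvent can also be evaluated as the truncated series
$\sum_l \bar G_{ss}^l$ with an L1 tail bound of $10^{-12}$
(`qr_eval = "series"`, depth recorded); solve and series agree to
$10^{-10}$ in the tests.

**Numerical choices.**

* The leading eigenpair of $G_{ss}$ comes from a dense eigensolver up to
  800 complement nodes (all desk-scale uses) and from power iteration
  beyond.  All entries of $G_{ss}$ are positive, so the Perron eigenvalue
  is real, simple and in $(0, 1)$ for a damped sub-stochastic block.
* A leading-eigenvalue gap below $10^{-8}$ is refused with a diagnostic
  rather than silently picking one eigenvector: the $G_{pr}$/$G_{qr}$
  split is ill-defined at a degenerate leading eigenvalue.  Real damped
  matrices have a clean gap.
* Eigenvector normalisation ($\psi_R$ summing to 1, $\psi_L \cdot \psi_R
  = 1$) makes $P_c$ a true projector and the decomposition reproducible
  across platforms, eliminating the sign/scale freedom of eigensolvers.
* $N_r = N$ is defined as the degenerate case $G_R = G_{rr} = G$,
  $G_{pr} = G_{qr} = 0$, $\lambda_c$ undefined (`NA`).

## Hidden links

$G_{rr}$ restricted to the subset reproduces the adjacency: an entry is a
real link exactly when it exceeds the teleportation floor
$(1-\alpha)/N$ (the implementation adds $10^{-15}$ slack to the strict
inequality so floating-point equality at the floor never counts as a
link).  A **hidden link** $(i, j)$ has no direct link but
$(G_{qrnd})_{ij} > 0$: the interaction exists only through the rest of the
network.  The default threshold is zero — any strictly positive indirect
weight on a structurally absent link qualifies; a higher threshold can be
set when only strong hidden links are wanted.

## PageRank sensitivity

The influence response of node $c$ to the link $b \to a$ inside the
subset: multiply $(G_R)_{a,b}$ by $(1+\delta)$, renormalise column $b$ to
unit sum, and define $D(b \to a, c) = d \ln P(c)/d\delta$ evaluated on the
$N_r$-dimensional reduced matrix (this matches the definition of the
quantity on $G_R$ elements; re-running the global network is neither
needed nor equivalent).  The definition fixes the derivative but not its
evaluation; this package uses central finite differences with
$\delta = 10^{-4}$ by default ($O(\delta^2)$ accurate; the forward scheme
and the step size are exposed).  The tests verify quadratic step
convergence, agreement of $\delta = 10^{-3}$ vs $10^{-4}$ to better than
three significant digits, and the exact identity at $\delta = 0$.
Perturbing a structural zero is refused, and the matrix-valued driver
reports such pairs as `NA` — "no link" must not be conflated with
"insensitive".  Note the sign structure: boosting an outgoing link of $b$
typically *lowers* $P(b)$ itself (flow is diverted), so diagonal
sensitivities are usually negative and "strongest partner" means largest
magnitude.

## Friend networks and partner tables

Interactions are scored by $(G_{rr} + G_{qrnd})$ — direct strength plus
genuinely indirect off-diagonal strength.  From seed nodes, each expanded
node contributes its `n_friends` strongest same-category partners; only
nodes newly added at iteration $t$ are expanded at $t+1$ (breadth-first),
until no new node appears.  Finite node set and monotone growth guarantee
the fixpoint; `max_iter` is a safety valve only.  Afterwards every
primary-category node — including seeds — receives its `n_attach`
strongest partners per attached category, and attached nodes are never
expanded.  Edges record iteration, weight and kind (direct/hidden, the
hidden flag cross-checked against the adjacency on every build).  Ties are
broken by ascending local PageRank index (deterministic, favouring the
more influential candidate); scores must be strictly positive to create an
edge (a non-positive score means there is no interaction to follow).  The
partner tables support both score variants $(G_{rr}+G_{qrnd})$ and
$(G_{rr}+G_{qr})$, since published usage varies between the two; the
choice is a parameter rather than a guess.

## Ranked-list overlaps and the packaged tables

$\eta(j)$ counts the common items in the top $j$ of two ranked lists; it
is symmetric, non-decreasing, and grows by at most 2 per step.  The
package ships plain-text transcriptions of the published tables: the 37
cancer types and 203 cancer drugs, their PageRank ordering in the May-2017
English Wikipedia analysis, and the GBD-2017 (deaths, DALYs) and
GLOBOCAN-2018 (deaths, new cases) cancer rankings.  Labels pass through an
explicit, versioned canonicalisation table (apostrophe variants,
abbreviations like "NETs", "GTD", "M. myeloma", short forms like "Lung");
overlap counts must never hinge on silent string matching, so duplicates
after canonicalisation are an error naming the collision.  "Melanoma" and
"Skin cancer" are distinct entries throughout (both appear separately in
the GLOBOCAN tables).  Recomputed from the tables, the network-derived
cancer ranking overlaps the GBD-2017 death ranking in 7 of the top 10,
the GLOBOCAN-2018 death ranking in 6 of the top 10, and the GLOBOCAN-2018
new-case ranking in 4 of the top 5 — the values the acceptance script
reports.

## The synthetic generator

No generative model exists for the real network (the analysis uses a full
encyclopedia dump of several million articles, out of scope here), so the
generator's contract is to reproduce the qualitative structure the
analysis relies on, not any degree-sequence detail:

* a background grown by directed preferential attachment (each new node
  sends `m_out = 4` links to existing nodes chosen $\propto$ in-degree
  + 1), giving the heavy-tailed in-degree distribution of citation
  networks — at 2000 background nodes the top 1% of nodes hold far more
  than 1% of the in-links;
* a few **hubs** (country analogues) cited by a configured fraction of the
  background (`hub_bias`, default 0.5 over 3 hubs), which occupy the top
  PageRank positions;
* two stratified **groups** (cancer and drug analogues, 8 nodes each)
  cited by the background at rates 0.05 and 0.015 — roughly a factor
  three apart, enough to stratify their median ranks (hubs before cancer
  analogues before drug analogues, a property checked over 20 seeds with
  a shuffled-label negative control);
* a 5% **dangling** fraction, exercising the uniform-column rule;
* **planted indirect pathways**: a fresh relay chain source → relay →
  target with no direct source→target link (any accidental direct link is
  removed).  The relay has out-degree one, so the two-hop channel carries
  weight $\approx \alpha^2 / k_{\mathrm{out}}(\mathrm{source})$ while
  competing background pathways are diluted over many nodes — this is why
  hidden-link recovery is a structural property of the scenario and not a
  tuned constant.

All rates are explicit configuration; a fixed seed gives byte-identical
output (Mersenne-Twister with rejection sampling, pinned in the generated
object).  What passing tests on these networks shows is that the
*machinery* — reduction, decomposition, hidden-link detection, sensitivity
— behaves correctly under the structural conditions it assumes; it does
not validate any claim about a particular real network, whose texture
(topical correlation of links, noise from editorially transient links,
orders-of-magnitude larger scale) the generator deliberately does not
imitate.

## Problem sizes and limitations

The default test and acceptance batteries use networks of up to a few
hundred nodes (method-contract checks: 200 random networks with
$N \le 60$, $N_r \le 12$; recovery: 50 configurations of ~170 nodes;
generator tail checks: one 2000-node network) — sizes at which the dense
complement solve is exact and the whole battery runs in seconds.  The
implementation is dense beyond the sparse link part of $G$; complements
past a few thousand nodes would need sparse iterative resolvents, which
are out of scope.  Other known limitations: the label canonicalisation
covers the word forms occurring in the shipped tables, not arbitrary
clinical nomenclature; sensitivity uses finite differences rather than an
analytic resolvent derivative (a documented possible extension); and the
friend-network construction is deterministic given its score matrix, so
any instability in the underlying ranking propagates to it unchanged.
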