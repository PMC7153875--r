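---
title: "Multiplex social networks from focal-sampling data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex social networks from focal-sampling data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socmux)
```

## The problem

Animal sociality is multidimensional: the same pair of individuals may
groom, tolerate each other at a feeding site, and compete, and each kind of
interaction carries different information about their relationship.
Classical social network analysis flattens this into one network per
behaviour, or worse, one aggregate network. `socmux` implements the
multiplex alternative for small, intensively observed groups (the motivating
setting is a captive matriline of six to seven female mandrills followed
with 15-minute focal samples): each interaction type becomes one layer of a
node-aligned multiplex network, and questions about individual importance
and about redundancy between behaviours are answered on the multiplex
object itself.

The pipeline is: focal records → dyadic totals → normalized dyadic
indices → multiplex network → per-layer eigenvector centrality, multiplex
versatility and edge overlap → structural reducibility.

## From observations to dyadic indices

Focal records are timed events (`groom`, `feed_proximity`, durations in
seconds) or point events (`aggression`, `supplant_avoid`, counted once per
record and merged into a single *agonism* class). Totals collapse
direction: all occurrences between the two members of a dyad are summed
regardless of actor and recipient.

Two summary conventions matter and are deliberate:

* **Dyadic observation time is $h_i + h_j$**, the sum of both members'
  focal hours: a dyad is on view whenever either member is the focal
  animal, and each event enters the data as exactly one record, so no
  double-count correction is needed. Per-hour rates divide each dyad's
  total by this quantity, and means/SDs are taken over *all* possible
  dyads, zeros included. Under equal effort this gives the algebraic
  identity $\bar r \cdot \binom{n}{2} \cdot (h_i+h_j) = \text{grand
  total}$, which the tests assert.
* **SD over dyads uses the sample ($n-1$) denominator by default**, with a
  `sd_type = "population"` switch. Field reports rarely state the
  convention; the default is the one a naive `sd()` call produces, and the
  switch makes the other reproducible.

Percentages are reported half-up to one decimal and rates to two; internal
values keep full precision (`round_half_up()` is applied only at the
reporting surface).

The **dyadic index** divides each dyadic total by the grand total for that
interaction type, so every layer sums to 1 over unordered dyads. This puts
seconds-scale layers (grooming) and count-scale layers (agonism) on a
common scale before they are combined. A zero-total interaction type is an
error rather than an all-zero layer: a zero layer has no Laplacian density
matrix, so the caller must drop it explicitly. Restricting the universe
(e.g. excluding an individual not observed in one period) drops her dyads
from the *totals* and re-normalizes, which commutes with computing the
index — a property the tests check.

## Multiplex construction

Layers share one ordered universe; individuals without interactions in a
layer stay in the matrix as isolates but carry a presence flag of `FALSE`.
Interlayer coupling is *categorical* — every pair of layers, weight
$\omega = 1$ by default — because layers are interaction types, not
time-ordered snapshots. Coupling attaches only where an individual is
present in both layers (the `couple_all = TRUE` switch couples everywhere,
for sensitivity analysis). The supra-adjacency matrix is the
$(nL) \times (nL)$ block matrix with layer adjacencies on the diagonal
blocks and $\omega$ on the matching-individual entries off-diagonal.

**Centrality and versatility.** Per-layer eigenvector centrality is the
nonnegative leading eigenvector of the layer adjacency; versatility is its
multiplex analogue, computed from the leading eigenvector of the
supra-adjacency with each individual's components summed across layers.
Both are max-normalized (largest score 1) by default, with a unit-sum
option; only ranks are interpreted downstream, so the normalization is
cosmetic.

The eigenvector is found by power iteration from the uniform positive
vector (tolerance $10^{-12}$ on the max-norm change, capped at $10^5$
iterations) applied to the *shifted* matrix $A + I$. The shift matters:
plain power iteration cycles with period two on bipartite layers — a star,
for example, has extreme eigenvalues $\pm\lambda$ of equal magnitude — while
$A + I$ has the same Perron eigenvector with strictly dominant eigenvalue
$\lambda_{\max} + 1$, so the iteration converges on every connected
nonnegative layer. On a disconnected layer the iteration converges to the
eigenvector of the component carrying the dominant eigenvalue; other
components receive numerically zero centrality, deterministically, given
the fixed start vector. "Most central" reports list *all* individuals
within $10^{-9}$ of the maximum rather than silently picking one.

**Edge overlap.** Two measures are provided. `binary_jaccard` compares
edge *sets*: shared positive dyads over the union. `weighted_min` sums the
dyad-wise minimum of two index layers — meaningful because each index layer
sums to 1, so the value is the fraction of index mass the layers share.
Published overlap figures for this kind of data cannot in general come
from a binary measure (an agonism layer frequently covers every dyad,
forcing binary overlaps to fixed set ratios), and the exact weighted
normalization used by any given graphical tool is usually unstated; both
well-defined measures are therefore exposed and every reported overlap
names its method. Global overlap is either the mean of the pairwise values
or the all-layer minimum mass.

## Structural reducibility

The reducibility analysis asks which layers can be aggregated without
losing non-redundant structure.

1. Each layer's **density matrix** is its trace-normalized combinatorial
   Laplacian, $\rho = (D - A)/\mathrm{tr}(D - A)$: positive semidefinite,
   trace 1.
2. **Von Neumann entropy** $h(\rho) = -\sum_i \lambda_i \log_2 \lambda_i$
   (eigenvalues below $10^{-12}$ treated as exact zeros). Base-2 logs make
   the Jensen–Shannon distance lie in $[0,1]$; the quality function below
   is a ratio and hence base-invariant. Closed forms pin the
   implementation: a single-edge graph has spectrum $\{0, 1\}$ and entropy
   0; $K_4$ has Laplacian spectrum $\{0,4,4,4\}$, hence entropy
   $\log_2 3$; a 4-node star has $\{0,1,1,4\}/6$.
3. **Jensen–Shannon distance**
   $D_{ab} = \sqrt{h(\tfrac{\rho_a+\rho_b}{2}) - \tfrac{h(\rho_a)+h(\rho_b)}{2}}$,
   with a radicand floor at $-10^{-10}$ (clipped to zero) for rounding.
4. **Ward clustering** of the distance matrix. The default is the Ward.D2
   convention (Lance–Williams recursion on squared distances); a `ward =
   "d1"` switch applies the recursion to raw distances, because older
   toolchains used that variant and the two can order merges differently.
   The agglomeration is written out explicitly (a few lines of
   Lance–Williams updates) so that ties break deterministically on the
   lexicographically smallest cluster-label pair; `stats::hclust` serves as
   an independent cross-check in the test suite rather than as the
   implementation.
5. **Relative entropy curve.** After $m$ merges the partition $C_m$ has
   $M - m$ groups; its quality is
   $q(C_m) = 1 - \bar H(C_m)/h_{\mathrm{agg}}$ where $\bar H$ is the mean
   entropy of the groups' summed adjacencies and $h_{\mathrm{agg}}$ the
   entropy of the everything-summed network. $q$ at the final step is
   identically 0. The best step is the argmax of $q$, ties resolved to the
   smallest step — the least-aggregated network — so "nothing can be merged
   without loss" is the default verdict under exact ties (e.g. for
   duplicated layers, where $\rho$'s scale-invariance makes $q \equiv 0$).

Entropy here is computed on **intralayer structure only**: interlayer
coupling is excluded from the density matrices. The alternative (including
$\omega$ in a supra-Laplacian) is defensible, but coupling is a modelling
constant, not data, and including it would let $\omega$ leak into a
data-similarity measure. Aggregation sums raw index weights without
re-normalization, which is immaterial for $\rho$.

The greedy dendrogram path does not necessarily contain the globally
optimal partition. For three and four layers the tests enumerate *all* set
partitions as an oracle: the greedy optimum can never exceed the
exhaustive optimum, must attain it whenever the optimal partition lies on
the dendrogram path, and any off-path instance is logged rather than
silently accepted — the greedy procedure is the method; the oracle bounds
it.

## The synthetic generator

`synth_config()` emulates one observation period of focal sampling so the
entire pipeline is testable without field data, and so structure-recovery
claims can be made on data whose ground truth is known.

* **Latent structure.** Each dyad has a shared affinity
  $a_{ij} \sim \Gamma(\text{shape}, \text{scale})$; layer $k$'s propensity
  is $p_k = \lambda_k a + (1-\lambda_k) e_k$ with independent noise $e_k$
  from the same Gamma. $\lambda_k \in [0,1]$ is the cross-layer
  redundancy dial: at 1 two layers share their dyadic structure exactly,
  at 0 they are independent. `duplicate_of` copies realized events
  verbatim for exact-twin layers.
* **Observation model.** Events per dyad and layer are Poisson with mean
  $\nu_k\, p_k\, (h_i + h_j)$; timed layers draw exponential bout lengths
  with mean $\mu_k$. Each event is assigned to a uniformly chosen member's
  focal session with uniformly random actor/recipient orientation —
  direction is randomized because all downstream analysis is undirected.
  Sessions are 15-minute blocks; events are not time-stamped within
  sessions, since rates are the modelled quantity.
* **Defaults as study conditions.** Six individuals at 16 focal hours
  each, three layers. Rates and bout means were set once from the
  magnitudes such focal studies report — grooming
  $\nu = 0.05$ events and $\mu = 530$ s (≈ 26 s of grooming per dyadic
  hour in expectation), proximity $\nu = 0.1$, $\mu = 84$ s (≈ 8 s/h),
  agonism $\nu = 0.87$ episodes/h — with Gamma shape 0.5 and scale 2
  (mean 1, strongly skewed) so that interactions concentrate on a minority
  of dyads (roughly half the dyads groom at all in expectation, matching
  the sparsity typical of grooming matrices), while agonism touches nearly
  every dyad. Redundancy defaults: 0.6 for grooming and proximity (animals
  that groom tend to feed together), 0.1 for agonism.
* **What it does not emulate.** No dominance-rank dynamics, no maturation
  or demographic change, no seasonality, no directed asymmetries, no
  observer error. Passing structure-recovery tests on these data shows the
  machinery is correct and sensitive to engineered redundancy; it does not
  validate any biological claim about real groups.

Deterministic fixtures (`make_fixture()`) complement the simulator:
`k4_vs_star` pins the entropies to closed forms, `duplicated_pair` forces
a zero distance and a known first merge, `independent_trio` is built so
that keeping all layers separate is optimal, and `study_shape` reproduces
the 7/10/15-edge layer shape of a six-individual, three-layer network.

## Numerical and interface choices

* Eigenvalue floor $10^{-12}$ before the entropy log; PSD tolerance
  $-10^{-10}$; JSD radicand floor $-10^{-10}$; index normalization checked
  to $10^{-12}$.
* Degenerate inputs error early and by name: edgeless layers (no density
  matrix, no centrality), all-zero totals, universes below two
  individuals, restriction that strands all interaction mass.
* The pipeline configuration is a YAML file mirroring `pipeline_config()`;
  CLI flags override file values. Reports are plain TSV/CSV plus a
  `summary.txt` carrying the seed, a config hash and the package version,
  and identical configs produce byte-identical artifacts whether run
  monolithically (`run_pipeline()`) or stage by stage.
* Test and acceptance problem sizes: random oracle checks use up to 10
  individuals and 3 layers ($nL \le 60$ supra matrices, dense
  eigendecompositions as oracles), Monte-Carlo calibration uses 200
  replicates of a 5-individual group, and redundancy-monotonicity checks
  average 20 replicate simulations — sizes at which every oracle is exact
  or statistically stable.

## Known limitations

* Directed analyses are out of scope by design; direction is collapsed at
  the totals stage.
* Published overlap values from specific graphical tools may not be
  reproducible without knowing their normalization; both overlap methods
  here are exactly specified instead.
* The greedy reducibility path can miss the globally optimal partition
  (bounded, and logged, by the exhaustive oracle at small layer counts).
* Rate SDs depend on the full per-dyad distribution, so they can only be
  checked against complete dyadic matrices, not against grand totals.
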