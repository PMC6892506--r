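---
title: "Reduced Google matrix analysis: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced Google matrix analysis: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regomax)
```

## The model

A directed network of $N$ nodes is described by its adjacency matrix $A$,
with $A_{ij} = 1$ when node $j$ points to node $i$. The link-following
transition matrix $S$ has columns $A_{\cdot j}/k_{out}(j)$; a dangling node
(no outgoing links) gets the uniform column $1/N$, so a random surfer
stranded there jumps anywhere. The Google matrix

$$G = \alpha S + (1-\alpha)\tfrac{1}{N}\mathbf{1}\mathbf{1}^T$$

mixes link-following with uniform teleportation at damping $\alpha$. Its
stationary vector $P = GP$, $\lVert P\rVert_1 = 1$, is the PageRank; sorting
$P$ in decreasing order gives the rank index $K$ ($K = 1$ most influential).
The CheiRank $P^*$ is the PageRank of the edge-reversed network and measures
outgoing-link diffusivity; its index is $K^*$. Both vectors exist and are
unique for $0 < \alpha < 1$ by Perron–Frobenius, and are computed here by
power iteration.

### The reduced Google matrix

For a subset $r$ of $N_r$ nodes of interest embedded in a much larger
network, partition $G$ into blocks over $r$ and its complement $s$. The
reduced Google matrix

$$G_R = G_{rr} + G_{rs}\,(\mathbb{1} - G_{ss})^{-1} G_{sr}$$

is the unique $N_r \times N_r$ column-stochastic matrix whose stationary
vector reproduces the relative global PageRank of the subset: if $P$ is the
global PageRank, the fixed point of $G_R$ equals
$\kappa P|_r$ with $\kappa = 1/\sum_{i \in r} P_i$. The geometric expansion
of $(\mathbb{1}-G_{ss})^{-1}$ shows what $G_R$ sums: direct transitions plus
every indirect pathway through any number of complement nodes.

The matrix splits into three parts, $G_R = G_{rr} + G_{pr} + G_{qr}$.
Writing $\lambda_c$ for the leading eigenvalue of $G_{ss}$ and
$\psi_R, \psi_L$ for its right and left eigenvectors, the spectral projector
$\mathcal{P}_c = \psi_R\psi_L^T/(\psi_L^T\psi_R)$ splits the resolvent, giving

$$G_{pr} = \frac{G_{rs}\,\mathcal{P}_c\,G_{sr}}{1-\lambda_c}, \qquad
  G_{qr} = G_{rs}\,\mathcal{Q}_c(\mathbb{1} - \mathcal{Q}_c G_{ss}\mathcal{Q}_c)^{-1}\mathcal{Q}_c\,G_{sr},
  \qquad \mathcal{Q}_c = \mathbb{1}-\mathcal{P}_c.$$

$G_{rr}$ is the literal sub-block of $G$ (direct links). $G_{pr}$ is exactly
rank one and carries the PageRank-dominated flow — each of its columns,
normalised, approximates the reduced PageRank — so it adds little beyond the
global ranking. The interesting object is $G_{qr}$: the indirect coupling
between subset nodes carried by multi-hop pathways. Its diagonal
($G_{qrd}$) holds self-interactions and is discarded for link inference; a
large off-diagonal entry ($G_{qrnd}$) between two nodes with no direct edge
is a *hidden link*.

Two properties deserve emphasis because they differ from an idealised
picture:

* **$G_{qr}$ can be genuinely negative.** The spectral remainder is not a
  nonnegative matrix; entries at the $10^{-3}$ level below zero appear even
  on well-structured networks, and much larger ones when $\lambda_c$ is
  weakly separated. The package never clips them (clipping would break the
  additive decomposition); it records the minimum as a diagnostic and warns
  below $-10^{-2}$.
* **Teleportation is itself an indirect pathway.** Even between nodes with
  no link-mediated paths, $G_{qrnd}$ entries sit at a teleportation-induced
  floor rather than at zero. What identifies a real hidden link is
  dominance over that floor, which is what the hidden-link screening and its
  tests measure.

### PageRank sensitivity

The influence of one effective link $j \to k$ on a component $i$ of the
reduced PageRank is measured by the logarithmic derivative

$$D(j \to k, i) = \frac{1}{P_i}\frac{dP_i}{d\delta},$$

where the perturbed matrix rescales column $j$ as
$G_{lj} \to G_{lj}/(1+\delta G_{kj})$ for $l \neq k$ and
$G_{kj} \to G_{kj}(1+\delta)/(1+\delta G_{kj})$, keeping the column sum at 1
exactly. $P(\delta)$ is the stationary vector of the perturbed $G_R$ itself;
no second damping is applied, since $G_R$ is already column-stochastic.
The diagonal profile $D(s \to c, c)$ over a target group answers questions
like "which countries respond most to a boost from this company".

### Friendship networks

From the top-ranked nodes of a seed group, the extraction follows, for each
processed node, its strongest same-group and partner-group couplings in
$G_{rr} + G_{qrnd}$ (the direct block plus indirect links, self-interactions
excluded), adding nodes level by level until an iteration contributes no new
seed-group node. Each traced edge is labelled direct or hidden by consulting
the adjacency restricted to the subset. Monotone growth bounded by the
seed-group size guarantees termination.

## Numerical realisation

* **Matrix-free operators.** $S$ is stored as its sparse link part plus a
  dangling indicator; the dangling and teleportation rank-one terms are
  applied analytically. No dense $N \times N$ object is ever formed, so the
  machinery is scale-agnostic.
* **Fixed points.** Power iteration with an L1 stopping rule
  (default `tol = 1e-12`, `max_iter = 1000`, uniform start). Start
  independence is guaranteed by Perron–Frobenius and asserted in tests.
  Non-convergence is an error carrying the residual, never a silent result.
* **Two reduction backends.** For complements up to `dense_cap` (default
  2000) nodes, dense LAPACK solves. Above that, an iterative path: since
  $G_{ss} = \alpha S^0_{ss} + \mathbf{1}t^T$ with $t$ the teleportation +
  dangling column constants, $(\mathbb{1}-G_{ss})^{-1}$ is evaluated by a
  Sherman–Morrison update around $M = \mathbb{1} - \alpha S^0_{ss}$, whose
  Neumann series contracts at rate $\alpha$ regardless of network size or of
  how close $\lambda_c$ is to 1. The $G_{qr}$ series contracts at the
  subleading eigenvalue after projection. Series stop when the current term
  falls below $0.01 \cdot tol$ relative to the accumulated sum. The two
  backends agree to $10^{-10}$ on every instance where both run, and both
  are compared in the tests against a third, fully independent dense-eigen
  oracle.
* **Eigenpair of $G_{ss}$.** Power iteration with L1 normalisation on the
  operator and its transpose. The teleportation term gives the synthetic
  networks a comfortable spectral gap; the iteration cap and tolerance are
  shared with the series solves.
* **Sensitivity.** Default is a symmetric finite difference at
  $\delta = 10^{-4}$, which matches the $\delta \to 0$ limit to second
  order; `method = "exact"` differentiates the fixed-point equation and
  solves the singular system $(\mathbb{1}-G_R)\,x = G_R' P$ under
  $\sum_i x_i = 0$ by augmented least squares. Stationary vectors in this
  module come from a dense least-squares solve (machine precision) rather
  than power iteration, so the finite difference is not polluted by solver
  noise. Agreement between the two routes is measured as relative error in
  the sup norm of the sensitivity field, $\max_i |D^{fd}_i - D^{ex}_i| /
  \max_i |D^{ex}_i|$: pointwise relative error is ill-posed at components
  where $D$ crosses zero.
* **Ties and determinism.** Rank indices break ties by ascending node id
  (stable); relative ranks by ascending label; friendship-network candidate
  selection by better relative PageRank, then label. Every path from a seed
  to an artifact is deterministic.

## The synthetic generator

Real encyclopedia-scale data is far beyond a test suite, so the generator
reproduces the *statistical* features the method relies on, at desk scale:

* a background of 5000 nodes wired by directed preferential attachment
  (default 5 out-stubs and 2 in-stubs per node, linear attachment), giving
  heavy-tailed in- and out-degree sequences;
* 20 "country-like" nodes each receiving in-links from 5% of the background
  — the high-centrality group;
* 10 "company-like" nodes with in-links from 0.5% of the background and
  dense intra-group direct links (each ordered pair present with
  probability 0.3, mirroring how densely real company articles cite one
  another) — the mid-centrality group;
* 10 "disease-like" nodes with only 3 in-links and 1 out-link — the
  low-centrality group, kept free of any direct company link so the orphan
  structure of the real data is preserved;
* optional planted two-hop paths company → fresh intermediaries → disease
  with no direct edge, the ground truth for hidden-link recovery. Three
  intermediaries per planting, each with out-degree one, concentrate the
  indirect flow the way a dedicated biography or subsidiary article does.

Group centrality contrasts are induced purely structurally (link counts),
not by biasing the teleportation vector, to stay faithful to the
uniform-damping model. Identical configurations (including the seed) give
byte-identical edge lists.

What the generator does **not** emulate: the real degree-distribution
exponents, article-age effects, the fine community structure of a real
hyperlink network, or its sheer size ($5\times10^6$ nodes). Passing tests on
these networks demonstrate the correctness and numerical robustness of the
machinery, not that any particular real-world ranking would be reproduced.

## Problem sizes used

The test suite and the acceptance script exercise: 20 independently seeded
5000-node layered networks with subsets of 6–40 nodes of interest for the
reduction properties and hidden-link recovery; random stochastic matrices up
to $20 \times 20$ for the sensitivity oracle (12 instances); a 12-node
planted toy for the friendship-network oracle; and the packaged 34-company
and 47-disease printed rank tables for the rank statistics. These sizes were
chosen so a full run completes in a couple of minutes while every property
is still measured at its stated tolerance.

## Design choices made where the design was open

* **Convergence thresholds.** The original analysis reports no tolerances or
  iteration counts; `tol = 1e-12` with `max_iter = 1000` makes power
  iteration at $\alpha = 0.85$ converge with margin and keeps every
  downstream property testable at $10^{-10}$.
* **Projector construction.** Only the three-component decomposition is
  named in the source analysis; the spectral-projector realisation above is
  the package's documented choice. The sum $G_R$ and the block $G_{rr}$ are
  uniquely defined regardless; only the $G_{pr}/G_{qr}$ boundary depends on
  it.
* **Hidden-link strength.** Friendship extraction uses
  $G_{rr} + G_{qrnd}$ — the self-interaction diagonal of $G_{qr}$ is
  excluded, since it carries no inter-node information. The direct flag
  consults the adjacency restricted to the subset.
* **$\kappa$** is reported as $1/\sum_{i\in r} P_i$, the ratio between the
  reduced and the restricted global PageRank normalisations.
* **Disease categories.** The packaged disease table carries the five
  clinical classes (congenital, glomerular, tubular/metabolic,
  nephrolithiasis, ciliopathies) reconstructed from the standard
  classification of these diseases; the printed source encodes them only as
  row colours. No numerical result depends on the category column.

## Known limitations

* The dense backend is quadratic in memory in the complement size; it is
  deliberately capped and exists mainly as a cross-check for the iterative
  path.
* Sensitivities are reported raw (they can be negative); classed map-style
  binning of sensitivity values is out of scope — export the table and bin
  downstream.
* The column-similarity of $G_{pr}$ is an asymptotic property of huge
  networks; at desk scale the package asserts the exact rank-one structure
  and a qualitative closeness of normalised columns to the reduced
  PageRank, not entrywise column equality.
* Weighted and multi-edge graphs, and personalised teleportation, are not
  supported.
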