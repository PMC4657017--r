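---
title: "Prioritizing disease metabolites by propagation on a multi-omics composite network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease metabolites by propagation on a multi-omics composite network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metprior)
```

## The problem

Metabolites sit at the end of the chain from genotype to phenotype: disease
processes perturb genes, the perturbation spreads through molecular
interaction networks, and the footprint shows up in metabolite levels.
Curated knowledge of *which* metabolites belong to *which* disease is thin —
a few hundred phenotype–metabolite links against thousands of phenotypes —
while gene–disease knowledge, protein interaction networks and
chemical-association databases are comparatively rich. `metprior` ranks
candidate metabolites for a phenotype of interest by exploiting that
asymmetry: it propagates a random walk from everything that *is* known about
the disease (the phenotype itself, its known genes, its known metabolites)
over a composite network that joins the gene, phenotype and metabolite
layers, and scores every candidate metabolite by the steady-state
probability of the walk.

The composite network is built from six weighted sub-networks: three
within-layer association networks ($A_{GG}$ gene–gene, $A_{PP}$
phenotype–phenotype, $A_{MM}$ metabolite–metabolite, all symmetric with
zero diagonals) and three cross-layer bipartite networks ($A_{GM}$
gene–metabolite, $A_{PG}$ phenotype–gene, $A_{PM}$ phenotype–metabolite).
Together with their transposes they form one symmetric block adjacency

$$A = \begin{pmatrix} A_{GG} & A_{PG}^{\mathsf T} & A_{GM} \\
                      A_{PG} & A_{PP} & A_{PM} \\
                      A_{GM}^{\mathsf T} & A_{PM}^{\mathsf T} & A_{MM}
      \end{pmatrix}.$$

Weights are non-negative confidence scores. The package accepts any
non-negative scale and never rescales on input — normalization happens
inside the transition matrix, so multiplying one sub-network by a positive
constant changes nothing (this is tested). The noise model (below) does
assume a 0–1 scale and warns otherwise.

## The walk

The ranking model is random walk with restart,

$$p_{k+1} = (1-\alpha)\, W p_k + \alpha\, p_0,$$

iterated until $\lVert p_{k+1}-p_k\rVert_1 < \varepsilon$. $\alpha$ is the
restart probability: the larger it is, the more the steady state
concentrates near the seeds. The fixed point can equally be obtained by the
direct solve $p = \alpha (I - (1-\alpha)W)^{-1} p_0$, implemented
independently in `solve_steady_state()` and used throughout the test suite
as the oracle against which the iteration is checked (they must agree to
$10^{-8}$ in L1).

### Transition matrix

$W$ is column stochastic: entry $(j, i)$ is the probability of stepping
from node $i$ to node $j$, and $W$ left-multiplies the probability vector
(stated this explicitly because transpose bugs in this construction are
silent). Out of each node, mass is budgeted per destination *layer* and
then spread within the destination block proportionally to edge weight.
The budgets are the jumping probabilities: out of a gene, $x$ to the
phenotype layer, $y$ to the metabolite layer, remainder $1-x-y$ to genes;
out of a phenotype, $x$ to genes, $z$ to metabolites, remainder within;
out of a metabolite, $y$ to genes, $z$ to phenotypes, remainder within.
Hence the budget constraints $x+y \le 1$, $x+z \le 1$, $y+z \le 1$.

A node often lacks edges into a budgeted block, and the published
description of this family of methods leaves the reallocation implicit.
The package fixes it with two rules, chosen to match the standard
two-network heterogeneous-walk convention and flagged here so users can
compare against other implementations:

* **R1** — the budget of a cross-layer block with no edges is reassigned
  to the node's within-layer block.
* **R2** — if the within-layer block is also empty, the mass is split
  among the present cross-layer blocks proportionally to their nominal
  budgets; if those budgets are all zero (a degenerate but legal parameter
  choice), it is split equally.

A node with no edges at all yields an all-zero column. Such dangling nodes
are kept (a candidate list must be able to contain any registered
metabolite), reported in the `"dangling"` attribute of the transition
matrix, and behave sensibly under iteration: the restart term re-injects
mass each step, an isolated node retains exactly $\alpha\, p_0(i)$, and
only in their presence is total mass not exactly conserved.

### Initial vector

Gene seeds share mass $a$ equally, phenotype seeds share $b$, metabolite
seeds share $1-a-b$. A layer without seeds donates its mass to the seeded
layers proportionally to their nominal weights, so $p_0$ always sums to 1;
if the seeded layers all have nominal weight zero the mass is split
equally among them. With a single phenotype seed this reduces to a unit
mass on the phenotype, whatever $a$ and $b$ are.

### Defaults

| parameter | default | meaning |
|---|---|---|
| $\alpha$ | 0.7 | restart probability |
| $x, y, z$ | 1/3 | layer-crossing budgets |
| $a, b$ | 1/3 | seed-layer weights (metabolites get $1-a-b$) |
| tol | $10^{-10}$ | L1 convergence threshold |
| max_iter | $10^6$ | iteration cap (reached only in pathological setups; non-convergence warns and is flagged, never silent) |

The restart probability and the seed-layer weight are configured
independently even though both are conventionally written as the method's
"importance" parameters; `parameter_sweep()` reproduces the standard
sensitivity protocol ($\alpha$ from 0.1 to 0.9, extreme assignments of
$x,y,z,a,b$) on any annotated network.

A caveat on locality worth knowing: score monotonically decaying with
distance from the seed is a restart-regime property, not a theorem for all
$\alpha$. As $\alpha \to 0$ the steady state tends to the
degree-proportional stationary distribution of the simple walk, which can
rank an interior chain node above the seed's first neighbor. The package's
locality tests therefore run at $\alpha \ge 0.5$, the regime the default
sits in.

## Significance: degree-preserving permutations

Ranks alone do not say whether a score is surprising.
`permutation_pvalues()` builds an empirical null by repeatedly (default
1000×) rewiring each of the six sub-networks with double-edge swaps —
within-layer swaps preserve every node's within-layer degree, bipartite
swaps preserve the degrees on both sides, weights travel with the edges,
and proposals creating self-loops or duplicate edges are rejected so each
sub-network stays simple. On each rewired network a random seed set of the
same per-layer sizes is drawn and the walk re-run. The p-value is the
add-one estimator $(1 + \#\{\text{null} \ge \text{observed}\})/(1 + B)$,
which never returns 0 and is exact under exchangeability. Ten attempted
swaps per edge is the (exposed) convention; the swap loop is compiled code
because it dominates the permutation runtime. Under null seeds the
p-values are uniform — the acceptance suite checks this with a
Kolmogorov–Smirnov test at the 1% level on a 200-candidate run.

## Validation: LOOCV, ROC, ablations

`loocv()` hides one known phenotype–metabolite link at a time, re-ranks
the held-out metabolite among candidates (metabolome-wide, or the held-out
metabolite plus 99 random others), and records its midrank. Three modes:

* **full** — seeds are the phenotype, its known genes, and its *other*
  known metabolites; a phenotype with a single known metabolite is seeded
  by phenotype + genes only.
* **metabolite_only** — the baseline comparator: the walk restricted to
  $A_{MM}$ with metabolite seeds only. This is the single-omics method the
  composite approach is measured against.
* **no_known_metabolites** — all phenotype–metabolite links of the target
  are removed and seeds are phenotype + genes: the cold-start scenario for
  diseases with no curated metabolites at all.

Per-fold scores are not comparable across folds (each fold ranks within
its own modified network), so the pooled ROC is built on normalized ranks
$u = (r-1)/(n-1)$, treating negatives as uniform on the rank scale; the
area under that curve is exactly the rank-sum identity implemented in
`auc_from_ranks()`,

$$\mathrm{AUC} = \frac{1}{F}\sum_{\text{folds}} \frac{n_f - r_f}{n_f - 1},$$

the Mann–Whitney probability that a held-out disease metabolite outranks a
random non-candidate. Ties use midranks, which makes the degenerate
$\alpha = 1$ point land exactly at AUC 0.5. The identity is verified
against a brute-force pairwise-comparison oracle on a thousand random fold
sets. `classwise_auc()` recomputes the same quantity per disease class.

Noise robustness follows the mixture model
$w' = (1-\sigma)\,w + \sigma\,u$, $u \sim U(0,1)$ i.i.d. per edge
(undirected edges perturbed once), with $\sigma$ the proportion of noise;
`noise_sweep()` re-runs LOOCV across a $\sigma$ grid, and $\sigma = 0$
reproduces the clean AUC bit-for-bit.

## The synthetic benchmark

Everything above is testable without downloads because
`simulate_composite()` generates composite networks with planted ground
truth. The default scenario — frozen as the package's reference
conditions — has 300 genes, 30 phenotypes and 200 metabolites;
within-layer Erdős–Rényi networks (densities 0.02 / 0.05 / 0.05) with
Beta(2, 5) confidence weights (skewed low, like database scores);
background cross-layer links (gene–metabolite density 0.03,
phenotype–gene and phenotype–metabolite 0.08); and 10 planted diseases.
Each disease is a phenotype with 6 true genes and 6 true metabolites:
phenotype–gene links of weight 1 (curated links carry weight 1, mirroring
how curated cross-layer associations are conventionally scored), dense
gene–gene and gene–metabolite module wiring with weights multiplied by
`signal_strength` 5 (capped at 1), and moderate metabolite–metabolite
wiring at *base* weights (density 0.3) — deliberately weaker, so that the
metabolite layer alone is informative but the composite layers add real
signal, which is the comparative claim the benchmark must be able to
detect. 80% of each disease's true metabolites (at least 2) are emitted as
"known" annotations; the rest stay hidden in the ground truth.

Two design points deserve explanation:

* *Background attachment is not minimal.* Each phenotype also gets random
  phenotype–gene/metabolite links (density 0.08) with ordinary Beta
  weights. With no weighted competition, the planted signal would be
  purely topological and the noise protocol — which perturbs only
  weights — would be vacuously robust. With it, part of the signal lives
  in the weights (curated 1 vs background ≈ 0.29), and the noise sweep
  shows the graded degradation it is meant to measure.
* *What the generator does not emulate:* heavy-tailed degree
  distributions (real interactomes are scale-free; the within-layer model
  is Erdős–Rényi, with the generator structured so degree-skewed models
  can be added), inter-disease module overlap, correlated measurement
  error, and database ascertainment bias. Passing benchmarks here
  demonstrates that the machinery recovers planted signal under the
  stated conditions, not that any particular AUC will transfer to real
  curated networks.

At these conditions full-mode LOOCV reaches AUC ≈ 0.99, the
metabolite-only baseline ≈ 0.79–0.90 depending on the draw, the
cold-start mode ≈ 0.97, and mean AUC decreases monotonically in $\sigma$
(the test suite averages 10 noise replicates). A no-signal configuration
(`signal_strength = 1`, module densities equal to background) sits at
chance, which is the negative control.

## Numerical and engineering choices

* Node order is genes, phenotypes, metabolites; ids are layer-scoped (the
  same string in two layers is two nodes) and sorted with radix order so
  indices are locale-independent.
* Duplicate edges on load keep the **maximum** weight — confidence-score
  semantics: two reports of the same association are the strongest
  evidence, not additive evidence. Zero-weight edges are dropped;
  self-loops are rejected.
* Ranking ties (bitwise-equal scores) break lexicographically by
  metabolite id and are flagged; evaluation uses midranks instead, so
  AUCs are tie-fair.
* Per-fold network modification is a copy of one sparse block (the
  held-out entry zeroed), asserted per fold to be absent — LOOCV cannot
  leak the test link.
* All randomness (candidate draws, rewiring, null seeds, noise,
  generation) flows through explicit integer seeds; every stochastic
  result in the package is reproducible from its arguments.
* Test-suite problem sizes: property tests run on networks of ~15–30
  nodes where the closed-form solve is the oracle; benchmark-level checks
  run the default 530-node scenario, for which a full LOOCV takes well
  under a second per fold.

## Limitations

* The transition reconstruction (R1/R2) is a documented convention, not a
  published formula; other implementations of the same idea may
  redistribute absent-block mass differently and will disagree in the
  third decimal of scores (rank agreement is typically unaffected in
  connected networks).
* Scores are probabilities on the walker's state space and depend on
  every layer's size; compare ranks, not raw scores, across networks.
* Permutation p-values are raw; no multiplicity adjustment is applied
  across candidates (`p.adjust` downstream if needed).
* The evaluation protocol treats all non-held-out candidates as
  negatives; undiscovered true metabolites depress measured AUC, as in
  any guilt-by-association benchmark.
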