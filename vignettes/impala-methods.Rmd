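---
title: "Pathway inference by Gibbs sampling: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway inference by Gibbs sampling: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impala)
```

## The problem

Protein–protein interaction (PPI) networks are undirected and condition
agnostic: they say which proteins *can* touch, not which way a signal flows
in a particular biological state. Given (i) an undirected interaction
network, (ii) a genes × samples expression matrix with two conditions (say,
treatment-sensitive vs resistant tumours), (iii) coarse subcellular
locations, and (iv) declared source genes (membrane receptors) and target
genes (transcription factors), `impala` reconstructs *directed, linear
signal-transduction pathways* from sources to targets, quantifies the
direction of every interaction as a Bernoulli probability, and organises
the sampled pathway ensemble into modules with crosstalk genes.

## The model

A candidate pathway is an ordered vector of genes
$\theta = (\theta_1, \dots, \theta_L)$ with $\theta_1$ a source, $\theta_L$
a target, consecutive genes adjacent in the network, and no repeats. Its
energy is additive over three potentials:

$$U(\theta; X) = w_1 \sum_{i=1}^{L} V_1(\theta_i; X)
  + w_2 \sum_{i=1}^{L-1} V_2(\theta_i, \theta_{i+1}; X)
  + w_3\, V_3(\theta),$$

with $w_1 = w_2 = w_3 = 1$ by default. Pathways are sampled from the
Boltzmann distribution $P(\theta) = \exp(U(\theta)/T)/Z$; the temperature
$T$ (default 1) sharpens ($T < 1$) or flattens ($T > 1$) the landscape.
Higher energy means a more *supported* pathway: more aberrant expression,
tighter co-expression, better compartment flow.

### The three potentials

The exact functional forms are this package's own instantiations (the
published description fixes only what each potential measures), isolated
behind `build_potential_tables()` so they can be swapped:

* **V1, differential expression** (`gene_potential()`): the absolute
  z-score of the Welch two-sample $t$ statistic, mapped through the
  two-sided p-value ($z = \Phi^{-1}(1 - p/2)$). Welch is used over the
  pooled-variance $t$ for robustness to unequal group variances; the
  absolute value is taken because both up- and down-regulated genes mark
  aberrant signalling. P-values are floored at `cap_p` ($10^{-16}$), so a
  zero-variance contrast yields a large finite score rather than infinity.
* **V2, co-expression** (`edge_potential()`): the significance z of the
  Pearson correlation over all $m$ samples via Fisher's transform,
  $|\mathrm{atanh}(r)|\sqrt{m-3}$, capped at the z equivalent of `cap_p`.
  Fisher's z is the canonical significance scale for a correlation;
  it needs $m \ge 4$.
* **V3, location flow** (`flow_potential()`): $\lambda$ times the fraction
  of consecutive transitions concordant with the compartment order
  membrane (1) → cytoplasm (2) → nucleus (3); a transition is concordant
  when the rank does not decrease, and genes with unknown/`other` location
  match anything. $\lambda$ defaults to the mean nonzero V1 score so the
  flow prior is commensurate with one typical node term — a deliberately
  mild prior: it rewards plausible membrane-to-nucleus flow without being
  able to overrule strong expression evidence.

Genes present in the network but absent from the expression matrix score 0
for V1 and V2 (neutral), keeping the landscape connected instead of
punching holes in it.

## Sampling

For each (source, target, length) the candidate landscape is the
source-centered `radius`-step subnetwork (`extract_subnetwork()`; default
radius 2, the scale at which receptor-centered subnetworks are usually
drawn) with per-position domains $\Omega_i$: position $i$ may hold genes
within $i-1$ steps of the source *and* $L-i$ steps of the target
(`candidate_domains()`); the pinned endpoints are excluded from interior
domains. This prunes genes that can never sit on a connected completion.

`run_chain()` performs systematic-scan Gibbs sweeps: positions
$2 \dots L-1$ are resampled in order from the exact full conditional —
candidates are the genes adjacent to both current neighbours, inside
$\Omega_i$, not already on the path (the incumbent stays eligible),
weighted by $\exp\{(V_1 + V_2(\mathrm{prev},g) + V_2(g,\mathrm{next}) +
\Delta V_3)/T\}$. One pathway sample is recorded per post-burn-in sweep
(default burn-in fraction 0.2, no thinning: the edge-probability estimator
is a sample average, and autocorrelation affects its variance, not its
bias). The starting path is drawn *uniformly* over all domain-respecting
simple paths by dynamic-programming walk counts plus rejection of
non-simple walks.

**Multiple chains.** Single-site updates cannot jump between pathway
families that share no genes: the move graph over path space can be
disconnected, and one chain then explores a single component forever. The
orchestrator `run_gist()` therefore splits the total budget of 10,000
sweeps across 32 independent, uniformly initialised chains per (source,
target, length, direction) and pools them — the same merge used to pool
lengths and source/target pairs. `run_chain()` itself remains one honest
chain, and the exact-oracle tests run it that way.

**Forward/reverse search and edge directions.** Reverse chains sample the
transposed problem (target → source, compartment order reversed). Each
undirected interaction seen in any sample is modelled as a Bernoulli
orientation: $p^*_{i,j} = n_{i\to j} / (n_{i\to j} + n_{j\to i})$ with
reverse-chain samples flipped back before counting
(`estimate_edge_probabilities()`); $p^*_{i,j} + p^*_{j,i} = 1$, and 0.5
means no directional confidence. The combination rule (pooling counts) is
this package's choice — the published account estimates both orientations
but does not state how they are merged — and is recorded in the output
metadata. The consensus network (`consensus_network()`) collapses the
`top_k = 200` distinct pathways by sampling count (ties: higher energy,
then lexicographic order, for reproducibility), annotating genes with
sampling frequency.

**Exact oracle.** `enumerate_exact()` enumerates all simple length-$L$
paths by DFS (capped, default 10,000), computes exact Boltzmann
probabilities with a max-shift, and derives exact edge-orientation
probabilities by summing path mass. It exists so the sampler can be tested
against ground truth on small instances; the full problem is NP-hard,
which is the reason for sampling in the first place.

### Known sampling limitations

* On landscapes whose single-site move graph is disconnected, a single
  chain is *provably* unable to represent the full Boltzmann law; multiple
  chains mitigate but do not eliminate this. The oracle-equivalence tests
  therefore verify ergodicity (via the enumeration oracle) before
  comparing distributions, and the reducibility risk is the stated reason
  for the multi-chain default.
* The binomial error model for $p^*_{i,j}$ ignores within-chain
  autocorrelation; the true standard error of an edge probability from one
  chain is 1.3–2× binomial. Tests that assert 3-binomial-sigma agreement
  on ~80 simultaneous edges occasionally see a ~3.7σ deviation from a
  perfectly correct sampler (verified: 8× more sweeps shrinks it to
  1.9σ). Total-variation agreement of the full pathway distribution is
  the stronger and more stable check.

## Module discovery

SOUL post-processes the pooled samples. Distinct pathways (canonically
ordered, so results are input-order invariant) are clustered by average
linkage on $1 - \mathrm{Jaccard}$ of gene sets (`cluster_pathways()`;
gene-set similarity is used because pathway membership, not wiring, is
what modules share). The dendrogram's leaves are deterministically
reordered with the lighter subtree first, the sampling frequencies are
laid out in leaf order (`reorder_frequency_landscape()`), smoothed with a
centered moving average (window 5, reflection-padded so the series ends
are not over-weighted), and local maxima with topographic prominence
$\ge$ 10% of the smoothed maximum become module seeds
(`detect_modules()`). With $k$ kept peaks, the landscape is cut at the
$k-1$ junctions where adjacent leaves have the largest cophenetic
distance — the deepest cluster splits — rather than at smoothed frequency
minima: smoothing blurs mass across block boundaries by up to half a
window, and frequency-valley cuts misassign 1–3 pathways per boundary,
which destroys exact crosstalk recovery. Every distinct pathway lands in
exactly one module; genes in $\ge 2$ modules form the crosstalk table
(`crosstalk()`).

Peak-calling parameters (window, prominence) are exposed because the
published account gives none. A practical limitation: when module masses
are very lopsided (lightest below ~1/8 of the heaviest), the lightest
module's hump falls under the default 10% prominence bar — lower
`min_prominence` in that regime.

## The synthetic benchmark

`simulate_network()` plants `n_paths` directed source→target paths. Every
intermediate gene carries a global random depth and path interiors are
laid out in depth order, so the planted edge set is orientation-consistent
(no interaction planted both ways, and *any* path through true edges
respects the true directions). Type I uses one source/target pair
(alternative routes; intermediates disjoint by default, shared when an
`intermediate_pool` is set); type II uses several sources/targets with a
shared pool and a construction guarantee that at least one gene is shared
by two paths (crosstalk). Direction is stripped for the observed network;
`round(phi * n_true)` uniformly random decoy interactions are added (never
duplicating a true one). Locations follow flow: sources membrane,
interiors cytoplasm, targets nucleus, decoys random.

`simulate_expression()` gives true genes a latent signal propagated along
the planted paths (`child = 0.8 * mean(parents) + sqrt(1-0.8^2) * innovation`,
unit variance, so adjacent true genes correlate at about
`0.8/(1+sigma2)`), plus a per-gene fixed-sign mean shift of `effect_size`
(default 1) in condition B, plus N(0, `sigma2`) noise; `sigma2` is the
noise-to-signal variance ratio. The two equal-sized groups share latent
draws by within-group sample index (a paired design), so at `sigma2 = 0`
every true gene's group mean difference equals the effect size *exactly* —
the noiseless world is exactly solvable, which is what a perfect-recovery
test needs. Decoy genes get independent noise only.

The reference scale (~260 genes, ~1000 interactions at `phi = 0.3`) is met
with 250 planted type I paths of length 4–6 over a 158-gene pool plus 100
decoy genes. Defaults for what the published protocol does not state —
effect size 1, 20 samples per group, decay 0.8 — were fixed once as
plausible for two-condition tumour cohorts.

**What a green benchmark does and does not establish.** The generator
produces exactly solvable worlds with honest degradation along the
false-interaction axis: gene and edge precision fall monotonically in
`phi`. It does *not* reproduce every degradation of real data: because
noise rescales all correlations — true edges and the dominant error
source, decoy shortcuts between latently correlated true genes — by the
same factor, edge-identification precision is nearly invariant in
`sigma2` in this world (gene precision does decrease). Real expression
data, where effect sizes are heterogeneous and much weaker, would not
show this invariance. The corresponding acceptance assertion is left
failing rather than papering over it by re-tuning the generator after the
fact; the analysis lives in the decisions ledger.

Evaluation: gene identification is scored on the consensus network's
nodes; edge identification on *all* pooled direction probabilities at the
call threshold `p* >= 0.6` (the Bernoulli-direction reading; the top-200
consensus is a visualization). A correct pair called in the wrong
orientation is a false positive and leaves the true orientation a false
negative.

## Numerical and degenerate-input choices

* Boltzmann weights are computed with a max-shift; probabilities sum to 1
  within 1e-12 and are invariant to energy offsets.
* Zero-variance genes: V1 = 0 when means agree, capped maximum otherwise;
  constant genes score V2 = 0 against everything.
* Infeasible (source, target, length) combinations raise a typed
  condition (`impala_infeasible`); `run_gist()` skips and logs them.
* All logging flows through `message()` with no wall-clock content, so
  two runs with one seed are byte-identical — including GraphML/TSV/JSON
  artifacts (numeric fields are serialized with round-trip-exact
  precision).
* SOUL clusters distinct pathways (weighted by counts), not raw samples;
  with one distinct pathway the clustering degenerates gracefully to a
  single leaf.

## Reproducibility

Every source of randomness flows from explicit seeds: `run_gist()` seeds
once and consumes one RNG stream (the compiled sweep kernel uses R's own
RNG), `simulate_network()`/`simulate_expression()` derive their streams
from the scenario seed, and the CLI exposes `--seed` everywhere. Identical
configuration + seed gives bitwise-identical sample sets, edge tables and
files.
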