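---
title: "Edge-centric network control: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric network control: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enct)
```

# The problem

Network control theory treats a parcellated brain as a linear dynamical
system wired by the structural connectome: regional activity `x(t)`
evolves under `x(t+1) = A x(t) + B u(t)` (or its continuous analogue),
and "controllability" quantifies how much a given element, receiving
input through `B`, can steer state transitions. The conventional
formulation controls *nodes*. `enct` moves the same machinery to
*edges*: the connectome is mapped to its weighted line graph, whose
nodes are the original network's connections, and controllability and
control energy are computed there. This gives every white-matter
connection — not just every region — a role in driving dynamics, and it
makes within- versus between-network contributions separable, because
edges (unlike nodes) belong unambiguously to a pair of canonical
networks.

# From connectome to edge network

A subject's connectome enters as a symmetric nonnegative `N × N` matrix
with zero diagonal. Weights below the **absence threshold** (default
0.001) are zeroed on load: deterministic tractography produces tiny
nonzero values for region pairs that are best treated as unconnected.

The transform runs through the incidence matrix. With edges enumerated
in row-major upper-triangular order (`(1,2), (1,3), …`), the `N × L`
incidence matrix carries `√w_α` in the two endpoint rows of each edge
column. Two conventions needed fixing here, and both are resolved by
requiring algebraic consistency:

* **Square-root entries.** With entries `√w_α`, the incidence matrix
  satisfies `C Cᵀ = A + D` exactly, where `D` is the diagonal matrix of
  weighted strengths `dᵢ = Σⱼ A_ij`. Any other power of the weight
  breaks this identity, so we treat the identity as the definition. The
  test suite asserts it to `1e−10` on random connectomes.
* **Zero diagonal of the edge adjacency.** `CᵀC` has diagonal `2w_α`,
  while a line-graph *adjacency* should have none; the two natural
  formulas for the edge network differ exactly there. We zero the
  diagonal, because every downstream computation (controllability,
  energy) expects an adjacency matrix with no self-loops, matching the
  node-level convention.

Off the diagonal, `A_E[α, β] = √(w_α w_β)` when edges α and β share
exactly one endpoint, else 0.

**Cross-subject alignment.** Different subjects have different edge
supports. Edge-level feature vectors are aligned on the *full*
`N(N−1)/2` upper-triangle index (7140 features for `N = 120`), with
value 0 for pairs absent in a subject (`align_edge_features()`, with an
`NA` option for analyses that prefer explicit missingness). Whether one
should line-graph all node pairs or only present edges is a genuine
modeling choice; we build the line graph on present edges only — absent
edges have no dynamics to control — and push the alignment to the
feature stage.

Isolated nodes are legal; they simply contribute no edges.

# Controllability

Both measures operate on the stabilized matrix `A / (1 + λ_max)`
(spectral radius < 1), the standard normalization that makes the
discrete dynamics stable and the Gramian series convergent. The raw
matrices themselves (nonnegative, symmetric) are never stable, so some
normalization is unavoidable; dividing by `1 + λ_max` is the one used
throughout the node-controllability literature, and we apply it
identically at node and edge level. The factor is recorded in every
`controllability_profile`.

**Average controllability** of element *k* is `Trace(W_K)` with
`B = e_k` (a single control input, mirroring the `L × 1` input matrix
of the edge formulation). We solve the discrete Lyapunov equation
`W − A W Aᵀ = B Bᵀ` in the eigenbasis of the symmetric system matrix,
which reduces to `Trace(W_K) = Σᵢ V[k,i]² / (1 − λᵢ²)` — exact, and
O(M³) once for all elements. The truncated series `Σ_τ ‖Aᵗ e_k‖²`
(τ ≤ 10⁴) serves as an independent oracle in the tests, agreeing to
`1e−8`. A multi-element control set is supported (`control_set=`);
its trace is the sum of the members' single-element traces.

**Modal controllability** is `φ_k = Σⱼ (1 − λⱼ²) v_kj²`. Under
eigenvalue degeneracy the eigenvectors are not unique, but φ is: only
sums of squared coordinates over an orthonormal basis of each
eigenspace enter, which are rotation-invariant. For nonnegative
matrices the stabilized spectrum lies in (−1, 1), so `φ ∈ [0, 1]` up to
round-off, and `Σφ = M − trace(A²)` exactly (asserted to `1e−10`).

The suite also checks two qualitative properties on synthetic
connectomes: eAC and eMC are negatively correlated across edges, and
node controllability correlates positively with the node-mean of edge
controllability (`node_mean_edge_values()`), i.e. the edge measures are
consistent with the node picture when summarized back to nodes.

# Control energy

Activation tasks are posed in continuous time: from the resting
baseline `x(0) = 0`, reach a target with 1 on the activated edges and 0
elsewhere, minimizing `∫ (x_T − x)ᵀ(x_T − x) + ρ uᵀu dt`. Note the
objective is quadratic tracking plus input energy; the reported
"energy" is the input term `Σ_k ∫ u_k² dt` alone, following the field's
convention of calling the optimal input's size the transition energy.

The Pontryagin conditions give a linear state/costate system

```
dx/dt =  A x − B Bᵀ p / (2ρ)
dp/dt = −2 x − Aᵀ p + 2 x_T,      u* = −Bᵀ p / (2ρ)
```

which we solve in closed form: the augmented `(x, p, 1)` generator is
exponentiated once for the horizon (to find `p(0)` by a linear solve
enforcing `x(T) = x_T`) and once for the step (to propagate the
trajectory on the grid). If the boundary solve is ill-conditioned
(reciprocal condition < 1e−12), a least-squares costate is used with a
warning — this is the "target unreachable in this geometry" escape
hatch. The relative terminal error is always computed and warned about
above `1e−4`.

Numerical settings, all configurable:

* horizon `T = 1` with `n_steps = 1000` (step 0.001), the conventional
  grid for this task;
* `ρ = 1` — the literature states only ρ > 0;
* energies by trapezoidal quadrature of `u_k²` on the grid;
* continuous stabilization `A/(1 + λ_max) − I`, the standard choice
  that makes the uncontrolled dynamics decay; both the rescale and the
  shift can be disabled.
* the control set `B` defaults to the identity (every edge can receive
  input); any mask is accepted.

Tests validate the solver against a fully independent oracle: the same
boundary-value problem integrated with an adaptive ODE solver
(`deSolve`) and linear shooting, agreeing on the energy to `1e−6`
relative; re-simulating the returned `u*` forward reaches the target to
`1e−4` relative; and energy scales exactly quadratically in the target.

`network_activation_energy()` divides total energy by the number of
target edges, so canonical network pairs of different sizes are
comparable; `decompose_energy_by_pairs()` splits per-edge energies over
the `K(K+1)/2` within/between network pairs (28 for seven canonical
networks), summing exactly to the total.

# Null models

`rewire_null()` implements a weight/degree/strength-preserving
surrogate in two stages: (1) Maslov–Sneppen double-edge swaps of the
binary topology (via `igraph::rewire`, default 10 attempted swaps per
edge — a conventional budget; the exact count is not critical and is
configurable), which preserve the binary degree sequence exactly; (2)
rank-matched weight reassignment — surrogate edges are scored by the
product of their endpoints' original strengths and receive the sorted
original weights in matching rank order. The weight multiset is thus
preserved exactly and nodal strengths approximately (correlation with
the original > 0.9 on 60-node synthetic connectomes in the suite).
Graphs too small to swap fall back to a weight reshuffle with a
warning; graphs with no legal swap (e.g. a complete triangle) come back
unchanged, which is the correct degenerate behavior.

`null_pvalues()` compares any statistic of the empirical connectome
(typically the group average) against the ensemble, default 5000
draws, with the permutation convention
`p = (1 + #extreme) / (1 + n_nulls)` — the pseudo-count keeps p away
from exactly 0 — and two-sided p as twice the smaller one-sided value,
capped at 1. With a statistic independent of topology the p-values are
uniform (KS-checked in the suite). FDR correction is Benjamini–Hochberg
(`fdr_bh()`, wrapping `p.adjust`).

# Connectome-based predictive modeling

The CPM protocol is deliberately plain: per fold, features are selected
by Pearson correlation with the phenotype at `p < 0.01` (two-sided —
the sidedness is a choice; two-sided is the safer default), split into
positive and negative masks, summed into a single score (default:
positive sum minus negative sum; positive-only and negative-only modes
exist, and the positive mask is the natural input for downstream
energy analyses of a predictive network), and a one-variable linear
regression maps score to phenotype for the held-out fold. Ten folds,
default 1000 repeats.

Fold splits are a pure function of `(seed, repeat index)`, so the same
splits can be replayed for different feature sets and compared pairwise:
`cpm_compare()` returns the proportion of repeats where one feature
set's performance fails to beat the other's. Leakage is structurally
impossible — selection and fitting see training rows only — and a test
verifies that perturbing a held-out fold's phenotypes leaves its
predictions bit-identical. Folds where nothing passes selection predict
the training mean and are counted.

# Synthetic data

The generator exists so every stage is testable without imaging data,
and its defaults mirror a realistic parcellated structural connectome:

* `n_nodes = 120` over `n_networks = 7` contiguous blocks (an
  AAL2-scale parcellation over the canonical resting-state systems);
* within-block edge probability 0.6, between-block 0.2 — overall
  density ≈ 0.26, in the range of deterministic-tractography
  connectomes after thresholding;
* log-normal weights (`meanlog = −2`, `sdlog = 0.8`): positive,
  right-skewed, median ≈ 0.135, emulating quantitative-anisotropy-like
  edge strengths; the absence threshold 0.001 is applied exactly as on
  real data;
* cohorts share the group topology with mean-one multiplicative
  log-normal subject noise (sd 0.2 on the log scale), so the cohort
  mean converges to the group matrix;
* `generate_edge_features()` produces feature matrices in which a
  designated signal subnetwork covaries across subjects through a
  shared latent factor (pairwise correlation 0.3 by default). This is
  the feature of real data that makes CPM work at all: with mutually
  independent features, 50 signal edges at a total R² of 0.5 each carry
  a population correlation of ~0.1 with the phenotype — below any
  sensible selection threshold — and no summary-score method can
  recover the signal. Phenotype-relevant edges in real connectomes
  covary (they are a subnetwork of the same brains), and the latent
  factor emulates exactly that;
* `generate_phenotype()` plants a linear signal on chosen edges and
  scales the noise to a requested population R².

What the generator does **not** emulate: spatial embedding and
distance-dependent connection probability, hub/rich-club topology
beyond what blocks induce, heteroscedastic measurement noise, site or
motion confounds, and non-linear brain–behavior relations. Passing
tests on these fixtures therefore demonstrates correctness of the
computations and calibration of the inference under a known model — not
that any particular empirical effect will appear in real data.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen
so the full suite completes in a couple of minutes: random connectomes
up to N = 60 for identity checks, N ≤ 20 for exhaustive line-graph
oracle comparisons, systems up to M = 50 for Gramian-series
comparisons, a 6-edge ring for the ODE-oracle energy checks (with 5000
grid steps where `1e−6` agreement is asserted), 200 null draws, and CPM
at 300 subjects × 1000 features × 100 repeats. All of these are
parameters, not limits; the same code runs a 120-node connectome's
7140-feature pipeline unchanged, with the energy solver the only
expensive stage (its matrix exponential is O((2L)³)).

# Known limitations

* Undirected, nonnegative connectomes only; no signed or directed edge
  networks, no hypergraphs.
* The energy solver's dense matrix exponential limits it to a few
  thousand edges in practice.
* Strength preservation in the null model is approximate by design;
  analyses where exact strength sequences matter need a different
  surrogate family.
* The CPM implementation covers the linear summary-score protocol;
  kernel or confound-adjusted variants are out of scope.
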