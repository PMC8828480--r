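---
title: "Directed fate mapping with velofate: models, parameters and design choices"
author: "velofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed fate mapping with velofate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velofate)
```

## The problem

Single-cell RNA sequencing destroys cells on measurement, so lineage
relationships must be reconstructed computationally. Similarity-based
pseudotime methods recover the *shape* of a differentiation trajectory but
not its *direction*; velocity estimates (from spliced/unspliced mRNA
ratios or any comparable vector field) supply direction, but only locally,
one noisy cell at a time. velofate combines the two: a Markov chain over
the observed cells whose support is the expression-similarity KNN graph
and whose edge weights are set by how well each neighbour lies along the
cell's velocity vector. Aggregating many short, noisy, local steps into
the long-run behaviour of the chain yields global statements: which
populations are initial, terminal or intermediate, and with what
probability each single cell will reach each terminal population.

## Model assumptions

The chain model assumes (i) state changes are gradual, so consecutive
states are transcriptomically similar and the sampled cells cover the
trajectory without gaps; (ii) dynamics are memoryless at the population
level; (iii) the velocity field approximates the expression derivative
well enough, for enough cells, to set the overall direction of flow — not
necessarily for every gene in every cell, since transitions are
stochastic, manifold-constrained and uncertainty-aware. Where velocities
are systematically biased, fate probabilities inherit the bias.

## Stage by stage

**Graph.** Expression is centred (optionally scaled; off by default since
log-normalized input is already variance-stabilized) and projected onto
`L = 30` principal components by exact SVD, with the per-component sign
fixed so results are bit-reproducible. Euclidean `K = 30` nearest
neighbours are union-symmetrized, so every cell has at least K neighbours;
distance ties break by ascending cell index. Similarities use a fuzzy
local-scaling kernel (per-cell shift to the nearest-neighbour distance,
smooth-k normalized bandwidth, t-conorm symmetrization a + b − ab) or an
adaptive-bandwidth Gaussian kernel symmetrized by the mean. One honest
caveat: after symmetrization the similarity of an edge mixes *both* cells'
local scales, so within one cell's neighbourhood the symmetrized
similarity is not strictly monotone in distance (the directed, pre-
symmetrization kernel is). An optional density normalization
W′ = D⁻¹WD⁻¹ discounts edges into dense regions; it is off by default.

**Velocity kernel.** Correlations between the velocity vector and the
state-change vectors towards neighbours are softmax-transformed with
inverse temperature σ estimated once as 1/median|c| — after scaling, the
median absolute correlation is exactly 1, which upscales weakly aligned
datasets. Genes without velocity estimates are dropped from the
correlations (a gene present in expression but with almost no unspliced
signal carries no directional evidence); zero-variance velocity vectors
fall back to a uniform row with a warning, and a fully degenerate field
yields the uniform chain rather than an error so that reversal-based
workflows still compose. The backward chain simply negates every velocity
vector.

**Uncertainty.** Each cell's velocity is modelled as Gaussian with
diagonal covariance, with moments estimated over the cell and its
neighbours (including the cell itself stabilizes sparse neighbourhoods;
population variances are clipped at zero). The default "stochastic" mode
computes the expected transition row analytically via a second-order
Taylor expansion whose diagonal Hessian terms are derived in closed form
and verified against central finite differences (step 3 × 10⁻⁴, chosen
where truncation and roundoff balance). The correction can leave the
simplex, so negatives are clipped and the row renormalized; a non-finite
correction falls back to the deterministic row. The expansion is accurate
when the velocity magnitude dominates its neighbourhood spread; near
attractors, where the mean velocity vanishes, the analytic and
Monte-Carlo modes can genuinely disagree — the sampling mode
(`nSamples = 1000` by default, seeded) is the arbiter there. σ is
estimated once, from the correlations at the neighbourhood mean velocity,
and shared across modes; re-estimating per Monte-Carlo draw would make σ
itself random without changing its scale.

**Combination.** P = (1 − λ)P_velocity + λP_similarity with λ = 0.2:
enough similarity mass to keep the chain irreducible on a connected graph
and to buffer noisy velocities, little enough that direction still comes
from the field.

**Coarse-graining (GPCCA).** Eigenvectors of a nonreversible chain are
complex, so macrostates are built on a *real Schur* basis instead. The
dense path (default, for chains up to a few thousand states) computes a
full real Schur decomposition and reorders diagonal blocks by descending
real part (or modulus, for cyclic dynamics) using orthogonal
Sylvester-based block exchanges, moving only the leading blocks; 2 × 2
complex-conjugate blocks are never split — requesting a splitting
dimension is an error naming the valid neighbours. An ARPACK-based Krylov
path serves larger, sparser problems; note ARPACK cannot separate exactly
degenerate eigenvalue clusters from a single starting vector, so the
dense path is preferred at desk scale. Because the Perron eigenvector of
a row-stochastic matrix is exactly constant, the first basis vector is
pinned to it whenever the leading eigenvalue is within 10⁻⁶ of 1 —
clustered leading eigenvalues otherwise hand back ill-conditioned
mixtures.

The rotation A is initialized by a greedy inner-simplex vertex search
(the row farthest from the origin, then repeatedly the row farthest from
the span of the chosen vertices, inverted), and optimized by Nelder–Mead
over its (n&#8347; − 1)² free entries; the constrained first row and column
are rebuilt after every evaluation, which also rescales the memberships
onto the feasible set (non-negative rows summing to one, clipped at
10⁻¹² noise level). The objective is shifted by +1 internally because it
approaches 0 on crisp chains, where a relative stopping rule would never
fire; with one free parameter, golden-section search replaces
Nelder–Mead. Model selection offers the eigengap heuristic (ties towards
fewer states), a crispness scan (candidates whose coarse-grained matrix
leaves the feasible region score out rather than aborting the scan), and
a minChi prefilter (|minChi| ≤ 0.05) before the scan; one sorted
decomposition at the top of the candidate range is truncated per
candidate. Weights D default to uniform: no presumption about the cell
distribution.

**Classification.** Stability index = diag(P_c); terminal iff
SI ≥ 0.96 (overridable, and specific macrostates can be promoted
manually — rare populations are often picked up as macrostates yet sit
just below threshold). Initial states take the smallest coarse-grained
stationary mass among non-terminal, non-outlier macrostates (ties break
by index, with a warning). The stationary distribution is a direct sparse
solve of πᵀP = πᵀ; disconnected graph components are excluded as
outliers first, and a weakly connected chain with a single recurrent
class is handled by solving on that class and padding with zeros.

**Fate probabilities.** For each selected macrostate the f = 30
highest-membership cells form its terminal index set; a cell ranked into
two sets goes to the higher membership and the loser backfills, via one
greedy pass over all memberships in decreasing order. Those rows become
self-loops and (I − Q)a_t = s_t is solved by sparse LU (one
factorization, all right-hand sides; absorption towards individual target
cells aggregates by linearity). A restarted, Jacobi-preconditioned GMRES
path (relative residual 10⁻⁸) is the iterative alternative and agrees
with the direct path to 10⁻⁶ in tests. Unreachable transient cells are
reported by index before any solve. A compiled random-walk oracle
(first-hit frequencies over seeded walks) provides the independent check
at small scale.

**Downstream.** Circular embeddings place lineages evenly on the unit
circle, ordered to maximize adjacent-column cosine similarity
(exhaustive over circular permutations up to 8 lineages with reflections
deduplicated, greedy insertion beyond), and each cell at the
fate-weighted vertex average. Priming uses natural-log entropy and KL
divergence from the mean fate distribution (0·ln 0 := 0). Driver genes
rank by Pearson correlation with a lineage's fate column, optionally
restricted to clusters where the decision occurs; zero-variance genes are
flagged undefined and ranked last.

**Trends.** Expression along pseudotime is fitted per gene by weighted
penalized regression on a cubic B-spline basis: 8 interior knots at
weighted pseudotime quantiles, a ridge penalty on *second divided
differences over the Greville abscissae* — whose null space is exactly
the linear functions, so linear signals are reproduced to numerical
precision at any penalty — selected by generalized cross-validation over
a fixed log-spaced grid (10⁻⁸…10⁴, half-decade steps). The fixed grid
makes the fit exactly equivariant under affine rescaling of the response.
Only cells with positive lineage weight enter the fit; weights below 0.01
are clipped *up* to 0.01 for trend fitting only, so early cells still
inform rare lineages. Predictions are made at 200 equally spaced points
spanning the contributing cells' pseudotime range. The uncertainty band
follows the residual-s.d. formula with n = number of *test points*, kept
verbatim for comparability even though the conventional choice is the
number of fitted cells (available via `bandN = "cells"`). Trend
clustering z-transforms the smoothed curves, projects onto up to 50 PCs,
builds a gene-gene KNN graph and runs seeded Louvain community detection
(resolution 0.2 by default, to avoid over-clustering).

## What the generators emulate — and what they do not

`simulateBranchingField()` draws cells along cubic Bézier curves in a
low-dimensional latent space embedded into gene space by a random
orthonormal map: a shared root from the planted source, bifurcating into
branches whose speed decays as (1 − s)² into the attractors, with control
points clustered at the source and the ends so cells pile up there — the
spatial signature of initial and terminal populations. Expression and
velocity receive additive Gaussian noise (s.d. 0.05 by default, a small
fraction of the O(1) curve scale — in the regime where velocity direction
is informative but individual vectors are visibly noisy). Defaults are
1,000 cells, 20 genes, 2 branches. `simulatePlantedChain()` builds
within-block-uniform chains with a prescribed leak and topology,
deterministically. `simulateTrendFamilies()` draws genes from linear /
sigmoid / transient-peak templates with amplitude jitter.

These fixtures plant exactly the structure the method assumes, so passing
tests demonstrate correctness of the machinery — sorted Schur bases,
rotation optimization, absorption algebra, trend recovery — not
robustness to everything real data does: no count noise or dropout, no
batch structure, no doublets, no systematically biased velocities, no
cell-cycle confounding, and clean, well-separated attractors. Problem
sizes in the tests (hundreds of states for oracle comparisons, 1,000
cells for end-to-end runs, 10 seeds for the recovery study) were chosen
as the smallest at which the planted structure is unambiguous.

## Numerical choices, in one place

Row-stochasticity enforced to 10⁻¹⁰; membership clipping at 10⁻¹²
noise with a hard error only below −10⁻⁴ in the coarse-grained matrix
(macrostate overlap beyond numerical precision means the number of
macrostates is wrong); Schur invariance residual warned above
10⁻⁶‖P‖_F; Sylvester exchanges refused (and order kept) when the
Kronecker system's reciprocal condition falls under 10⁻¹²;
finite-difference step 3 × 10⁻⁴; GMRES restart 100; KNN ties and CGSD
ties break by ascending index; duplicate points are legal and receive
the maximal similarity of their neighbourhood.

## Known limitations

The dense Schur path scales cubically and is intended for up to a few
thousand cells; the analytic uncertainty mode loses accuracy at
low velocity signal-to-noise (by construction of the Taylor expansion);
no automatic tuning of the terminal stability threshold is attempted;
fate probabilities towards *intermediate* macrostates are supported but
all selected sets are absorbed jointly, so probabilities are conditional
on that joint absorption; and the KL priming score is infinite for cells
with mass on a lineage absent from the dataset mean — mathematically
correct and reported as `Inf`.
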