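---
title: "The redundancy bottleneck: model, algorithm, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The redundancy bottleneck: model, algorithm, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbottleneck)
```

## The problem

Given a discrete target variable $Y$ with full-support marginal $p_Y$ and $n$
source channels $p_{X_s|Y}$, partial information decomposition asks how much
of the information the sources carry about $Y$ is *redundant* — available
from every source individually. Blackwell redundancy formalizes this as the
most informative variable $Q$ that is a stochastic garbling of each source
channel:
$$ I_\cap = \max_Q I(Q;Y) \quad \text{s.t.} \quad p_{Q|Y} = \kappa_s \circ p_{X_s|Y} \ \ \forall s $$
for some row-stochastic $\kappa_s$. This package implements an equivalent
*bottleneck* formulation. Pool the sources into one joint distribution over
$(Y, S, Z)$, where $S$ is the index of the source (drawn from fixed
full-support weights $\nu_S$, independently of $Y$) and $Z$ is the pooled
outcome, living on the union of the source alphabets:
$$ p(y,s,z) = p_Y(y)\, \nu_S(s)\, p_{X_s|Y}(z\,|\,y) \ \ \text{for } z \in \mathcal X_s. $$
By construction $I(Y;S) = 0$; `build_joint()` enforces and tests this. A
bottleneck variable $Q$ with Markov structure $Q - (Z,S) - Y$, i.e. a channel
$r(q\,|\,s,z)$ on the supported $(s,z)$ pairs, is then scored by two terms:

* **prediction** $I(Q;Y|S)$ — information extracted about the target;
* **compression** $I(Q;S|Y)$ — leakage about *which source* provided it.

The redundancy bottleneck value at rate $R$ is
$I_{RB}(R) = \max I(Q;Y|S)$ subject to $I(Q;S|Y) \le R$. At $R = 0$ this
equals $I_\cap$; it is non-decreasing and concave in $R$ and capped by
$\sum_s \nu_S(s) I(X_s;Y)$ (reached by $Q = Z$), while rates beyond
$I(Z;S|Y)$ change nothing (`prediction_bound()`, `rate_bound()`). Because
$Q$ conditions jointly on $(s,z)$, nothing depends on how source outcomes are
labeled; shared labels only change the *pooled* quantities such as
`rate_bound()`, never the optimal tradeoff points.

Both terms decompose exactly over sources through the specific conditional
mutual informations $I(Q;Y|S{=}s)$ and $I(Q;S{=}s|Y)$, weighted by
$\nu_S$; these per-source traces (`per_source_curves()`) may individually be
non-monotonic and non-concave — only the averaged frontier is guaranteed
concave. Each source's compression share is bounded below by the KL-weighted
deficiency between its channel and the induced bottleneck channel
$p_{Q|Y}$ (`deficiency()`, `bottleneck_target_channel()`).

## The alternating algorithm

`solve_rb()` maximizes the Lagrangian relaxation
$$ F(\beta) = \max_r\; I(Q;Y|S) - \tfrac1\beta\, I(Q;S|Y), $$
or, by default, the *exponential* variant with penalty
$e^{I(Q;S|Y)}/\beta$: benchmark systems like the AND gate have frontiers
that are not strictly concave, where the linear Lagrangian can only land on
extreme points. Introducing a variational joint $\omega$ over $(Y,S,Z,Q)$
decouples the objective; the two block updates are closed-form:

1. $\omega \leftarrow p_{YSZ}\, r$ (the induced joint), and
2. $r(q\,|\,s,z) \propto \exp \sum_y p(y\,|\,s,z)\big[\beta_t \ln \omega(y|q,s)
   + \ln \omega(q|y) + \ln \omega(z|s,y,q)\big]$,

with $\beta_t = \beta$ for the linear objective and
$\beta_t = \beta e^{-I_r(Q;S|Y)}$ (nats) for the exponential one. The printed
form of this update is typographically ambiguous about what falls under the
logarithm, so the implementation re-derives it as the stationary point of the
variational objective in $r$; a term $\ln p(z|s,y)$ that is constant in $q$
is absorbed into the row normalization. The objective is concave in $r$ for
fixed $\omega$, so each sweep is an exact block maximization and the trace is
non-decreasing — the test suite asserts monotone ascent (within $10^{-9}$
bits) on every solver run it performs, which was also the arbiter used to
settle the grouping.

Internally all divergences are evaluated in nats (where $\beta$ multiplies
the log-likelihood terms) and reported in bits; the linear objective
converts to $\text{pred} - \text{comp}/\beta$ bits, the exponential one to
$\text{pred} - e^{\text{comp(nats)}}/(\beta \ln 2)$.

### Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `beta` | — | Tradeoff weight (dimensionless); small favors hiding source identity, large favors prediction. |
| `objective` | `"exponential"` | Resolves non-strictly-concave frontiers; `"linear"` kept for cross-checks. |
| `n_q` | $\sum_s \lvert\mathcal X_s\rvert + 1$ | Sufficient bottleneck cardinality; tests confirm doubling it never improves the objective. |
| `tol` | `1e-10` bits | Absolute objective change declaring convergence. |
| `max_iter` | `2000` | Cap per run; non-convergence is a warning, never an error. |
| `n_restarts` | `5` | Flat-Dirichlet random restarts; the objective is not jointly concave, so runs can end in local optima. Best objective wins, ties to lower compression. |
| `seed` | `0` | Controls every draw; identical seeds give identical results. |

`anneal_curve()` sweeps an increasing $\beta$ grid (default: 50
log-spaced values in $[10^{-2}, 10^3]$, which reaches both limits on all
benchmark gates), warm-starting each solve from the previous solution in
addition to the fresh restarts. `rb_at_rate()` interpolates $I_{RB}(R)$
linearly on the upper concave envelope of the achieved (compression,
prediction) pairs: points are sorted by compression, dominated points (an
artifact of restart noise) are dropped, and the concave hull is taken —
concavity of the true frontier licenses this. Beyond the largest achieved
compression the maximum achieved prediction is returned; below the smallest,
the first envelope point (the solver's compression-dominated limit) is used.

## Exact Blackwell redundancy

For small systems `blackwell_redundancy()` solves the garbling problem
exactly. The feasible set — row-stochastic $\kappa_s$ with
$\kappa_1 \circ p_{X_1|Y} = \kappa_s \circ p_{X_s|Y}$ — is a polytope, and
$I(Q;Y)$ is convex in $p_{Q|Y}$, so the maximum sits at a vertex. The package
ships its own double-description vertex enumerator: equality constraints are
eliminated first by an SVD null-space parametrization, duplicate halfspaces
are merged, and rays are grown constraint-by-constraint with the
combinatorial adjacency test. A bottleneck cardinality of
$\sum_s \lvert\mathcal X_s\rvert - n + 1$ suffices. The practical limit is the
*reduced* polytope dimension (capped at 60): the three-spin benchmark has
$120$ raw garbling entries but an 18-dimensional feasible set with exactly
100 vertices, and solves in well under a second. Larger systems should use
the iterative solver at small $\beta$ instead — that is precisely what the
bottleneck reformulation is for.

`is_blackwell_leq()` decides the degradation order by driving the convex
quadratic residual $\lVert \kappa \circ c - b\rVert^2$ to zero with an
accelerated projected gradient over the product of simplices (max-abs
residual $10^{-7}$ declares feasibility). `deficiency()` minimizes the
$p_Y$-weighted KL divergence with multiplicative updates and backtracking;
entries of $\kappa$ that would push mass onto zeros of the reference channel
are removed a priori, and an `Inf` sentinel is returned when no admissible
$\kappa$ remains.

## Benchmark gates and what the tests show

`make_gate()` reproduces the standard PID benchmark systems with uniform
source weights: UNIQUE (a copied bit plus noise; $I_\cap = 0$,
bounds $0.5$/$0.311$ bits), AND (identical channels, a single curve point
$(0.311, 0)$), four binary symmetric channels with error probabilities
$(0.1, 0.1, 0.2, 0.5)$ (bounds $0.335$/$0.104$; the $\epsilon = 0.5$ source
never contributes prediction), the three-spin overlap target
($I_\cap = 1$, bounds $2$/$0.459$), and COPY($\epsilon$) (correlated bits;
$Y$ outcomes that are impossible at $\epsilon = 0$ are pruned to keep the
target marginal full-support). `random_system()` draws flat-Dirichlet
systems for property tests.

These fixtures are *exact rational distributions*, not sampled data: passing
tests demonstrate that the optimization machinery reproduces known
information-theoretic ground truth, but say nothing about estimation error,
sampling noise, or plug-in bias that real empirical distributions would add.
Ground truth for the solver itself comes from independent routes: term-by-term
summation oracles for all measures, a $10^5$-channel random search that the
solver must dominate on two-source binary systems, and the exact vertex
enumerator, which must agree with the annealed curve at $R = 0$ on every
fixture (within $5\times10^{-3}$ bits).

A subtlety the COPY gate exposes: its true frontier is *linear*, from
$(0, 0)$ to $(\epsilon/2, 1)$, so $I_{RB}(R) = \min(1, 2R/\epsilon)$.
The exponential Lagrangian traverses a linear segment only within a narrow
$\beta$ window that log-spaced grids typically straddle, so interpolation
across the resulting gap — which yields exactly the chord, i.e. the correct
value — is doing real work there. The continuity tests assert this closed
form directly: $I_{RB}(0.01)$ decays continuously in $\epsilon$ (successive
grid steps of at most $\approx 0.6$ bits) while exact $I_\cap$ jumps
discontinuously from 1 to 0 as soon as $\epsilon > 0$.

## Numerical choices

* **Units.** All reported information quantities are bits (base-2 logs),
  with $0 \log 0 = 0$ and an `Inf` sentinel when absolute continuity fails.
* **Validation.** Distributions and channel rows must normalize within
  $10^{-12}$ at construction; the target marginal and source weights must be
  strictly positive (callers prune impossible outcomes — silent pruning
  would silently shift alphabet indices).
* **Stability.** The bottleneck update works in log space with a
  $10^{-300}$ floor inside logarithms and max-subtraction before
  exponentiation, so rows cannot lose all mass even at $\beta = 10^3$.
* **$\beta$ grids** are strictly positive; the $R = 0$ regime is reached by
  the smallest grid value, not $\beta = 0$, where the update degenerates.
* **Determinism.** A seed-scoped RNG wrapper means no package function
  perturbs the caller's random stream, and every stochastic path is
  reproducible from integer seeds.
* **Problem sizes.** The shipped analyses are desk-scale: curves use 50
  $\beta$ values with 5 restarts (seconds per gate); broader property scans
  in the test suite use 20 $\beta$ values and 2 restarts, which the loose
  bounds they assert do not notice.

## Limitations

* Only discrete systems with enumerable $(y, s, z, q)$ support; no
  continuous variables and no variational/neural approximations.
* The source-identity variable is always independent of the target
  ($I(Y;S) = 0$); correlated constructions are not implemented.
* The alternating solver can hit local optima or saddle points; restarts and
  annealing mitigate but do not eliminate this, and non-convergence at
  extreme $\beta$ (a slow $10^{-10}$-bit creep) is reported via the
  `converged` flag rather than hidden.
* Vertex enumeration is exponential in the worst case and refuses reduced
  dimensions above 60.
* Per-source curves are reported raw; no changepoint/phase-transition
  detection is attempted.
* Only the KL-weighted deficiency orientation used by the compression bound
  is provided, not the reversed-argument variant found elsewhere in the
  literature.
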