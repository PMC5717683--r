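---
title: "Generating weighted networks with prescribed spectral properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating weighted networks with prescribed spectral properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netforge)
```

## The problem

Many questions about networked systems — metapopulations connected by
dispersal, contact networks carrying an epidemic, interaction webs — hinge
on *how much* network structure matters, which requires ensembles of
networks whose structure is controlled. Most generative models in the
graph literature control *unweighted* structure (degree distributions,
clustering). `netforge` instead controls a hierarchy of *weighted*
metrics: given a node count $n$, it produces symmetric, nonnegative,
zero-diagonal weight matrices $A$ whose

* **spectral radius** $r = \max_k \lambda_k(A)$ — a one-number summary of
  overall connectivity — and whose
* **dominant-eigenvector moments** — the population variance $v$ and
  skewness $s$ of the Perron eigenvector's elements, i.e. of the nodes'
  eigenvector-centrality scores —

match user-supplied targets $(r^*, v^*, s^*)$. The three metrics are
hierarchical: infinitely many weighted networks share a spectral radius;
fixing $v$ pins how *heterogeneous* node contributions are; fixing $s$
pins the *balance* of strongly versus weakly contributing nodes.

In the motivating habitat-graph setting the nodes are habitat patches and
$a_{ij}$ is the cost (e.g. distance in km) of moving between patches $i$
and $j$; dispersal is bidirectional at equal rates, hence symmetry.

## Metric definitions and normalisation

For a connected (irreducible) nonnegative symmetric matrix the dominant
eigenvalue is simple and its eigenvector can be chosen strictly positive
(Perron–Frobenius). `netforge` normalises this eigenvector to **unit
Euclidean norm with nonnegative orientation**, which makes it unique; the
moments are **population** moments,

$$v = \frac1n \sum_{k=1}^n \left(x_k - \langle x\rangle\right)^2, \qquad
  s = \frac{(1/n)\sum_k x_k^3 - 3\langle x\rangle v - \langle x\rangle^3}
           {v^{3/2}},$$

where the skewness expression is the expanded form of the standardised
third central moment (the test suite checks the algebraic identity on
thousands of random vectors). The normalisation matters: $v$ and $s$ are
invariant under rescaling of $A$ but not under rescaling of $x$, so a
convention is required for the targets to be meaningful numbers. Unit
$L^2$ norm makes the attainable variance range $[0, (n-1)/n^2]$, which
comfortably contains the target magnitudes used throughout
(0.005–0.026).

Two consequences to keep in mind:

* $v = 0$ (homogeneous eigenvector, e.g. any uniform-weight complete or
  ring network) leaves the skewness **undefined**; `spectralSummary()`
  reports `NA`, `eigvecSkewness()` raises an error, and criteria that
  request a skewness together with $v^* = 0$ are rejected as
  inconsistent.
* With the usual statistical sign convention, a single node contributing
  far *more* than the rest gives **positive** skewness and a single node
  contributing far *less* gives **negative** skewness. Verbal summaries of
  skewness as "the proportion of highly to weakly connected nodes"
  circulate in the applied literature with the opposite sign attached;
  `netforge` follows the literal formula above and leaves the verbal
  interpretation to the user.

## The algorithm

Targets enter through the weighted least-squares objective

$$\min_{a_{ij}}\;
  \omega_1 (r^* - r_0)^2 + \omega_2 (v^* - v_0)^2 + \omega_3 (s^* - s_0)^2,$$

where $(r_0, v_0, s_0)$ are the metrics of the current matrix, subject to
the linear equality constraints $B\,a = E$ over the row-major
vectorisation $a$ of $A$: one row per diagonal entry ($a_{ii} = 0$), two
rows per forced disconnection ($a_{ij} = a_{ji} = 0$), and one row per
connected pair ($a_{ij} - a_{ji} = 0$, symmetry). The generator proceeds
as a hill-climb:

1. draw a random conforming matrix with free weights uniform on
   $[w_{\min}, w_{\max}]$;
2. minimise the objective over the free weights (`minimizeStep()`);
3. if every metric difference is within tolerance, stop; otherwise
   randomise one off-diagonal weight pair and go to 2.

Non-convergence within `maxOuter` perturbations is a reported outcome,
not an error — some target combinations are simply unattainable (see
feasibility below), and a convergence map over a target grid
(`feasibilityMap()`) makes the attainable region visible empirically.

### The inner solver

The constraints are *eliminated by construction*: for a symmetric pattern
the feasible matrices are exactly parameterised by one free weight per
connected upper-triangle pair (`freeParameterization()`), so the inner
solver is an unconstrained-in-shape, box-bounded quasi-Newton method
(`optim(method = "L-BFGS-B")`). The full system $B a = E$ is still built
and used as a post-hoc validator on every emitted matrix — identical
feasible set, far better conditioning than solving the $n^2 \times n^2$
system each step.

Gradients are analytic. For the simple dominant eigenpair $(r, x)$ of a
symmetric $A$ and a joint perturbation of the pair $(i, j)$,

$$\frac{\partial r}{\partial a_{ij}} = 2 x_i x_j, \qquad
  \frac{\partial x}{\partial a_{ij}}
  = \sum_{k \ge 2} \frac{u_k^\top (\partial A)\, x}{r - \lambda_k}\, u_k,$$

with $(\lambda_k, u_k)$ the remaining eigenpairs, and the moment
derivatives follow by the chain rule. Analytic sensitivities make the
inner solver both fast and accurate to near machine precision, which is
why achieved metrics typically agree with the targets to far better than
the stopping tolerance. The eigenvector-sensitivity denominator requires
the dominant eigenvalue to be simple, which holds for every connected
nonnegative symmetric matrix; the solver additionally clamps $v$ away
from zero ($10^{-14}$) inside the skewness term so the objective stays
finite if the search passes near a homogeneous eigenvector.

The solver stops at relative improvement `factr = 1e4` (i.e.
$\sim 2\times10^{-12}$ of the objective), or after `maxInner` (default
2000) iterations. It is deterministic, so a whole generation run is a
pure function of `(criteria, seed)` — the test suite checks bit-identical
trajectories.

### Objective weights

The targets live on wildly different scales ($r^* \sim 20$–$80$,
$v^* \sim 0.005$). The default weights are scale-normalised,

$$\omega_k = \frac{1}{\max(t_k^2,\; f_k^2)},$$

with scale floors $f = (1, 0.01, 0.01)$ for $(r, v, s)$. The floors keep
the weight finite when a target is exactly zero: a floor as small as,
say, $10^{-6}$ would give a zero skewness target a weight of $10^{12}$,
making the objective so ill-conditioned that the quasi-Newton solver
stalls — in trials, the same run that converges immediately with the
$0.01$ floor needed hundreds of perturbations without it. The floor value
is the absolute tolerance `tolAbs`: differences below it are considered
converged anyway, so there is no benefit to weighting them harder.

### Weight box versus solver floor

`wMin` and `wMax` bound the *random draws* — the initial matrix and every
perturbation. Inside the minimiser, weights are bounded above by `wMax`
but below only by a tiny positive floor `wFloor` (default
$10^{-8} w_{\max}$), which preserves connectivity (irreducibility) while
letting optimised weights fall below `wMin` where the targets demand very
weakly coupled nodes.

This asymmetry is deliberate, and feasibility is the reason. If every
off-diagonal weight is at least $w_{\min}$, then for the Perron pair
$(r, x)$ with $S = \sum_k x_k$,

$$r x_i = (A x)_i \ge w_{\min} (S - x_i)
  \quad\Longrightarrow\quad
  x_i \ge \frac{w_{\min} S}{r + w_{\min}},$$

so no node's centrality can fall below a floor set by $w_{\min}$ and $r$.
That floor caps how *negative* the eigenvector skewness can be at a given
variance: with $n = 10$, $r^* = 20$, $w_{\min} = 1$, an extremal
three-point enumeration puts the minimum attainable skewness at
$v = 0.025$ at about $+0.32$ — targets such as $(v^*, s^*) =
(0.025, -0.5)$ would be provably unattainable, and the solver indeed
stalls at the same compromise point from every start if the floor is
enforced. With the box read as a bound on random draws only, the same
targets are met immediately and exactly. Users who need strict
$[w_{\min}, w_{\max}]$ weights can set `wFloor = wMin`, accepting the
shrunken attainable region.

### Tolerances

Convergence is judged per metric: relative difference
$|t - a|/|t| \le$ `tol` (default 1%) when the target magnitude is at
least `tolAbs` (default 0.01), absolute difference $\le$ `tolAbs`
otherwise — the per cent difference is meaningless at or near a zero
target. The same band is used when validating criteria against the
feasibility bounds, so a target that abuts a bound within its own
tolerance (e.g. $s^* = -1.79$ against the $n = 6$ bound
$-4/\sqrt 5 \approx -1.7889$) is admissible and the optimiser lands on
the boundary, while a clear exceedance ($s^* = 3$) is rejected before any
work, naming the violated bound.

## Feasibility bounds

For unit-norm nonnegative vectors, $\sum_k x_k^2 = 1$ gives
$v = 1/n - \langle x\rangle^2$ with
$\langle x\rangle \in [1/n,\, 1/\sqrt n]$, hence

$$0 \le v \le \frac{n-1}{n^2},$$

and the classical extremal skewness of $n$ numbers (two-point
configuration with mass on a single outlier) gives

$$|s| \le \frac{n-2}{\sqrt{n-1}}.$$

These bounds are derived here from the normalisation convention — they
are not transcribed from elsewhere — and they are corroborated
empirically: no generated or random network in the test suite ever
exceeds them (tolerance $10^{-9}$). They are *necessary*, not sufficient:
the attainable $(v, s)$ region additionally shrinks with the weight box
and the radius target (the Perron floor argument above), which the
package treats empirically via `feasibilityMap()` rather than
analytically.

## Degenerate inputs and numerical choices

* **Disconnected structures** (from forced-disconnection patterns) have
  no unique positive Perron vector; `dominantEigenvector()` refuses them,
  and `randomConforming()` rejects patterns that disconnect the graph.
* **Dominant-eigenvalue ties** (multiplicity > 1) are rejected rather
  than resolved by an arbitrary choice; for symmetric nonnegative
  matrices they only arise in the disconnected case already excluded.
* **Homogeneous eigenvectors**: variance below $10^{-24}$ (the square of
  round-off on unit-norm elements) is treated as zero and skewness as
  undefined.
* **Solver failure** inside `minimizeStep()` returns the starting matrix
  unchanged with a warning; the outer loop continues via perturbation, so
  a single bad step cannot poison a run.
* **Vectorisation order** of $B a = E$ is row-major and recorded in the
  `EqualitySystem` object, so external checks are reproducible.
* **File output** uses 17 significant digits, making write-then-read
  round-trips bit-exact across the matrix, edge-list and GraphML
  dialects.

## What the random-instance generator does and does not emulate

`randomConforming()` draws free weights i.i.d. uniform on
$[w_{\min}, w_{\max}]$ — the same distribution the generation loop uses
for initial conditions and perturbations. This emulates the study
condition of interest (dense weighted networks with bounded,
unstructured costs) and gives the self-consistency tests their source
targets: measured $(r, v, s)$ of such networks are attainable by
construction, so regenerating networks from them must succeed. It does
**not** emulate spatially embedded cost matrices (distances obey the
triangle inequality; uniform draws do not), degree-heterogeneous
topologies, or sparse empirical networks. Passing tests therefore
demonstrate that the algorithm recovers attainable targets and respects
its structural contracts — not that uniform random networks resemble any
particular empirical system.

## Problem sizes and test design

The package's validation uses $n = 6$ and $n = 10$ for generation runs
(matching the demonstrated target combinations), $n \le 30$ for metric
property checks, and 40 self-consistency recoveries (20 each at
$n \in \{6, 10\}$, $\ge 90\%$ required to converge at 1% tolerance
within 500 perturbations; in practice nearly all converge with zero
perturbations). The dense symmetric eigendecomposition is adequate far
beyond these sizes (hundreds of nodes); no sparse or iterative path is
provided.

## Known limitations

* The inner minimisation is local; convergence to a local rather than
  global minimum cannot be ruled out, and the perturbation loop is a
  heuristic escape, not a guarantee. Different solvers may therefore
  converge on different subsets of near-boundary target combinations.
* Only symmetric (undirected) patterns are supported by the generator;
  `buildEqualitySystem()` can represent asymmetric patterns (by omitting
  symmetry rows), but generation under them is untested and unsupported.
* Binary (0/1) weight constraints would turn the problem into a
  nonlinear integer program and are out of scope.
* The equality-constraint right-hand side $E$ is structurally general
  but all supported rules have $E = 0$; pinning individual weights to
  nonzero values is representable in the object, not exercised by the
  generator.

## A worked run

```{r example}
crit <- generationCriteria(6, rStar = 80, vStar = 0.026, sStar = 0,
                           seed = 1)
res <- generateNetwork(crit)
res
round(adjacency(finalNetwork(res)), 2)
```

The achieved metrics sit on the targets to many digits: the analytic
gradients let the inner solver finish the job in a single descent, with
zero hill-climb perturbations.
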