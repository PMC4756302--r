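---
title: "Localized and global activation patterns on networks: methods"
author: "shnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized and global activation patterns on networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shnet)
```

## The model

`shnet` implements a single-species excitation model on a simple, undirected,
connected graph. Each node carries an activation potential $u_i$ governed by

$$\frac{du_i}{dt} = f(u_i,\mu) + I_i, \qquad
  I = -\left(2L^{(2)} + L^{(4)}\right)u,$$

where $L^{(2)} = A - \mathrm{diag}(k)$ is the graph Laplacian,
$L^{(4)} = (L^{(2)})^2$ the bi-Laplacian, and

$$f(u,\mu) = -(1+\mu)\,u + b\,u^2 - u^3, \qquad b = \tfrac32
\text{ by default.}$$

Substituting $-(1+\mu)u - (2L^{(2)}+L^{(4)})u =
-\mu u - (\mathrm{Id}+L^{(2)})^2 u$ shows that the system is the network
analogue of the quadratic–cubic Swift–Hohenberg equation
$u_t = -\mu u - (1+\nabla^2)^2 u + b u^2 - u^3$, with the Laplacian
eigenvalues $\Lambda_\alpha \le 0$ playing the role of $-q^2$. The coupling
combines short-range anti-correlation (nearest neighbours) with
longer-range correlation (two-jump neighbourhood); both operators
annihilate constants, so the interaction currents conserve the total state
and vanish identically on flat states.

### Why this nonlinearity and these coefficients

The quadratic–cubic force with $b = 3/2$ and coupling coefficients $(2,1)$
on $(L^{(2)}, L^{(4)})$ is adopted because, in the dense-spectrum
idealization (treat $\Lambda$ as continuous; large networks have spectra
dense near the critical value $\Lambda = -1$), it reproduces the four flat
bifurcation values simultaneously:

```{r}
str(flat_bifurcation_points(1.5))
```

$\mu_0 = 0$ (trivial-state threshold, rate maximum at $\Lambda = -1$),
$\mu_1 = b^2/4 - 1 = -0.4375$ (flat saddle-node), and
$\mu_\pm$ (stability exchange of the nonzero branches, where $f(u) = 0$ and
$f'(u) = -1$) printing as $-0.62$ and $-1.82$ at two decimals. It also
yields the full collision sequence of the topological eigenvalues (the four
roots of $(1+s^2)^2 = -\mu$): a complex quartet for $\mu > 0$, pairwise
collision at $\pm i$ at $\mu = 0$, four imaginary roots for $-1<\mu<0$, a
double root at the origin at $\mu = -1$, and two real roots beyond — the
reversible 1:1 resonance scenario that admits homoclinic (localized)
states for small $\mu > 0$.

Note a subtlety of the stability ordering: between $\mu_+$ and $\mu_1$ the
upper flat branch has $f'(u_+) \in (-1, 0)$, so its maximal growth rate
$f'(u_+) + 1$ is *positive*; $u_+$ is stable only below $\mu_+$. On a
specific finite network the realized thresholds use the actual spectrum
(`max_growth_rate()`), which can differ from the idealization when the
spectrum is sparse near $\Lambda = -1$ (e.g. small rings).

## Numerical integration

The bi-Laplacian makes the system stiff (eigenvalues grow like
$\Lambda^2$), so `evolve()` uses first-order Lie splitting: the linear
coupling is treated implicitly,
$(\mathrm{Id} + \Delta t\,C)\,u_{n+1} = v_n$, with $C = 2L^{(2)}+L^{(4)}$
factorized once per (network, $\Delta t$) by sparse Cholesky — the matrix
is positive definite for $\Delta t < 1$ because the spectrum of $C$ is
$2\Lambda + \Lambda^2 \ge -1$. The reaction part advances explicitly, but
sub-cycled so each substep $h$ satisfies $h\,|f'| \le 1/2$; the cubic is
confining, and without sub-cycling a single explicit step diverges for
$|u| \gg 1$ (strong stimuli, large noise draws). Near equilibrium the
sub-cycling is inactive and the splitting's fixed points coincide exactly
with steady states of the continuous system, which is why integration to
`settle_tol` followed by a Newton polish (`newton_steady()`, exact sparse
Jacobian $J = \mathrm{diag}(f'(u_i)) - C$, backtracking line search) moves
the state only marginally. The default $\Delta t = 0.05$ trades accuracy
for speed safely because only equilibria are of interest.

## Continuation and snaking

`continue_branch()` performs pseudo-arclength continuation of stationary
states in $\mu$, with equal weights on $u$ and $\mu$ in the arclength
metric. The corrector solves the bordered system
$\{F(u,\mu)=0,\ t\cdot\Delta x = ds\}$ by Newton with block elimination on
the sparse Jacobian ($F_\mu = -u$). The predictor is the secant tangent
(first step: the Jacobian null-space direction). The step is adapted —
halved on corrector failure, doubled after fast convergence, clamped to
$[ds/16,\,4ds]$ — and two guards reject steps that leave the branch:
consecutive points must be at most $2\,ds$ apart, and the realized secant
may not reverse against the tangent. Without these guards the corrector
occasionally converges onto a distant branch, visible as jumps of several
unstable directions at once.

Every accepted point is tagged with the leading Jacobian eigenvalue and
with the *Morse index* (number of unstable directions). On irregular
networks the classic snaking structure appears with its rung
(ladder) bifurcations folded into the branch: along one period the index
cycles $0,1,2,1,0$, and each fold exchanges exactly one direction
($|\Delta\,\text{index}| = 1$). The boolean stable flag therefore follows
stable plateau — three unstable arcs — stable plateau, rather than strict
alternation at every fold; `snaking_diagram()` warns when segment-level
alternation is violated rather than failing.

Branch seeding follows the stimulus protocol: `make_stimulus()` builds a
step signal on the closed two-jump neighbourhood of the best-connected
node (ties broken by lowest id). Whether the centre node itself belongs to
the support is configurable (`include_center`, default `TRUE`); the
equilibrium reached from such a stimulus at the target $\mu$ starts the
branch. Default step $ds = 0.5/\sqrt{N}$ on networks, $0.05$ on the
single-node oracle, whose flat-state curve and fold at
$(u,\mu) = (3/4, -0.4375)$ are known in closed form.

## Robustness experiments

`amplitude_sweep()` raises the stimulus amplitude across a grid and
records the polished equilibrium energy $E = \sum_i u_i^2$ (the snaking
measure; pluggable via `energy_fn`). Rows are classified *relaxed*
($E < 10^{-6}$), *robust* (member of the terminal energy plateau; 1-D
segmentation with relative tolerance $10^{-3}$) or *fragile* (quantized
but below the terminal plateau). `threshold_estimate()` brackets the
activation threshold between the last relaxed and first quantized
amplitude and bisects until the bracket is an eighth of the grid step.

`noise_monte_carlo()` perturbs the robust step stimulus with
support-restricted uniform noise of half-width
$\rho \times$ amplitude and tracks, over seeded realizations
(default 100; realization seeds derived deterministically from the master
seed), the fraction whose final energy matches the noise-free state to
$10^{-3}$ relative. The noise distribution (uniform on $[-a,a]$) is a
modeling choice; nothing in the protocol depends on its exact shape. The
result table carries both the noise-to-signal ratio and its reciprocal.
One practical caveat documented here because it affects reproduction: the
*basin* of the quantized state narrows near the plateau's lower edge, so
the noise experiment should start from an amplitude well inside the robust
plateau (the worked runs use amplitude 3 on a plateau that begins near 1);
just above threshold, even 1% noise can tip the system into the
neighbouring quantized state.

## Mean-field approximation of global Turing patterns

For $\mu < 0$ the trivial state is Turing-unstable and small perturbations
grow into global stationary patterns. The degree-based reduction closes
the local fields with the global means
$H_u = \sum_i k_i u_i / \sum_i k_i$ and
$H_{uu} = \sum_i k^{(2)}_i u_i / \sum_i k^{(2)}_i$ (two-jump-degree
weighted; a $k^2$-weighted variant is available for sensitivity checks),
giving one cubic per node class $(\alpha, \beta, s)$ =
(degree, two-jump degree, two-walk count):

$$g(u) = f(u,\mu) + (\alpha - \alpha^2)\,u
       + (\alpha^2 - 2\alpha)\,H_u + (s - \beta)\,H_{uu}.$$

With the tree-consistent substitution $s = \alpha + \beta$ the coupling
terms cancel identically on uniform states, so every flat state of the
full model is an exact fixed point of the reduction
(`tree_consistent = TRUE` in `mfa_overlay()`); with the measured two-walk
count the cancellation is only approximate on graphs with triangles or
shared neighbours. `mfa_overlay()` measures $H_u, H_{uu}$ on a simulated
pattern, solves the cubic for every class, and reports each node's
distance to its nearest stable root, with nodes ordered by $(k, k^{(2)})$.

### Known limitations of this closure

Two structural facts, established while validating the module, bound what
the overlay can show:

* The self-coupling term $(\alpha-\alpha^2)u$ is the *exact* diagonal of
  $-C$, and it is $\le 0$ for every degree $\alpha \ge 1$. At
  $\mu = -1/4$ this makes the reduced cubic strictly monotone for every
  node class — one real root, always. Per-node bifurcation diagrams with
  coexisting stable branches cannot arise from this closure at that
  parameter value.
* Regressing the exact coupling $(Cu)_i$ on $u_i$ within degree classes of
  a converged pattern shows $C$ acting like $-1$ (the critical-subspace
  value $2\Lambda + \Lambda^2$ at $\Lambda = -1$) plus a class-dependent
  constant — and the constant's *within-class* scatter, driven by which
  particular neighbours a node has, is what the mean field discards. Even
  an oracle closure that assigns each class its true mean coupling
  reproduces only about 72% of nodes within 15% of the pattern range on an
  Erdős–Rényi graph ($N = 1000$, $\langle k\rangle = 6$, $\mu = -1/4$);
  the implemented closure reaches about 69%. Agreement of that order is
  the realistic ceiling for any $(k, k^{(2)})$-class mean field here.

What the reduction does capture well is the *shape* of the profile: hubs
are pinned near $H_u$ by the strong self-coupling, the stable-root curve
tracks the simulated pattern closely for $k \gtrsim 5$, and the
smoothness contrast between topologies is reproduced robustly — the
total variation (per pattern range) of the stable-root curve over the
$(k,k^{(2)})$-sorted node index is roughly an order of magnitude smaller
on an ER graph than on a Barabási–Albert graph of equal size and mean
degree, because the narrower degree distribution makes the class
parameters, and hence the pattern, more homogeneous.

## Synthetic networks as study conditions

All experiments run on synthetic graphs, as in the source study:
Barabási–Albert preferential attachment (`generate_ba`; seed clique of
$m+1$ nodes for $m>1$, a single edge for $m=1$, $m$ draws without
replacement per new node) and Erdős–Rényi `G(n,p)` with
$p = \langle k\rangle/(n-1)$ (`generate_er`; disconnected draws keep the
giant component, with a message). The worked analyses use BA $N=200$,
$m=1$ (snaking, robustness — a tree, minimum degree 1), BA $N=2000$
(dispersion checks), and ER $N=1000$, $\langle k\rangle = 6$ with BA
$N=1000$, $m=3$ as the matched comparison (mean-field overlay). The mean
degrees of the ER/BA comparison pair and the $m=1$ choice for the snaking
network are configuration, not derived quantities. Because generated
trees, `G(n,p)` draws, and preferential-attachment graphs are far more
regular in their degree–degree correlations than most empirical networks,
passing tests on them demonstrates the mechanisms (quantization,
robustness, mean-field smoothness) but not quantitative accuracy on real
topologies.

## Numerical conventions

* Stationarity: residual max-norm below $10^{-8}$ (integration) polished
  to $10^{-10}$ (Newton); continuation corrector tolerance $10^{-8}$.
* Stability calls use tolerance $10^{-8}$ on the leading eigenvalue;
  eigen-decompositions are dense (`base::eigen`, symmetric), cached per
  network — the scales of interest ($N \le 2000$) make iterative solvers
  unnecessary.
* Degenerate inputs: the single-node network (zero Laplacian) is admitted
  everywhere and serves as the continuation oracle; flat patterns have
  zero range, so overlay tolerances carry a $10^{-10}$ absolute floor;
  exact-zero $\Delta\mu$ steps inherit the previous sign in fold
  detection.
* Ties: "best-connected" resolves to the lowest node id among maximal
  degrees; equal growth rates (e.g. the $\Lambda = 0$ / $\Lambda = -2$ tie
  on the 4-ring at $\mu = -1/4$) return the first maximizer in descending
  eigenvalue order.
* Problem sizes in the shipped tests (BA 200 for snaking and robustness
  with 100 noise realizations, ER/BA 1000 for the overlay, BA 2000 for
  dispersion) were chosen to keep the full suite under a minute of
  wall-clock on one core while matching the study's scales.
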