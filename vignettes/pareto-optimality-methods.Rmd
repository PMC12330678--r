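---
title: "Cost-efficiency Pareto optimality of root system architectures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-efficiency Pareto optimality of root system architectures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootpareto)
```

## The model

A traced two-dimensional root system is an arborescence: nodes with image
coordinates (y grows downward), parent links, and a root-order label per
node (0 for the primary root, 1 for first-order laterals, and so on). For
the optimality analysis only the *terminals* matter: the hypocotyl base
$\rho_0$ — the hub through which every transported molecule passes — and
the root tips, where growth and much of the uptake happen. Candidate
transport networks over these terminals are trees with undirected branches
$\beta$, optionally with added junction points.

Two competing objectives score a network:

* **total length** — the sum of all branch lengths, a proxy for the
  construction (growth) cost;
* **travel distance** — the sum over tips of the along-network path length
  from $\rho_0$, a proxy for transport inefficiency.

Travel distance is always accumulated over the *terminal* tips: a network
that routes other branches through a tip still pays that tip's path. The
two extremes are the **satellite tree** (the star of straight base-to-tip
segments, the global minimum of travel distance) and the **Steiner tree**
(the minimum-total-length network, which may add junction points). All
intermediate optima are swept by the linear scalarization

$$\mathrm{Joint}(\rho, \beta) \;=\; \min \; \alpha\,(\text{total length})
  + (1-\alpha)\,(\text{travel distance}), \qquad 0 \le \alpha \le 1,$$

whose minimizers form the Pareto front: the satellite at $\alpha = 0$, the
Steiner tree at $\alpha = 1$. The exact joint optimization is NP-hard, so
the front is built heuristically and benchmarked against an exhaustive
oracle on small instances (below).

A measured plant is projected onto the front through its own cost pair.
Its **scaling distance** is

$$\min_{f \in \text{front}} \; \max\!\left(
   \frac{L_{\text{plant}}}{L_f}, \frac{T_{\text{plant}}}{T_f}\right),$$

the factor by which the plant's (cost, travel) pair exceeds the nearest
front point; a tree on the front scores exactly 1. The $\alpha$ of the
minimizing front point is the plant's **alpha value**, its position on the
cost-efficiency spectrum; ties go to the smallest $\alpha$. The name
"distance to the front" is used loosely in the field for several related
quantities; we implement the max-ratio scaling factor because it is
unit-free, equals 1 exactly on the front, and doubles when the plant's
pair doubles — the behaviour expected of a Pareto-optimality *value*. The
raw Euclidean distance in (cost, travel) space is kept as an auxiliary
diagnostic (`euclidean_distance`), and the choice is isolated inside
`scaling_distance()`.

**Null model.** To calibrate how non-random a plant is, spanning trees
over the same terminals are drawn uniformly from all labeled spanning
trees of the complete graph (random Prüfer sequences; Cayley's formula
gives $m^{m-2}$ trees on $m$ terminals). The component-wise mean of their
cost pairs — the barycenter, one representative random architecture — is
scored against the same front. For the collinear textbook instance
($\rho_0 = (0,0)$, tips $(0,1), (0,2)$) the three labeled trees have cost
pairs $(3,3)$, $(2,3)$ and $(3,5)$, the front is the single point
$(2,3)$, and the equal-weight barycenter $(8/3, 11/3)$ has scaling
distance $4/3$ — the worked example frozen in the test suite.

## Front construction

`build_front()` runs, for every grid $\alpha$:

1. **Greedy insertion** (`greedy_joint_tree`): starting from $\rho_0$,
   repeatedly attach the (tip, tree-vertex) pair minimizing the
   incremental joint objective $\alpha d(u,v) + (1-\alpha)(\mathrm{pathlen}(v)
   + d(u,v))$, ties to the smallest tip then vertex index. At $\alpha = 0$
   this is exactly the satellite (special-cased so floating-point ties
   cannot perturb the star); at $\alpha = 1$ it is Prim's minimum spanning
   tree.
2. **Junction insertion and relocation** (`refine_junctions`): for each
   vertex, the pair of incident edges whose weighted pull exceeds the
   weight of a fresh junction edge (the weighted 120° rule) receives a
   junction, which is then relocated to the weighted geometric median of
   its neighbours by coordinate descent — with edge weights
   $\alpha + (1-\alpha) k_e$, where $k_e$ is the number of tips routed
   through edge $e$, each relocation is an exact coordinate-descent step
   for the joint objective. Iterates that coincide with a neighbour use
   the Vardi–Zhang step, which escapes exactly when escaping lowers the
   objective; for the symmetric two-tip instance this reproduces the
   interior-junction threshold $\alpha = 2 - \sqrt 2$ analytically.
   Junctions whose removal is objective-neutral (within $10^{-9}$
   relative) are merged away; degeneracy is judged on the objective rather
   than on raw distance because a junction parked at a boundary optimum
   converges only linearly in position.
3. **Cross-alpha polish**: refined geometries are linear in their cost
   pair, so every topology found anywhere on the grid is re-evaluated at
   every $\alpha$; where a borrowed topology wins, its junctions are
   re-relocated at that $\alpha$. This pass also makes the front monotone
   essentially by construction.

Refinement effort scales with instance size: instances with at most 6
tips additionally run a subtree-reattachment local search (detach a
subtree, reattach it elsewhere, re-refine; a first-order screen keeps the
move count small), and instances with at most 12 tips run a second
refinement chain seeded from the satellite star, which explores the
root-outward topology family the greedy tree cannot reach. On 200 random
3–4-tip instances this combination stays within a fraction of a percent
of the exhaustive oracle (the acceptance suite asserts 3%).

Assembled fronts are cleaned deterministically: equal cost pairs collapse
onto their smallest $\alpha$, dominated points are removed, and a final
monotone sweep enforces total length non-increasing and travel distance
non-decreasing in $\alpha$. The default grid step of 0.01 (101 values)
matches the two-decimal alpha resolution customarily reported for this
analysis; it is configurable through `alpha_step`.

## The exhaustive oracle

`brute_force_front()` (at most 4 tips) enumerates all labeled spanning
trees over the terminals (Prüfer sequences) and all *full Steiner
topologies* — $n-2$ junctions of degree 3, generated recursively by edge
insertion (1, 3, 15 topologies for 3, 4, 5 terminals). For a fixed
topology the joint objective is convex in the junction coordinates, and
every degenerate Steiner topology is a limit of a full one, so minimizing
each full topology and taking the best candidate is exact up to numerical
tolerance. Junction coordinates are optimized by Weiszfeld coordinate
descent from deterministic starts (warm starts carry across the alpha
grid), followed by a Nelder–Mead polish that resolves the rare stalls at
junction–junction coincidences, and a final re-descent so that junction
*positions* — not just the objective — are converged: the cost-pair
components are first-order sensitive to position even where the objective
is stationary. Optimized trees are canonicalized by the same
objective-neutral merge as the heuristic, so two optimizations of the
same instance yield identical cost pairs.

## Numerical choices

* Relocation stops when no junction moves more than $10^{-10}$ in a
  sweep (1000 sweeps cap); the oracle uses $10^{-11}$/1500.
* Junction merges use a relative objective tolerance of $10^{-9}$.
* Greedy ties break to the smallest tip index, then smallest tree-vertex
  index; front deduplication keeps the smallest $\alpha$; scaling-distance
  ties resolve to the smallest $\alpha$.
* Scaling distance requires strictly positive front components and
  errors on degenerate fronts.
* CSV output formats doubles with 12 significant digits so fixed-seed
  batch runs are byte-identical across platforms.
* All samplers take explicit integer seeds and restore the caller's RNG
  state.

## Alpha recovery and its identifiability limits

Fixtures generated as exact-front trees at a chosen $\alpha^\*$
(`generate_front_fixture`) sit on the front (scaling distance 1) and are
the ground truth for alpha recovery. Two structural degeneracies make
recovery impossible for *any* method, and the corresponding checks in the
test suite therefore require, before using a fixture:

1. every tip remains a leaf of the fixture graph — an optimal tree that
   routes through a tip (a chain) presents a smaller terminal set when
   re-read as a traced architecture;
2. $\alpha^\*$ does not sit inside a flat run of the front — the satellite,
   for instance, is the exact optimum for every $\alpha$ below an
   instance-specific threshold ($2-\sqrt2$ in the symmetric two-tip
   case), all those grid points share one cost pair, and only the run's
   smallest $\alpha$ is recoverable under the smallest-alpha tie rule.

Both preconditions are computed from the front itself, never from the
recovery outcome. Under them, recovery is exact to within one grid step
on the seeded instance stream used in the acceptance suite.

## The synthetic generator

`generate_root_system()` emulates an Arabidopsis seedling traced from a
vertical agar plate, in millimetres: the primary root is a downward
random-heading walk (default 80 mm, 1 mm steps, heading noise
sd 0.05 rad/step — plate-grown primaries are nearly straight, tortuosity
about 1.005); first-order laterals are placed by a Poisson process along
the primary (0.25 /mm, matching the 2–3 laterals per cm typical of
10–17-day seedlings), emerge at $1.2 \pm 0.25$ rad from the local primary
direction, and have truncated-normal lengths ($12 \pm 6$ mm, truncated at
zero). For time series the primary elongates 6 mm/day, a lateral emerges
one day after the primary passes its position and elongates at half the
primary rate; all randomness is drawn once per seed into a fully grown
blueprint, and each day materializes a prefix of it, so daily graphs are
exactly nested. Lengths in a series are quantized to whole discretization
steps — that is what makes the nesting exact, at the price of rate
staircasing when the elongation rate is not a multiple of the step.

The generator reproduces the structural features the analysis consumes —
a dominant primary, stochastic laterals, tips spread in a downward fan,
arc lengths mildly above chord lengths — but not root diameters, higher-
order laterals, gravitropic curvature profiles, or tracing noise.
Passing tests on generated plants therefore demonstrate the correctness
and internal consistency of the computations, not biological conclusions
about real architectures.

Default parameter values were chosen once, from the morphology of
plate-grown Arabidopsis seedlings, and are not tuned to any test
outcome. Test and acceptance runs use plants of 25–80 mm primary length
(developmental stages from first-lateral emergence to plate bottom) so a
full run of the suite stays within ordinary desktop budgets; the sizes
are stated in the tests themselves.

## Known limitations

* The heuristic front carries no optimality certificate beyond the
  oracle benchmark; on large instances the scaling distance of a valid
  tree can dip slightly below 1 (the tests document a 0.97 floor).
* The alpha value is ill-conditioned where the plant's ratio curve along
  the front is flat: plants nearly equidistant from a stretch of the
  front can flip between neighbouring alphas under tiny front
  perturbations. The scaling distance is stable in the same situations.
* RSML lateral attachment snaps to the nearest parent-polyline vertex;
  no interpolated branch point is created. Writing includes the branch
  point in the child polyline, so our own round trips are lossless, but
  third-party RSML with sparse parent polylines will see attachment
  displaced by up to half a segment.
* Only 2D geometry is analyzed; junctions are never added in the null
  model (random trees span the terminals alone).

## Session

```{r}
sessionInfo()
```
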