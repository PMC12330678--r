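# rootpareto

Cost-efficiency Pareto-optimality analysis of traced root system
architectures (RSA).

A root system has two jobs that pull in opposite directions: transport
resources efficiently between the soil and the shoot, and grow as little
material as possible. `rootpareto` quantifies where a traced 2D root
system sits on that tradeoff. From the terminals of the traced
arborescence — the hypocotyl base ρ0 and the root tips — it constructs
the two extreme architectures (the **satellite tree**, a star of straight
base-to-tip links minimizing travel distance, and the **Steiner tree**,
the minimum-total-length network with added junction points) and the
Pareto front of the joint objective

    Joint(ρ, β) = min  α · (total length) + (1 − α) · (travel distance),   0 ≤ α ≤ 1

where total length is the summed branch length of the network and travel
distance the summed base-to-tip path length. The measured plant is
projected onto the front by its own (cost, travel) pair, giving

* the **scaling distance** to the front (1 = Pareto optimal; the
  max-ratio factor by which the plant exceeds the nearest front point),
* the **alpha value** (0 = transport-favouring satellite-like,
  1 = cost-favouring Steiner-like),

and compares it against a null model of uniform random spanning trees
over the same terminals (their barycenter is scored against the same
front). Canonical RSA traits (lengths, depth, width, convex-hull area,
lateral counts and density, tortuosity), growth-rate extraction from
daily time series and per-group aggregation round out the toolkit. Inputs
are a documented JSON arborescence schema and RSML; a parametric
generator of Arabidopsis-like root systems provides ground-truth fixtures
for every computation.

The exact joint optimization is NP-hard; the front is built by a greedy
insertion + junction-relocation heuristic whose error is bounded in the
test suite by an exhaustive Steiner-topology oracle on small instances.
See the methods vignette (`vignettes/pareto-optimality-methods.Rmd`) for
the model, the algorithms and the numerical choices.

## Worked example

```r
library(rootpareto)

# a synthetic 17-day-like Arabidopsis plant (or read_root_json / read_rsml)
g <- generate_root_system(sim_params(seed = 3))
g
#> Traced root system: 429 nodes, 428 edges, 28 tip(s)
#>   scale: 1 length/px; max order: 1
#>   metadata: plant_id=synthetic-3; genotype=synthetic; condition=control

fit <- pareto_rsa(g, null_n = 1000, seed = 5)
fit
#> Pareto optimality of a root system (28 tip(s), greedy front)
#>   total length    411.8995
#>   travel distance 1441.899
#>   scaling distance to front: 1.109356   alpha value: 0.15
#>   null barycenter scaling distance: 4.083603 (1000 random trees)
```

The plant's network costs 412 mm of root and 1442 mm of summed
base-to-tip transport path. Its scaling distance of 1.11 says the
architecture is within 11% of the Pareto front — far closer than the
random-tree barycenter at 4.08 — and its alpha value of 0.15 places it on
the transport-favouring side of the cost-efficiency spectrum.
`plot(fit)` draws the front, the plant, the random-tree cloud and its
barycenter; `coef(fit)`, `summary(fit)`, `simulate(fit)` and
`as.data.frame(fit)` expose the fitted quantities; `extract_traits(g,
fit)` returns the one-row trait record.

Batch processing from the shell (`analyze`, `traits`, `simulate`,
`aggregate`):

```sh
inst/cli/rootpareto analyze --input 'plants/*.rsml' --out results.csv \
    --alpha-step 0.01 --null-n 1000 --seed 1
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "rootpareto",
                               load_package = "installed")'
```

The suite covers the I/O round trips, the closed-form benchmark
geometry (Fermat-point junctions, the 2 − √2 junction threshold), the
exhaustive-oracle bound on the heuristic front, the worked collinear
null model, alpha recovery on exact-front fixtures, front invariants on
synthetic plants, and end-to-end determinism.

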