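# redmetrics

Phylogeny-based conservation prioritization for floras in which most
species have no formal threat assessment.

The EDGE framework ranks species by combining **evolutionary
distinctness** — the fair-proportion index
`ED(i) = Σ_e ℓ(e)/n(e)` over the branches `e` on the root-to-tip path,
with `ℓ` the branch length and `n` the number of descendant tips — with a
**Globally Endangered** component derived from the IUCN red-list category,
either as `EDGE = ln(1+ED) + GE·ln2` (GE = 0…4 for LC…CR) or as the
expected loss `EDGE = ED × p(category)` under published 50/100/500-year
extinction-probability transformations. EDGE is undefined for unassessed
species, which in many regional floras are the majority.

`redmetrics` implements the **Relative Evolutionary Distinctness (RED)**
surrogate: occurrences are projected on a 0.5° grid, every branch of the
tree is divided by the number of grid cells occupied by its descendant
species, and ED is recomputed on this *range-weighted* tree. Narrow-ranged,
evolutionarily isolated species rise to the top — no threat assessment
needed. The package also provides the surrounding machinery: Newick I/O and
root-depth calibration, midpoint-sister and random within-genus placement
of unsequenced species over seeded replicate trees, median score tables,
dense priority ranking, and validation of RED against EDGE with Kendall's
W, Spearman correlation and top-k list overlap. Synthetic generators
(genus-structured pure-birth trees, log-normally skewed gridded ranges,
configurable status distributions) make the entire pipeline testable
offline.

## Worked example

```r
library(redmetrics)

cfg <- simulation_config(n_species = 60, n_genera = 12,
                         status_counts = c(CR = 2, EN = 16, VU = 7, NT = 2, LC = 1),
                         withheld_fraction = 0.2)
sim <- simulate_dataset(cfg, seed = 42)        # tree, grid, statuses, plan
out <- run_pipeline(sim$backbone, sim$plan, sim$grid, sim$statuses,
                    n = 25, seed = 42, k = 10)

out$red
#> RED scores: 60 species x 25 replicates
head(dense_rank(out$red), 5)
#>        species rank
#> 1 Genus11 sp01    1
#> 2 Genus02 sp01    2
#> 3 Genus04 sp04    3
#> 4 Genus02 sp02    4
#> 5 Genus04 sp01    5
out$comparisons$isaac
#> n = 28 species: Kendall W = 0.935, Spearman rho = 0.870 (p = 1.9e-09), top-10 overlap = 7 (70%)
```

Twelve species missing from the 48-tip backbone were re-grafted at random
inside their genera in each of 25 replicate trees; `out$red` holds
per-replicate RED with per-species medians; the comparison line says that
over the 28 evaluated species the median-RED ranking agrees closely with
the median-EDGE ranking (W and rho near 1, p ≪ 0.001) and shares 7 of the
top 10 priorities — the surrogate behaviour RED is designed for, since this
simulation couples threat severity to range size.

A thin command-line front-end ships at `inst/exec/red-metrics`
(`red-metrics {tree,impute,ed,edge,rangeweight,red,compare,simulate,pipeline}`),
writing diff-able TSV/JSON outputs plus a manifest that records seeds,
parameters and the extinction-probability table used.

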