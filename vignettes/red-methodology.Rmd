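---
title: "Range-weighted evolutionary distinctness as an EDGE surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-weighted evolutionary distinctness as an EDGE surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redmetrics)
```

## The problem

EDGE prioritization ranks species by combining evolutionary distinctness
(ED) with their red-list threat category (GE). For most plant floras,
however, the majority of species have never been formally assessed, so EDGE
cannot be computed for them. Geographic range is among the strongest
correlates of extinction risk and is usually available even for unassessed
species. `redmetrics` implements a range-based surrogate: the Relative
Evolutionary Distinctness (RED) index, which is ED recomputed on a
*range-weighted* phylogeny. Where threat tracks rarity, RED ranks species
much like EDGE does, but needs only a tree and occurrence records.

## The indices

**Fair-proportion ED.** For a rooted tree with branch lengths, the ED of a
tip is

$$\mathrm{ED}(i) \;=\; \sum_{e \,\in\, \mathrm{path}(root,\,i)}
  \frac{\ell(e)}{n(e)},$$

where $\ell(e)$ is the branch length and $n(e)$ the number of tips
descending from branch $e$: every branch is split equally among the species
that share it, so $\sum_i \mathrm{ED}(i)$ equals the total branch length of
the tree (a conservation identity the test suite checks on thousands of
random trees, polytomies included).

**EDGE.** For an evaluated species, threat enters either through the
log-form score $\mathrm{EDGE} = \ln(1+\mathrm{ED}) + \mathrm{GE}\,\ln 2$
with $\mathrm{GE} \in \{0,\dots,4\}$ for LC through CR (Isaac et al. 2007),
or as the expected loss of distinct history
$\mathrm{EDGE} = \mathrm{ED} \times p(\text{category})$ under a
category-to-probability transformation for a 50-, 100- or 500-year horizon
(Mooers et al. 2008). The probability table ships as an editable CSV
(`inst/extdata/schemes.csv`) and is echoed into every pipeline manifest, so
the constants in use are auditable. Only ranks of EDGE values are
interpreted; within a scheme any strictly monotone variant of the score
ranks identically, which is why the choice of functional form is isolated in
`edge_score()`.

**RED.** Occurrences are projected on a plain degree grid (default 0.5°,
half-open cells, `floor` indexing, boundary points in the higher-index
cell; no map projection). Each branch is divided by the number of grid
cells occupied by the union of its descendant species' ranges, and ED is
recomputed on the weighted tree. Branches subtending narrow endemics keep
almost their full length; branches subtending widespread clades shrink.
RED values have no units of their own — only their ranking is used.

## Adding unsequenced species

Species without sequence data are grafted onto the backbone in two ways:

* **Midpoint sister** (`place_midpoint_sister()`): the branch subtending a
  named tip, genus or labelled clade is bisected and the new tip attached
  there, with terminal length chosen so the tree stays ultrametric. Used for
  placements fixed from the literature; they are identical in every
  replicate, as a single literature-based placement implies.
* **Random within genus** (`add_species_to_genus_random()`): one edge is
  drawn uniformly at random among the eligible edges of the genus clade
  (terminal edges of congeners, internal edges wholly inside the clade, and
  the clade stem), then a uniform height along it. Uniform-per-edge rather
  than length-weighted selection is the simplest defensible rule where the
  choice is otherwise unspecified; it is isolated in one function so a
  length-weighted variant is a local change.

`generate_replicates()` repeats the random placements (default 100
replicates) from per-replicate seeds derived from one master seed, making
replicate $i$ a pure function of (backbone, plan, seed, $i$). All scores are
summarised as per-species medians over replicates (mean of the central pair
for even counts). Backbone tips never move, so their root-to-tip paths are
identical across replicates; note that their ED still varies slightly
between replicates, because each grafted tip changes the descendant counts
of the branches it shares with them — a property of fair proportion, not an
artifact.

The backbone tree is accepted as ultrametric input (relative depth
deviation at most `1e-6` by default) and can be rescaled with
`calibrate_root_depth()`; the conventional root depth of 100 is an
arbitrary relative scale, since every ranking computed here is invariant to
it. Rate smoothing and tree inference are out of scope.

## Rank comparison

Two ranking conventions coexist deliberately. Priority lists are presented
with *dense* ranks (tied species share a rank; the next distinct score takes
the next integer). The concordance statistics use *midranks*, as their tie
corrections require: `kendall_w()` implements the two-judge $W$ with the
standard tie correction
($W = 12S / (m^2(n^3-n) - m\sum T_j)$, $m=2$), and `spearman_rho()` is the
Pearson correlation of midranks with the large-sample $t$ approximation for
its p-value. For untied rankings $W = (1+\rho)/2$ exactly, an identity the
suite verifies over a thousand random permutations.

`topk_overlap()` compares the *k best-ranked species* of two lists: the cut
is positional, extended only when a tie straddles the $k$-th position. With
dense ranks this matters — a list can print 21 species over ranks 1–20 when
two species share an internal rank, and the positional rule still yields a
20-species top-20 in that case. This is the reading under which the bundled
published top-20 lists (`chile_top20_ranks()`) reproduce a 13-species (65%)
overlap of RED with every EDGE scheme, and 13 species common to all five
lists.

The comparison universe is evaluated species only: RED is computed for all
species, but its validation against EDGE is meaningful only where EDGE
exists.

## Synthetic data

The generators in `simulate_*()` emulate the structure the analysis
assumes, so the full pipeline is testable without any external downloads:

* `simulate_tree()`: a pure-birth genus backbone with log-normally skewed
  genus sizes; each multi-species genus tip is replaced by a pure-birth
  subtree whose crown sits partway down the genus stem, giving
  genus-monophyletic, ultrametric trees calibrated to depth 100. Pure-birth
  is the simplest ultrametric generator; the indices depend only on the
  realized tree.
* `simulate_ranges()`: log-normal range sizes (default meanlog 1.5, sdlog
  1.2 — median ≈ 4.5 cells with a long right tail, a typical
  endemic-flora skew) placed as contiguous blocks in a 20 × 80-cell
  extent, a long narrow band of 0.5° cells. Contiguous blocks create nested
  unions on internal branches, exercising the range-weighting machinery
  harder than scattered cells would.
* `simulate_statuses()`: exactly 7 CR, 54 EN, 23 VU, 7 NT and 4 LC over 95
  evaluated species by default, the remainder not evaluated. With
  `couple_to_range = TRUE`, severity follows ascending range size, the
  regime in which geographic rarity is informative about threat.

Default problem sizes for the end-to-end recovery experiment are 200
species (95 evaluated), a quarter of the species withheld for within-genus
imputation, 5 replicate trees per run and 20 seeds per condition — large
enough for stable rank statistics at $n = 95$ while keeping the whole
experiment comfortably fast. Under range-coupled threat the median Spearman
correlation between median-RED and median-EDGE ranks across seeds is
required to reach at least 0.6 (an artifact-level acceptance constant, not
an external claim) and to exceed the uncoupled control; observed values sit
near 0.86 versus 0.50.

What the synthetic data do *not* emulate: spatial autocorrelation of
diversification, island/continent structure, coastline clipping of the
grid, and any correlation between clade age and range size. Passing the
recovery test therefore shows the machinery behaves as designed under the
stated coupling, not that RED will track EDGE for any particular real
flora.

## Numerical choices and degenerate inputs

* Ultrametricity is asserted at relative tolerance `1e-6`; replicate trees
  re-enter downstream steps with accumulated float error well below it.
* Zero-length target branches cannot be bisected (hard error), and species
  with zero occurrence cells are a hard error by default —
  `assume_range_one` assigns a private single cell instead, with a warning,
  because silently dropping species would corrupt internal-branch unions.
* Ranks break score ties by sharing the rank; `dense_rank()` is invariant
  under strictly increasing transforms of the scores.
* A root edge in the input Newick is discarded: it adds equally to every
  tip and cancels in all rankings.
* Medians use the mean-of-central-pair convention for even replicate
  counts.

## Limitations

RED substitutes range for threat; where threat is driven by factors other
than rarity (disease, harvesting, habitat quality) it will misrank, and the
published comparisons suggest its agreement with EDGE weakens below the top
few dozen ranks. EDGE should always be preferred once categories exist.
Heightened-EDGE and EDGE2-style methods, which account for the extinction
risk of close relatives, are out of scope, as is model-based phylogenetic
placement of missing species.
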