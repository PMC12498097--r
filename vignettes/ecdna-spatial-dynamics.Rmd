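---
title: "Spatial ecDNA dynamics: model, sampling, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial ecDNA dynamics: model, sampling, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdnasim)
```

## The model

Extrachromosomal DNA (ecDNA) circles carry amplified oncogenes but no
centromere, so at mitosis they are not partitioned faithfully: the mother's
$c$ copies replicate to $2c$ and each copy independently joins either
daughter with probability $1/2$ (binomial partitioning). This single
mechanism generates the extreme cell-to-cell copy-number heterogeneity seen
in ecDNA-positive tumors, and it interacts with selection and with the
spatial structure of a growing tumor.

`ecdnasim` grows tumors on a two-dimensional square lattice, one cell per
site, starting from a single founder at the origin carrying `k` ecDNA
copies. Three parameters control the dynamics:

* **`k`** — founder ecDNA copy number. Large `k` means ecDNA accumulated
  before the clonal expansion began; `k = 1` means the expansion started
  with the ecDNA-forming event itself.
* **`s`** — selection coefficient under a *constant selection* model:
  cells with at least one ecDNA copy divide at rate $1+s$, ecDNA-free
  cells at rate $1$, independent of how many copies a cell carries. The
  base division rate fixes the time unit; `s = 2` means ecDNA-positive
  cells divide three times as fast as ecDNA-free cells, a 200% increase.
* **`q`** — pushing range, in lattice units. A dividing cell may displace
  the contiguous run of occupied sites along one of its 8 lattice (Moore)
  directions by one step, provided the nearest empty site on that ray lies
  within `q` steps. `q = 1` confines division to cells with an empty
  neighbor (boundary growth); `q = Inf` removes the constraint. The values
  `1, 2, 5, 10, 50, 1000` span the regimes from strict boundary growth
  through strong (`2, 5`) and weak (`10, 50, 1000`) spatial constraint.

Events are drawn by rejection-free kinetic Monte Carlo
(Bortz–Kalos–Lebowitz): each cell contributes its division rate and a
death rate `d` (default 0), an event is picked with probability
proportional to its rate, and time advances by an exponential waiting time
with mean one over the total rate. A division whose every direction is
blocked is consumed without a birth — rates stay state-independent between
events, which keeps the draw rejection-free; whether a blocked mother
should redraw another direction is not observable in any of the model's
outputs at `q`'s extremes, and aborting is the simplest consistent
reading. Runs stop at `n_final` cells (default $10^4$; extinction under
`d > 0` is reported as an outcome, not an error).

The well-mixed engine (`run_well_mixed()`) removes the lattice: identical
division and segregation rules, every division succeeds. It is both the
weak-constraint limit of the spatial model and the reference against which
the spatial engine is validated (at `q = 1000` the two agree within
Monte-Carlo noise). An optional fixed-passage mode subsamples the
population back to `n0` cells after a set number of doublings, emulating
serial cell culture; it is off by default since the tumor-expansion regime
has no carrying capacity.

### Choices fixed by the implementation

* **Neighborhood and pushing geometry.** Moore (8-direction) rays; the
  displaced run moves one step outward toward the nearest empty site; ties
  among eligible directions break uniformly at random. This is the
  simplest geometry in which `q = 1` reduces exactly to boundary growth.
* **Mother/daughter placement.** The mother keeps its site; the daughter
  takes the newly opened adjacent site. The binomial split is symmetric,
  so assigning share A to the mother is a convention without consequence.
* **Lattice bounds.** A bounded square with half-width
  `ceiling(2 * sqrt(n_final / pi)) + 10` — twice the radius of a fully
  compact tumor — with a runtime check that errors if any cell would
  reach the boundary.
* **Reproducibility.** All randomness flows through R's session RNG; every
  run accepts a `seed` and records it in its outputs.

## Spatial sampling

Multiregion FISH measurements are emulated by circular samples
(`sample_circular()`): the radius around a center grows until at least
`n` cells are enclosed, then exactly `n` are subsampled uniformly without
replacement. The **core** is centered on the founder's coordinates.
**Infiltrating margins** (10 per tumor by default) are centered on the
occupied cell nearest to a point at 75% of the tumor radius — the maximum
founder-to-cell distance — at a uniformly random angle; an angle with no
occupied cell within 3 lattice units of its target is redrawn. The
**leading edge** uses fraction 0.95; because a target that close to the
*maximal* radius overshoots the irregular tumor boundary at most angles,
its center is clamped to the most peripheral occupied cell toward the
drawn direction rather than being subjected to a fixed tolerance. The 0.95
fraction itself is this package's convention: the leading edge is the most
peripheral region distinguishable from the margin, and any fraction
materially above 0.75 encodes that; results are insensitive to the exact
value because the center is boundary-clamped anyway.

Before distribution comparisons, cells with fewer than 3 total copies are
removed from both simulated and observed samples (`filter_min_copies()`),
mirroring the filter used on patient FISH data to exclude non-tumor
cells. Positive-cell fractions are always computed on unfiltered counts.

```{r example-sim}
st <- run_tumor(sim_config(k = 20, s = 1, q = 5, n_final = 5000, seed = 1))
st
core <- core_sample(st, 300, seed = 2)
margin <- margin_samples(st, 300, count = 1, seed = 3)[[1]]
wasserstein1d(filter_min_copies(core)$counts,
              filter_min_copies(margin)$counts)
```

## ABC inference

`abc_rejection()` fits `(k, s, q)` to observed per-region copy-number
distributions by rejection sampling. Per draw: parameters are sampled from
a uniform grid prior (`prior_grid()`, defaults `k` in `1:150`, `s` in
`seq(0, 4, 0.25)`, `q` in `{1, 2, 5, 10, 50, 1000}`), one tumor is grown,
a core and 10 margin samples are taken size-matched to the observed
regions, and the core is paired with each margin. A pair is accepted when
**every** region individually passes two gates: Wasserstein distance
between filtered copy distributions at most `eps_region`, and
ecDNA-positive-fraction difference (unfiltered) at most `delta_fraction`.
The positive fraction enters as a hard gate, not a distance summand, so
the recorded total distance $\sigma$ — the sum of per-region Wasserstein
terms — remains a pure distribution distance. `posterior_summary()`
reports each parameter's marginal mode with the central 68% of accepted
values as an asymmetric interval (`mode -lo +hi`).

Numerical conventions worth knowing:

* `wasserstein1d()` is the first Wasserstein distance between empirical
  distributions, computed as the integral of the absolute ECDF difference;
  for size-matched samples this reduces to the mean absolute difference of
  the sorted values. A region with nothing left above the copy filter gets
  distance `Inf` — it can never be accepted, and shows up as such in the
  diagnostics attached to an empty posterior.
* Acceptance is monotone in both thresholds: loosening them never removes
  an accepted pair under the same seed.
* The default `eps_region = 5` makes an accepted core–margin pair satisfy
  $\sigma < 10$. For *parameter-recovery experiments* at desk scale we use
  `eps_region = 3`: with $10^4$-cell tumors and 300-cell regions the
  default accepts roughly a quarter of all candidate pairs, far from the
  sub-percent acceptance rates at which rejection ABC approximates the
  posterior, whereas `eps_region = 3` accepts a few per thousand.
* Because W₁ scales with the magnitude of the copy numbers, no fixed
  threshold suits a 5-copy and a 140-copy tumor alike. Setting
  `accept_fraction` switches to quantile-based acceptance — keep the
  closest fraction of candidate pairs, ranked by their worst per-region
  distance among pairs passing the positive-fraction gate — the standard
  self-calibrating form of rejection ABC; the realized threshold is
  reported alongside the results.

### Desk-scale problem sizes

Cluster-scale inference in this problem domain runs millions of simulated
tumors of $10^6$ cells per patient. The package's defaults are sized for a
single CPU: tumors of $10^4$ cells, budgets of a few thousand simulations,
and region samples of ~300 cells. Two geometric consequences of the
scale-down matter when designing recovery experiments:

* Region samples must stay *small relative to the tumor* (here ~3% of
  cells). Patient-sized regions of ~1,400 cells would each cover a seventh
  of a $10^4$-cell tumor, overlap each other, and erase the core-versus-
  margin signal that identifies `q`.
* The spatial-constraint parameter is intrinsically harder to pin down at
  $10^4$ cells than at $10^6$: a pushing range of 5 is small against a
  tumor radius of ~560 but moderate against ~56, so desk-scale tumors at
  `q = 5` are less sectored than their full-scale counterparts, and the
  weak-constraint candidates `{10, 50, 1000}` fit a given realization more
  often than they would at scale. `k` is robustly recovered regardless,
  because the copy-number distribution's location is dominated by the
  founder count under constant selection.

Because all 10 core–margin pairs of one simulated tumor share that tumor's
parameters, `posterior_summary()` can be applied to the accepted *pairs*
(the recorded unit) or to the unique accepted *simulations*; the package
records pairs, and summarizing unique simulations avoids giving spatially
homogeneous tumors — whose margins all resemble each other, so all 10
pairs tend to pass together — up to ten votes where a sectored tumor gets
one or two.

## Wild-type / variant heteroplasmy

`run_variant_sim()` tracks two copy types per cell: wild type and an
activating variant arising on the same ecDNA backbone (the
EGFRwt/EGFRvIII situation). The variant either exists in the founder
(`kvar > 0`, `vvar = 0`) or arises when the population first reaches
`vvar` cells, by converting one wild-type copy chosen with probability
proportional to each cell's wild-type count — mutation converts copies,
never creates or destroys them, so per-type conservation holds at every
event. The two types segregate independently; fitness is dominated by the
variant (`1 + s_var` with any variant copy, else `1 + s_wt` with any
wild-type copy, else 1), encoding a strongly advantageous variant under
copy-number-independent selection. With equal selection and no mutation,
expected heteroplasmy — the wild-type percentage of all copies — stays at
its initial value `100 * kwt / (kwt + kvar)`.

`covariegation_probability()` measures how often the variant is detected
in both a core and a random margin sample across replicate tumors: early
variants (small `vvar`) sweep the whole tumor; late variants remain
spatially variegated. `mutation_origin_distribution()` runs wild-type-only
well-mixed growth in which each newly replicated copy mutates with
probability `mu`, and records the wild-type abundance of the cell
receiving the first variant copy; mutation-origin questions concern
precancerous accumulation before spatial expansion, which is why the
well-mixed engine is the default there. When the mutation falls among the
founder's `k` copies the recorded abundance is `k - 1`; at a later
division it is the wild-type share inherited by the daughter that receives
the variant — the cell that would seed the ensuing clonal expansion.

## Two ecDNA species

`run_two_species()` models two distinct ecDNA species with two coupling
mechanisms. **Cosegregation** (`cosegregate()`): after duplication,
`round(rho * min(2 c1, 2 c2))` cross-species pairs each follow a single
fair coin, unpaired copies segregate independently; `rho = 0` recovers
independence, `rho = 1` with equal counts forces identical splits, and
per-species conservation holds for every `rho`. The pairing mechanism and
its `[0, 1]` parameterization are this package's construction, chosen for
exact conservation and clean limits; pair counts round half to even.
**Coselection** enters through the fitness rule: `1 + s_p` for cells with
exactly one species, `1 + s_m` for mixed cells. With `k2 = 0` the engine
reduces exactly to the single-species model at `s = s_p`.

For two-species observations, `abc_rejection()` applies the Wasserstein
gate to each species' marginal distribution and adds the mixed-cell
fraction gap as an extra acceptance gate at `delta_fraction`; $\sigma$
sums the marginal Wasserstein terms. The joint prior covers `k1` (and
`s_m` through the prior's `s`), with `k2`, `s_p`, and `rho` supplied as
fixed values — in practice the second species' founder count comes from
its own single-species inference, and a two-dimensional `k` grid would
waste most of a desk-scale budget.

## The synthetic-patient generator

`generate_synthetic_patient()` simulates one tumor under known truth
parameters and emits per-region per-cell copy tables in the same CSV
schema used for real FISH-derived counts, plus a YAML sidecar carrying the
truth, the seed, and the data file's checksum. It emulates what the
downstream inference consumes — integer foci counts per nucleus, grouped
by region — and nothing about the measurement process itself: no
segmentation error, no probe inefficiency, no foci clustering, no
non-tumor-cell contamination (the <3-copy filter exists because real data
need it; synthetic counts are exact). Recovery experiments built on it
therefore test the inference machinery under the model's own assumptions,
not robustness to FISH measurement artifacts.

## Known limitations

The model is deliberately minimal: two-dimensional growth, constant
selection independent of copy number, no microenvironment, no chromosomal
co-alterations, parameters fixed over time. The leading-edge sampling
fraction and the cosegregation parameterization are package conventions
(the corresponding quantities are not fixed by the biology). At
desk-scale sizes the spatial-constraint parameter is only coarsely
identified, as discussed above; conclusions about `q` from $10^4$-cell
runs should be read as strong-versus-weak constraint, not exact values.
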