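---
title: "The foundress model: multilevel selection for cooperative colony founding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The foundress model: multilevel selection for cooperative colony founding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foundress)
library(dplyr)
```

## The biological question

In most harvester ant populations a new colony is founded by a single queen
(haplometrosis). In some populations of *Pogonomyrmex californicus*,
however, groups of unrelated queens excavate and provision a nest together
(pleometrosis), and those queens are behaviourally *tolerant* of one
another. Tolerance is costly inside a group — an *aggressive* nestmate that
attacks her co-foundresses tends to outlive them — so ordinary
individual-level selection should eliminate it. Cooperative founding can
nevertheless spread if groups containing only tolerant queens outperform
groups with aggressors when colonies compete with one another: a
multilevel-selection scenario in which the between-group advantage outweighs
the within-group disadvantage.

`foundress` implements a generational agent-based model of this scenario,
the contingency-table and survival statistics used to summarise foundress
experiments, a Monte Carlo quadrat test for spatial clustering of colonies,
and seed-deterministic generators for every synthetic input the pipeline
needs.

## The model

Each generation has two phases on an `n_side` x `n_side` toroidal lattice
in which each cell is a suitable nest site with probability `p_suitable`.

**Foundation phase.** `m` new queens (a fraction `x_c0` cooperative) land
on uniformly chosen suitable cells, then cluster: in a uniformly random
order, each queen moves to the suitable cell within toroidal distance
`r_cluster` of her position that holds the most *other* queens at that
moment (her own cell is a candidate; ties between equally full cells break
uniformly at random; a queen with nobody in reach stays put). Queens that
share a cell form a foundress association. Every unordered pair of
co-founding queens is then evaluated once, in random order, skipping pairs
with a dead member. An aggressive queen initiates a fight with probability
`p_initiate`; cooperative queens never initiate. Every fight kills exactly
one queen: two aggressors flip a fair coin, and in a mixed fight the
aggressor dies with probability `p_death_aggressor = 0.40`, the cooperator
otherwise (0.60) — mortalities taken from staged encounters between the
two phenotypes.

**Growth phase.** The survivors of each occupied cell form one colony.
A colony of `x` queens has competitive potential

$$s(x) = x \, e^{1 - x/6},$$

zero at zero queens, increasing to a peak at six queens and declining
beyond it. The peak reflects the faster workforce build-up of co-founding
queens, and the decline the crowding costs reported for very large
associations; the exact functional form used in the original simulation is
not published, so this closed form was chosen as the simplest one with
those properties, and `model_params(productivity_fun = )` accepts a
replacement. Two colonies compete when their territories of radius
`r_territory` overlap (centre distance at most `2 * r_territory`; the
alternative `center-in-disk` reading, distance at most `r_territory`, is
available via `overlap_rule`). Overlapping pairs are resolved nearest
first (equal distances in random order), skipping pairs with an eliminated
member: colony 1 wins with probability `s(x1) / (s(x1) + s(x2))` and the
loser's queens all die. No two surviving colonies overlap.

**Reproduction.** Every surviving colony contributes an equal share of the
next generation regardless of its queen number, so the landscape-level
cooperative share is the unweighted mean of per-colony cooperative
proportions. `m` offspring are drawn cooperative at that share, each
switching phenotype independently with probability `p_mutate`, and the
cycle repeats for `n_generations`. Because mutation keeps literal fixation
out of reach, a phenotype is scored as fixed when its share at the final
generation reaches `fixation_threshold` (default 0.95).

## Choosing the unpublished parameters

The fight-initiation probability and the mutation rate have no published
point values. They matter, and one of them is structurally constrained.

If every pair fights whenever an aggressor is present (`p_initiate = 1`),
then at the end of the foundation phase any association that contained an
aggressor has either exactly one surviving queen or only cooperators left:
any two living queens of which one is aggressive would still have to
fight. One can then compute the fate of a rare cooperator exactly. Let
`t(k)` be the probability that the single cooperator in an association of
`k` queens survives the melee; enumeration and simulation give
`t = 0.40, 0.24, 0.12, 0.014` for `k = 2, 3, 5, 20`. When cooperators are
rare, the expected number of cooperative colonies produced per cooperative
queen is `k * t(k)`, and this is below 1 for *every* `k`. A rare tolerant
phenotype therefore cannot invade at any radius or density under certain
initiation — the dynamics are bistable, and starting from a 5% share the
aggressive type always wins. That contradicts the empirically motivated
regime this model exists to explore, in which tolerance spreads from
rarity once interaction radii or densities are large enough.

With moderate initiation probabilities the picture changes qualitatively:
mixed associations no longer annihilate, surviving tolerant queens carry
their groups' numerical advantage into the growth phase, and the selection
map favours rare cooperators at large radii while staying neutral-to-
negative at radius zero. Sweeps over `p_initiate` in 0.1–0.5 all show the
threshold switch; the default is fixed at `p_initiate = 0.25`. The
mutation rate is set to `p_mutate = 0.005` so that, at the default desk
scale (`m` up to 500, 50 generations), a handful of mutants per generation
keeps outcomes stable rather than path-dependent, which is the stated
purpose of mutation in this model class.

## Desk-scale study design

The full published protocol (a 100-cell torus, 200 generations, 100
replicates for each of 10 x 10 radius combinations at three population
sizes) is a configuration choice away, but the package's default sweep is
sized for a desk machine: a 50-cell torus, 50 generations, 20 replicates,
tied radii `r_cluster = r_territory` over {0, 1, 2, 4, 8, 16} cells, and
cohort sizes `m` of 125, 250 and 500 (densities 0.05–0.2 queens per cell,
matching the published densities at the larger lattice). At this scale the
model reproduces the qualitative result: no tolerant fixation at radius 0,
fixation in 80–90% of replicates at the largest radius and highest
density, and interpolated threshold radii that shrink as density grows
(about 7, 3.4 and 2.9 cells in a seed-42 sweep).

```{r, eval = FALSE}
spec <- sweep_spec(seed = 42)         # desk-scale defaults as above
sw   <- run_sweep(spec)               # ~1 minute on one core
summarize_sweep(sw)
estimate_threshold(sw, m = 500)
autoplot(sw)
```

Randomness is controlled by one root seed per run; the landscape, the
initial cohort and every generation draw child seeds from it in a fixed
order, so any `(params, seed)` pair reproduces bit for bit, and sweep
replicates receive independent child seeds drawn once from the sweep seed
(replicates are exchangeable by construction).

## Empirical statistics

`pearson_chisq()` is the classic uncorrected Pearson statistic with
margin-based expectations and an upper-tail chi-square p-value. No Yates
continuity correction is applied at any table size; many libraries
silently correct 2x2 tables, which does *not* reproduce the uncorrected
statistics quoted for the foundress data (23.9 for the field group-size
comparison, 14.8 for the population comparison — both recomputed exactly
by `foundress_fixtures()` plus `pearson_chisq()`).

`aggression_table()` tabulates aggressive-phenotype counts by source
population and treatment; the all-groups rows aggregate the group
treatments only, since aggression toward co-foundresses is undefined for
solitary queens. Proportions are rounded to two decimals only in the
display column, never in computation. One published display value (3/19 =
0.158 shown as 0.15) is a truncation rather than a rounding; the package
reports 0.16. `aggression_death_fraction()` reports the share of deaths
attributable to aggression (the "severed head or abdomen" criterion in the
laboratory), rounded to a whole percent at the reporting layer.

`kaplan_meier()` and `log_rank()` are standard product-limit and
two-sample log-rank utilities for inspecting synthetic experiments, with
censoring only at the 60-day horizon. The mixed-effects proportional-
hazards models used for the real laboratory analysis are deliberately out
of scope.

## The quadrat test

`quadrat_mc_test()` splits the rectangular window into equal-area
half-open quadrats, computes `sum((O - E)^2 / E)` with a uniform `E`, and
compares it with the statistic's distribution under complete spatial
randomness, simulated at the same point count. A Monte Carlo reference is
used because quadrat expectations are routinely below 5, where the
chi-square approximation fails. The p-value is the plus-one estimator
`(1 + #{sim >= obs}) / (n_sim + 1)`, valid by construction, with floor
`1/(n_sim + 1)` (0.0005 at the default 1999 simulations). The default
alternative is the upper tail — clustering inflates the statistic, and
clustering is the scientific question — with a two-sided option for
detecting regularity. `quadrat_size_scan()` repeats the test over a list
of quadrat grids without multiplicity adjustment, flagging whether every
size rejects; irregular windows and inhomogeneous null models are out of
scope.

## Synthetic data

`simulate_foundress_experiment()` emulates the five-treatment laboratory
design (21 + 29 solitary queens, 20 mixed pairs, 30 pure groups of six,
19 mixed groups of 5+1, 60 days). Each queen draws the aggressive
phenotype with her source population's probability (0.33 haplometrotic,
0.11 pleometrotic). Mortality runs day by day: each living aggressive
queen attacks a living tolerant nestmate with daily probability 0.045
(the attacker dying with probability 0.40, her victim otherwise), on top
of a baseline daily hazard of 0.012 from all other causes. The two hazard
constants were calibrated once, by simulation, so that roughly 60% of
queens die within the horizon and aggression accounts for about 20% of
deaths — the two summary anchors available for the real experiment — and
then frozen. Day-level pairwise attacks (rather than the model's one-shot
melee) give the records the daily resolution of laboratory survival data.

What the generator does *not* emulate: brood production, the dependence of
aggression on nest excavation stage, heterogeneity between groups beyond
composition (no group-level random effects), and any within-day ordering
of events. Tests that pass on these records therefore validate the
package's statistics and plumbing, not the biology of the real
experiment; in particular the real survival curves are not reproduced,
only their gross mortality structure.

`simulate_point_pattern()` provides the fixed-count uniform null ("csr")
and a parent–offspring (Thomas-like) clustered process — uniform parents,
Gaussian dispersal, out-of-window displacements redrawn — the minimal
generator whose clustering a quadrat test should detect. With
`dispersal_sd = 0` all offspring sit on their parents, the most extreme
clustering possible at a given parent count.

## Numerical conventions and degenerate inputs

* Distances are Euclidean between cell centres with toroidal wraparound;
  radius comparisons use `<=`, and a radius of 0 legally disables
  clustering or competition.
* In the clustering rule a tie at a count of zero resolves to "stay",
  preventing diffusive drift of isolated queens; ties at positive counts
  are uniform draws.
* `p_death_cooperator` must equal `1 - p_death_aggressor`: exactly one
  queen dies per fight, so the two mortalities are complements by
  construction.
* Zero suitable cells with queens to place, empty foundress groups,
  zero-margin contingency tables, experiments with no deaths, zero-area
  windows and patterns with no points are all rejected with explicit
  errors rather than propagating NaNs.
* Extinction (no surviving colony) is recorded in the run result, not
  raised, and cannot occur while any queen survives the growth phase.

## Known limitations

The model is a lattice abstraction: no continuous space, no within-season
colony growth (workers appear only through `s(x)`), no brood raiding
beyond the contest rule, and offspring disperse globally rather than near
their natal colony. The threshold estimates from desk-scale sweeps carry
Monte Carlo error of a few tenths of a cell and interpolate linearly
between grid radii. The synthetic generators are calibrated to printed
summary numbers, not fitted to raw data, and the exact threshold radii of
the original large-scale simulation are not reproduced here — only the
existence of the switch and its ordering with density.
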