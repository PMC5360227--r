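---
title: "Methods: networks, knockouts and inference in troopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: networks, knockouts and inference in troopnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troopnet)
```

`troopnet` implements a complete analysis chain for the question *what does
excluding an age class do to an animal social network?* — from raw
focal-sampling records to networks, metrics, knockout simulations and
rank-based inference. This vignette documents the model, the tunable
parameters, the numerical choices, what the synthetic generator does and
does not emulate, and the known limitations.

## From records to networks

Focal-animal sampling yields, per focal hour, dyadic events: grooming
bouts (with durations) and agonistic acts (counts). Two conventions govern
network construction:

* **Bout merging.** A grooming bout interrupted for at most `gap_s = 30`
  seconds continues the same bout; its duration is the sum of groomed
  seconds (gap time excluded). A change of partner or direction always
  starts a new bout. Merging groups events by directed dyad after sorting
  by (actor, recipient, start time); a consequence is that a same-dyad
  interruption *by a third party* shorter than the threshold still merges.
  This keeps the engine's invariant that splitting a bout into sub-events
  with sub-threshold gaps never changes an edge weight, which exact
  cross-dyad splitting would break.
* **Rate normalisation.** Edge weights are hourly rates. Whose hours make
  the denominator is genuinely open in the field literature; the default
  is the dyad's combined focal hours, `H = hours(i) + hours(j)`, because a
  dyadic interaction is observable while either member is the focal
  animal. `actor_hours` and `total_hours` are selectable, and all
  downstream machinery is agnostic to the choice.

Networks are directed and weighted; isolated study subjects stay in the
node set with zero degree, because out-degree zero is itself a finding.
Symmetrisation — used for total degree and all clustering — adds the two
directed weights of a dyad and is idempotent.

## Metrics and the alpha convention

Weighted measures follow the generalised-degree framework: a tuning
parameter `alpha` in `[0, 1]` sets the weight of tie *presence* against
tie *strength*. Strength is the `alpha = 1` endpoint; binary degree is
`alpha = 0`; betweenness uses `alpha = 0.5` by default so both aspects
count equally. Concretely, the cost of traversing an edge of weight `w`
is `(1/w)^alpha`, and betweenness counts, over all ordered pairs of other
nodes, the fraction of minimal-cost paths through each node (Brandes
accumulation over *all* minimal paths, raw and unnormalised; unreachable
pairs contribute nothing).

Numerical choices:

* **Cost ties.** Real-valued costs make exact shortest-path ties fragile.
  Two path costs are treated as equal when they differ by at most a
  relative `1e-10`; the test suite checks the implementation against an
  exhaustive path-enumeration oracle on random digraphs of up to 7 nodes.
* **Clustering.** The weighted local coefficient is the triplet-value
  share of closed triplets centred on a node, computed on the symmetrised
  network. The triplet value combines the two tie weights at the centre;
  the combination method (arithmetic mean by default, geometric mean, max
  or min) is exposed because the literature does not fix it. No alpha
  enters clustering. Nodes with fewer than two partners have an undefined
  coefficient and are *excluded* from the mean rather than scored zero —
  scoring zero would conflate "cannot close a triangle" with "closes
  none".
* **Density and centralisation.** Density defaults to directed ties over
  `n(n-1)` (a symmetrised variant is available). Centralisation is
  Freeman's index on the symmetrised binary graph with denominator
  `(n-1)(n-2)`, which attains exactly 1 on a star and 0 on any regular
  graph, and needs at least 3 nodes.

## Knockout simulations

Removal means node deletion with incident edges; surviving weights are
untouched, because hourly rates are dyad-level quantities that do not
depend on group size. Three schemes:

1. **Targeted, exhaustive.** Every size-`r` subset of the target class at
   each step `r`, i.e. `choose(n_target, r)` replicate networks — no
   sampling error within a step.
2. **Random control** for the size reduction per se: 500 uniformly random
   subsets per step, *except* that whenever `choose(n, r)` is below the
   budget all subsets are enumerated exactly once (pseudoreplication
   would otherwise overweight the tiny subset spaces of the first steps).
   Subsets are drawn independently across replicates, so repeats across
   replicates are possible in the sampled regime — matching a "repeat the
   procedure 500 times" design.
3. **Class-effect removals**: random juvenile subsets (50 per step, same
   exhaustive fallback), tracking the mean weighted betweenness and mean
   clustering of each surviving focal class (adult males, adult females,
   subadult females by default; singleton classes are best excluded by
   the caller since a class mean of one animal is noise).

Step 0 (the intact network) is always included, giving the 11-level
step factor the downstream tests expect. Steps that would leave fewer
than 3 nodes are skipped with a warning (density and centralisation lose
meaning below that). Step summaries report mean and standard error
(sample SD over replicates / sqrt(replicates)).

## Inference

* **Selective node permutation** compares classes on a metric by
  enumerating all `choose(10, 5) = 252` five-member subsets per class and
  comparing the two subset-mean distributions with a rank-sum test. This
  is the classical design for this analysis and is reported as such, but
  subset means of overlapping subsets are dependent: the test is
  anti-conservative and its p-value is not a nominal error rate.
  `run_aim1()` therefore also reports a plain Mann-Whitney test on the
  raw per-individual values, which *is* nominal-level and is what the
  package's type-I calibration checks (the exact rank-sum test at
  10-vs-10 attains ~4.3% at nominal 5%, so calibration is asserted within
  [0.025, 0.075]).
* **Scheirer-Ray-Hare** is implemented from scratch: all values are
  ranked jointly with midranks, two-way sums of squares are computed on
  the ranks, and each effect's `H = SS_effect / MS_total` (with
  `MS_total` the rank variance, denominator `N - 1`) is referred to
  chi-square with the effect's df. With a degenerate second factor this
  reduces *exactly* to the tie-corrected Kruskal-Wallis H, which the test
  suite verifies to `1e-9` across random datasets.
* **Slope comparison** stacks two trajectory series and tests the
  step-by-series interaction, F with `(1, n_a + n_b - 4)` df — `(1, 18)`
  for two 11-point series. (Published analyses of this design sometimes
  print other df conventions that cannot be reconstructed from the series
  lengths; the convention here is stated rather than guessed.)
* **Bootstrap t comparisons** resample class members with replacement
  (N = 1000) and compare bootstrap-mean distributions with Welch's t.
  Bootstrap distributions understate between-class sampling variance, so
  these p-values are anti-conservative; the result carries a note saying
  so.
* No multiple-testing correction is applied anywhere by default (matching
  standard practice for this analysis); `holm_adjust()` is provided for
  users who want one.

## The synthetic troop

The generator's defaults state one fixed world, chosen once:

* **Composition** 3 adult males, 7 adult females, 4 subadult females,
  1 subadult male, 8 juvenile males, 2 juvenile females — the canonical
  25-subject study design with a 10-member juvenile class and a 10-member
  adult class, which the 252-combination permutation design assumes.
* **Effort** ~8 focal hours per individual (SD 0.52 h), normal truncated
  to positive.
* **Rates** Poisson bout/event counts per ordered dyad with mean
  `rate x dyad hours x multipliers`; lognormal bout durations
  (mean 150 s, sdlog 0.8). Baselines (0.0235 grooming bouts and 0.014
  agonistic events per dyad-hour) are calibrated analytically so a
  default troop yields roughly 320 grooming bouts and 270 agonistic
  events in expectation — the scale of a three-month dry-season study —
  as a sanity anchor, not a fitted quantity.
* **Planted class structure**, as positive multipliers (1 = no effect):
  juveniles start twice the bouts (each proportionally shorter, so
  outreach redistributes rather than inflates grooming time); grooming
  *directed at* juveniles is damped to 0.4 (juveniles are groomed by few
  partners, chiefly their mothers — this damping is what makes juvenile
  removal *increase* density, since an outreach-only juvenile class would
  be denser than average); juveniles receive twice the aggression; adults
  initiate 2.5x the aggression; female actors groom twice as much; and
  adult-male-juvenile interaction of either kind is damped to 0.25
  (adult males rarely groom or fight juveniles), which is what makes the
  adult-male betweenness trajectory the flattest under juvenile removal.

What the generator does **not** emulate: kinship (mother-offspring
concentration appears only implicitly through the class-level received
damping, so the empirical pattern "juvenile in-strength comparable to
adults despite low in-degree" — grooming time concentrated on mothers —
is not reproduced); dominance hierarchies; temporal autocorrelation of
bouts within a follow; observation bias. A green pipeline test therefore
establishes that the machinery recovers class-structured signals planted
at realistic scale — not that any particular field system behaves this
way.

## Degenerate inputs and edge cases

Constant responses yield `H = 0, p = 1` flagged degenerate rather than
errors; empty classes after removal yield `NA` class means; grooming
events lacking durations, self-interactions, unknown ids, non-positive
hours and unsorted bout streams are rejected with the offending row or id
named. `n_combinations()` is exact integer arithmetic (multiplicative
algorithm; warns past `2^53`).

## Scaling and budgets

The heavy defaults (exhaustive removals: 1023 subsets per 10-member
target set; 500-iteration random controls) run in tens of seconds on one
CPU for a 25-node network because the global metrics are O(n^2)-ish
matrix operations. The unit-test suite uses scaled-down settings (fewer
iterations, shallower removals) and states so; the acceptance suite runs
the full-scale properties, using an endpoint proxy (intact vs all
juveniles removed) for per-troop slope signs in the 200-troop recovery
check, with the full 50-iteration trajectory machinery exercised on
single troops elsewhere.

## Known limitations

* Weighted betweenness is exact but O(n^3)-ish in pure R; fine for troop
  networks (tens of nodes), not for networks of thousands.
* The selective-permutation and bootstrap-t procedures are reported for
  design fidelity despite their anti-conservative p-values (see above);
  users should treat the raw-value Mann-Whitney column as the
  nominal-level comparison.
* Rates assume homogeneous dyads within a class pair (Poisson, no
  overdispersion); dyad-level heterogeneity can be approximated by
  adjusting `bout_sdlog` only for durations, not for counts.
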