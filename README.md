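# troopnet

Social network analysis of primate troops from focal-animal sampling
records, with node-knockout simulations that quantify how excluding an
age class — typically juveniles — distorts the apparent network structure
and the apparent social roles of the remaining age-sex classes.

Behavioural ecologists routinely build grooming and aggression networks
from focal follows but often drop juveniles for logistic reasons.
`troopnet` makes the consequences of that choice measurable: it builds the
directed, weighted networks, computes the standard individual and global
metrics, and compares networks with and without a target class through
stepwise knockout simulations and rank-based inference.

## The model

**Networks.** Nodes are study subjects; a directed edge `i -> j` carries an
hourly rate: grooming seconds per hour, or agonistic events per hour. The
default rate denominator is the dyad's combined focal hours
`H = hours(i) + hours(j)` (actor-hours and total-hours are selectable).
Grooming bouts interrupted for at most 30 s are merged before rates are
computed; a change of partner or direction always starts a new bout.

**Metrics.** Binary degree (symmetrised), in-/out-degree, in-/out-strength
(`s_i = sum_j w_ij`), and the alpha-tuned generalisations in which tie
presence and tie strength trade off through `alpha` in `[0, 1]`:

- generalised degree `k_i^(1-alpha) * s_i^alpha` (alpha = 0 counts
  partners, alpha = 1 sums weights);
- weighted betweenness: Brandes' algorithm over edge costs
  `(1 / w)^alpha`, default `alpha = 0.5` (ties and strengths weighted
  equally), raw and unnormalised;
- weighted local clustering on the symmetrised network: the triplet-value
  share of closed triplets centred on each node (arithmetic-mean triplet
  value by default), `NA` below two partners;
- global: density, Freeman degree centralisation
  `sum(d_max - d_i) / ((n-1)(n-2))`, and mean clustering.

**Knockouts.** Targeted removals enumerate every size-`r` subset of the
target class (`choose(n, r)` replicates per step); random controls draw
500 uniform subsets per step, switching to exhaustive enumeration whenever
`choose(n, r) < 500` to avoid pseudoreplication; class-effect removals
(50 iterations per step) track per-class mean betweenness and clustering.
Inference uses selective node permutation (all `choose(10, 5) = 252`
five-member subsets of a ten-member class), Kruskal-Wallis over removal
steps, the Scheirer-Ray-Hare rank-based factorial test, Mann-Whitney
post-hocs, slope comparisons of knockout trajectories, and bootstrapped
(N = 1000) class means with Welch t comparisons.

A synthetic focal-sampling generator (Poisson dyadic rates with
class-structured multipliers, lognormal bout durations) reproduces the
canonical 25-subject troop design so the whole pipeline is testable
without field data.

## Worked example

```r
library(troopnet)

ds   <- generate_study_dataset(seed = 1)   # 25-subject synthetic troop
nets <- build_study_networks(ds$events, ds$effort, ds$roster)
nets$grooming
#> <social_network> grooming, directed, 25 nodes, 218 ties

round(global_metrics(nets$grooming), 3)
#>        density centralization     clustering
#>          0.363          0.254          0.623

a1 <- run_aim1(nets)                       # juveniles vs adults
head(a1[, c("network", "metric", "juvenile_mean", "adult_mean",
            "permutation_p", "mann_whitney_p")], 4)
#>    network       metric juvenile_mean adult_mean permutation_p mann_whitney_p
#> 1 grooming    in_degree           5.6       10.5      2.82e-84        0.00292
#> 2 grooming   out_degree          10.3        8.0      1.18e-67        0.14846
#> 3 grooming  in_strength          44.2      123.3      4.97e-84        0.00013
#> 4 grooming out_strength          65.7      112.2      1.19e-79        0.05243

juv <- ds$roster$id[ds$roster$age_class == "juvenile"]
tr  <- knockout_targeted(nets$grooming, juv, r_max = 3)
head(summary(tr)[summary(tr)$metric == "density", ], 4)
#>    step  metric n_replicates  mean      se
#> 9     0 density            1 0.363 0.00000
#> 10    1 density           10 0.366 0.00241
#> 11    2 density           45 0.369 0.00150
#> 12    3 density          120 0.373 0.00109
```

Reading the output: in this simulated troop juveniles groom more partners
(out-degree 10.3 vs 8.0) but are groomed by fewer (in-degree 5.6 vs 10.5)
and invest less grooming time (out-strength 65.7 vs 112.2 s/h) — so
network density *rises* step by step as juveniles are removed (0.363 to
0.373 after three removals, with all `choose(10, r)` subsets evaluated at
each step). The permutation p-values compare the 252 subset-mean
distributions of the two classes (the classical procedure for this
design; anti-conservative by construction), while `mann_whitney_p` is a
nominal-level test on the raw individual values.

The full pipeline, including the Scheirer-Ray-Hare tables, slope
comparisons, bootstrap t-tables and betweenness rank changes:

```r
res <- run_pipeline(list(seed = 1, output_dir = "troopnet_out"))
```

or from the shell:

```sh
Rscript -e 'troopnet::troopnet_cli()' all --seed 1 --out troopnet_out
```

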