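Package: troopnet
Title: Social Network Analysis of Primate Troops with Knockout Simulations
Version: 0.1.0
Authors@R:
    person("Troopnet", "Developers", email = "troopnet@example.org",
           role = c("aut", "cre"))
Description: Builds directed, weighted grooming and aggression networks from
    focal-animal sampling records of a primate troop, computes individual and
    global network metrics (binary degrees, strengths, alpha-tuned weighted
    betweenness, weighted local clustering, density, Freeman degree
    centralisation), and quantifies the structural contribution of age-sex
    classes through stepwise node-knockout simulations (targeted exhaustive,
    random control, and class-effect removals). Inference tools include
    selective node permutation, bootstrap comparison of class means, the
    Scheirer-Ray-Hare rank-based factorial test, and slope comparison of
    knockout trajectories. A synthetic focal-sampling data generator with
    class-structured interaction rates makes the full pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
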