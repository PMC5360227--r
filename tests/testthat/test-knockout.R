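test_that("n_combinations is exact and guards its domain", {
  expect_identical(n_combinations(10, 4), 210)
  expect_identical(n_combinations(10, 5), 252)
  expect_identical(n_combinations(7, 0), 1)
  expect_identical(n_combinations(25, 12), choose(25, 12))
  expect_error(n_combinations(3, 4), "exceed")
  expect_error(n_combinations(-1, 0), "non-negative")
  expect_error(n_combinations(2.5, 1), "integer")
})

# 12-node fixture: a 5-clique core with 7 pendant nodes hanging off it.
pendant_fixture <- function() {
  core <- paste0("c", 1:5)
  pend <- paste0("p", 1:7)
  ee <- expand.grid(source = core, target = core, stringsAsFactors = FALSE)
  ee <- ee[ee$source != ee$target, ]
  ee$weight <- 1
  hang <- data.frame(source = core[rep(1:5, length.out = 7)], target = pend,
                     weight = 1)
  toy_net(rbind(ee, hang), ids = c(core, pend))
}

test_that("targeted knockout enumerates every subset exactly once", {
  net <- pendant_fixture()
  pend <- paste0("p", 1:7)
  traj <- knockout_targeted(net, pend, r_max = 4)
  reps <- tapply(traj$results$replicate[traj$results$metric == "density"],
                 traj$results$step[traj$results$metric == "density"], max)
  expect_equal(as.vector(reps[as.character(1:4)]),
               vapply(1:4, function(r) n_combinations(7, r), numeric(1)))
  # subsets all distinct
  for (r in 1:4) {
    subs <- traj$removed[[as.character(r)]]
    keys <- vapply(subs, function(s) paste(sort(s), collapse = "|"), "")
    expect_equal(anyDuplicated(keys), 0L)
  }
  # pendant removal can only densify: density strictly increases with step
  sm <- summary(traj)
  dens <- sm$mean[sm$metric == "density"]
  expect_true(all(diff(dens) > 0))
  expect_error(knockout_targeted(net, c(pend, "ghost"), 2), "ghost")
  expect_error(knockout_targeted(net, pend, 8), "r_max")
})

test_that("targeted knockout with r = |targets| leaves one replicate", {
  net <- pendant_fixture()
  traj <- knockout_targeted(net, paste0("p", 1:7), r_max = 7)
  last <- traj$results[traj$results$step == 7 &
                         traj$results$metric == "density", ]
  expect_equal(nrow(last), 1)
  core_net <- remove_nodes(net, paste0("p", 1:7))
  expect_equal(last$value, network_density(core_net))
})

test_that("random knockout falls back to exhaustive below the budget", {
  ds <- small_dataset()
  net <- build_study_networks(ds$events, ds$effort, ds$roster)$grooming
  traj <- knockout_random(net, r_max = 3, n_iterations = 500, seed = 1)
  res <- traj$results[traj$results$metric == "density", ]
  counts <- tapply(res$replicate, res$step, max)
  expect_equal(as.vector(counts[c("1", "2", "3")]), c(25, 300, 500))
  # C(25,1), C(25,2) < 500 -> exhaustive; C(25,3) = 2300 >= 500 -> sampled
  expect_true(n_combinations(25, 2) < 500 && n_combinations(25, 3) >= 500)
  # reproducibility
  traj2 <- knockout_random(net, r_max = 3, n_iterations = 500, seed = 1)
  expect_equal(traj$results, traj2$results)
  traj3 <- knockout_random(net, r_max = 3, n_iterations = 500, seed = 2)
  expect_false(identical(traj$results, traj3$results))
  expect_error(knockout_random(net, r_max = 23, seed = 1), "at least 3")
})

test_that("random removal preserves expected density", {
  ds <- small_dataset()
  net <- build_study_networks(ds$events, ds$effort, ds$roster)$grooming
  traj <- knockout_random(net, r_max = 5, n_iterations = 500, seed = 99)
  d0 <- network_density(net)
  res <- traj$results[traj$results$metric == "density" &
                        traj$results$step == 5, ]
  mc_se <- sd(res$value) / sqrt(nrow(res))
  expect_lt(abs(mean(res$value) - d0), 4 * mc_se + 1e-12)
})

test_that("knockout engine introduces no state leakage", {
  ds <- small_dataset()
  net <- build_study_networks(ds$events, ds$effort, ds$roster)$grooming
  juv <- ds$roster$id[ds$roster$age_class == "juvenile"]
  traj <- knockout_targeted(net, juv[1:4], r_max = 2)
  # a replicate's metrics equal metrics of an independently reduced network
  subs <- traj$removed[["2"]]
  for (k in c(1, 3, 6)) {
    indep <- global_metrics(remove_nodes(net, subs[[k]]))
    got <- traj$results[traj$results$step == 2 &
                          traj$results$replicate == k, ]
    expect_equal(stats::setNames(got$value, got$metric), indep)
  }
  # trajectories invariant to target-id ordering
  traj_rev <- knockout_targeted(net, rev(juv[1:4]), r_max = 2)
  expect_equal(traj$results, traj_rev$results)
})

test_that("class-effect knockout tracks per-class means with fallback", {
  ds <- small_dataset()
  net <- build_study_networks(ds$events, ds$effort, ds$roster)$grooming
  juv <- ds$roster$id[ds$roster$age_class == "juvenile"]
  traj <- knockout_class_effect(net, juv, r_max = 2, n_iterations = 50,
                                seed = 3)
  res <- traj$results
  # C(10,1) = 10 <= 50 -> exhaustive; C(10,2) = 45 <= 50 -> exhaustive
  expect_equal(max(res$replicate[res$step == 1]), 10)
  expect_equal(max(res$replicate[res$step == 2]), 45)
  expect_true(all(c("betweenness.adult_male", "clustering.subadult_female")
                  %in% res$metric))
  # full removal forces the single all-juvenile combination
  traj_full <- knockout_class_effect(net, juv, r_max = 10,
                                     n_iterations = 1, seed = 3)
  last <- traj_full$results[traj_full$results$step == 10, ]
  expect_equal(max(last$replicate), 1)
  reduced <- remove_nodes(net, juv)
  bt <- weighted_betweenness(reduced)
  am <- reduced$roster$id[age_sex_class(reduced$roster) == "adult_male"]
  expect_equal(last$value[last$metric == "betweenness.adult_male"],
               mean(bt[am]))
})

test_that("isolated-class betweenness stays flat when juveniles are removed", {
  # adult males form their own component; juveniles hang off females, so no
  # path to or from a juvenile can cross an adult male
  am <- paste0("am", 1:3); af <- paste0("af", 1:3); jv <- paste0("j", 1:4)
  edges <- rbind(
    data.frame(source = am, target = am[c(2, 3, 1)], weight = 1),
    data.frame(source = af, target = af[c(2, 3, 1)], weight = 1),
    data.frame(source = jv, target = af[c(1, 2, 3, 1)], weight = 1))
  ro <- as_roster(data.frame(
    id = c(am, af, jv),
    sex = c(rep("male", 3), rep("female", 3), rep("male", 4)),
    age_class = c(rep("adult", 6), rep("juvenile", 4)),
    is_study_subject = TRUE))
  net <- edgelist_network(edges, roster = ro)
  traj <- knockout_class_effect(net, jv, r_max = 4, n_iterations = 50,
                                seed = 1, classes = c("adult_male",
                                                      "adult_female"))
  sm <- summary(traj)
  am_bt <- sm[sm$metric == "betweenness.adult_male", ]
  expect_equal(diff(am_bt$mean), rep(0, nrow(am_bt) - 1))
})

test_that("betweenness rank table reports midranks and rank changes", {
  ds <- small_dataset()
  net <- build_study_networks(ds$events, ds$effort, ds$roster)$grooming
  tab <- betweenness_rank_table(net, net)
  expect_true(all(tab$rank_change == 0))
  expect_equal(attr(tab, "top_full"), attr(tab, "top_reduced"))
  # equal betweenness -> equal midranks (symmetric toy: leaves tie at 0)
  star <- toy_net(data.frame(source = c("S", "B", "S", "C", "S", "D"),
                             target = c("B", "S", "C", "S", "D", "S"),
                             weight = 1))
  tab2 <- betweenness_rank_table(star, star, top_n = 4)
  leaf_ranks <- tab2$rank_full[tab2$id != "S"]
  expect_equal(leaf_ranks, rep(3, 3))      # midrank of positions 2,3,4
  # removing the broker's feeder worsens the broker's rank
  # line a - b - hub - c, plus clique d,e,f connected to c
  edges <- rbind(
    data.frame(source = c("a", "b", "hub", "c"),
               target = c("b", "hub", "c", "d"), weight = 1),
    data.frame(source = c("d", "e", "f"), target = c("e", "f", "d"),
               weight = 1))
  roster <- as_roster(data.frame(
    id = c("a", "b", "hub", "c", "d", "e", "f"), sex = "female",
    age_class = c("juvenile", "juvenile", rep("adult", 5)),
    is_study_subject = TRUE))
  full <- edgelist_network(edges, roster = roster)
  reduced <- remove_nodes(full, c("a", "b"))
  tab3 <- betweenness_rank_table(full, reduced)
  hub <- tab3[tab3$id == "hub", ]
  expect_gt(hub$rank_change, 0)
  expect_error(betweenness_rank_table(reduced, full), "absent")
})
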