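# End-to-end analysis pipeline.
#
# aim 1: do juveniles and adults differ in individual network metrics?
# aim 2: does removing juveniles/adults/random individuals change global
#        network structure?
# aim 3: does removing juveniles affect age-sex classes differently?

#' Read a troop composition table
#'
#' A troop table lists every group member (including dependent infants and
#' unhabituated animals) with columns `id`, `sex`, `age_class` (which may
#' include `"infant"`) and `excluded_reason` (`"none"` for observable
#' animals). See [study_roster()] for the exclusion rules. A synthetic
#' reconstruction of the canonical 30-member study group ships with the
#' package (`system.file("extdata", "gashaka_troop_synthetic.csv",
#' package = "troopnet")`).
#'
#' @param path CSV path.
#' @return data frame of the full troop.
#' @export
read_troop_table <- function(path) {
  read_table_checked(path, c("id", "sex", "age_class", "excluded_reason"))
}

#' Apply study-subject exclusion rules to a troop table
#'
#' Dependent infants are not independently moving and are dropped from the
#' roster; any individual with a non-`"none"` exclusion reason (e.g.
#' unhabituated) is kept in the roster but flagged as a non-subject.
#'
#' @param troop a troop table (see [read_troop_table()]).
#' @return a roster whose study subjects are the observable, independently
#'   moving individuals.
#' @export
study_roster <- function(troop) {
  troop <- as.data.frame(troop, stringsAsFactors = FALSE)
  troop <- troop[troop$age_class != "infant", , drop = FALSE]
  as_roster(data.frame(id = troop$id, sex = troop$sex,
                       age_class = troop$age_class,
                       is_study_subject = troop$excluded_reason %in%
                         c("none", ""),
                       stringsAsFactors = FALSE))
}

#' Build both behavioural networks from raw records
#'
#' Merges interrupted grooming bouts, then builds the grooming and
#' aggression networks under a common normalisation.
#'
#' @param events raw event table (both behaviours).
#' @param effort focal-hours table or named vector.
#' @param roster the troop roster.
#' @param normalization rate denominator mode.
#' @param gap_s grooming bout-merge threshold (s).
#' @return list with `grooming` and `aggression` networks.
#' @export
build_study_networks <- function(events, effort, roster,
                                 normalization = "dyad_hours", gap_s = 30) {
  events <- as_events(events, roster)
  groom <- events[events$behaviour == "grooming", , drop = FALSE]
  groom <- groom[order(groom$actor, groom$recipient, groom$start_time_s), ,
                 drop = FALSE]
  groom <- merge_grooming_bouts(groom, gap_s)
  aggr <- events[events$behaviour == "aggression", , drop = FALSE]
  list(grooming = build_grooming_network(groom, effort, roster,
                                         normalization),
       aggression = build_aggression_network(aggr, effort, roster,
                                             normalization))
}

ids_of_age_class <- function(net, age_class) {
  net$roster$id[net$roster$age_class == age_class]
}

AIM1_METRICS <- c("in_degree", "out_degree", "in_strength", "out_strength",
                  "betweenness", "clustering")

#' Aim 1: juvenile vs adult individual metrics
#'
#' For each network and each of the six individual metrics, reports the
#' juvenile and adult means and observed ranges, the rank-sum p-value of
#' the selective-node-permutation comparison (all subset means of
#' `subset_size` members per class), and a plain Mann-Whitney p-value on
#' the raw individual values (a nominal-level test, unlike the permutation
#' comparison).
#'
#' @param networks list with `grooming` and `aggression` networks (see
#'   [build_study_networks()]).
#' @param subset_size permutation subset size (default 5).
#' @param alpha alpha for betweenness.
#' @return data frame, one row per network x metric.
#' @export
run_aim1 <- function(networks, subset_size = 5, alpha = 0.5) {
  rows <- list()
  for (net_name in names(networks)) {
    net <- networks[[net_name]]
    nm <- node_metrics(net, alpha)
    juv <- nm$id[nm$age_class == "juvenile"]
    adu <- nm$id[nm$age_class == "adult"]
    for (metric in AIM1_METRICS) {
      v <- stats::setNames(nm[[metric]], nm$id)
      vj <- v[juv]; va <- v[adu]
      flag <- ""
      perm_p <- NA_real_
      if (length(juv) >= subset_size && length(adu) >= subset_size &&
          !anyNA(vj) && !anyNA(va)) {
        dj <- suppressWarnings(
          selective_node_permutation(v, juv, subset_size))
        da <- suppressWarnings(
          selective_node_permutation(v, adu, subset_size))
        perm_p <- compare_class_distributions(dj, da)$p_value
      } else {
        flag <- "permutation skipped: class too small or metric undefined"
      }
      mw_p <- if (sum(!is.na(vj)) && sum(!is.na(va)))
        mann_whitney(vj[!is.na(vj)], va[!is.na(va)])$p_value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        network = net_name, metric = metric,
        juvenile_mean = mean(vj, na.rm = TRUE),
        juvenile_min = suppressWarnings(min(vj, na.rm = TRUE)),
        juvenile_max = suppressWarnings(max(vj, na.rm = TRUE)),
        adult_mean = mean(va, na.rm = TRUE),
        adult_min = suppressWarnings(min(va, na.rm = TRUE)),
        adult_max = suppressWarnings(max(va, na.rm = TRUE)),
        permutation_p = perm_p, mann_whitney_p = mw_p,
        note = flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

traj_groups_by_step <- function(traj, metric) {
  res <- traj$results[traj$results$metric == metric, , drop = FALSE]
  split(res$value, res$step)
}

#' Aim 2: knockout effects on global network structure
#'
#' Runs the three removal schemes (juvenile-targeted, adult-targeted, both
#' exhaustive; random control) on one network, then tests whether each
#' global metric changes over removal steps (Kruskal-Wallis per scheme),
#' whether adult and juvenile removals differ (Scheirer-Ray-Hare with
#' removal category and step as factors, including their interaction), and
#' where the categories differ (per-step Mann-Whitney post-hocs).
#'
#' @param net a `social_network`.
#' @param juvenile_ids,adult_ids the two target sets.
#' @param r_max deepest removal step (default 10).
#' @param n_random random-control iterations per step (default 500).
#' @param seed integer seed for the random control.
#' @return list with `trajectories` (named `knockout_trajectory` list),
#'   `kruskal` (data frame), `srh` (data frame) and `posthoc` (data frame).
#' @export
run_aim2 <- function(net, juvenile_ids, adult_ids,
                     r_max = 10, n_random = 500, seed = NULL) {
  r_j <- min(r_max, length(juvenile_ids))
  r_a <- min(r_max, length(adult_ids))
  trajs <- list(
    juveniles = knockout_targeted(net, juvenile_ids, r_j),
    adults = knockout_targeted(net, adult_ids, r_a),
    random = knockout_random(net, min(r_max,
                                      network_size(net) - 3L),
                             n_random, seed))
  metrics <- unique(trajs$juveniles$results$metric)
  kw <- do.call(rbind, lapply(names(trajs), function(sc) {
    do.call(rbind, lapply(metrics, function(m) {
      g <- traj_groups_by_step(trajs[[sc]], m)
      res <- kruskal_wallis(g)
      data.frame(scheme = sc, metric = m, chisq = res$statistic,
                 df = res$df, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  srh <- do.call(rbind, lapply(metrics, function(m) {
    dj <- trajs$juveniles$results
    da <- trajs$adults$results
    dj <- dj[dj$metric == m, ]; da <- da[da$metric == m, ]
    vals <- c(dj$value, da$value)
    step <- c(dj$step, da$step)
    cat_ <- rep(c("juveniles", "adults"), c(nrow(dj), nrow(da)))
    res <- scheirer_ray_hare(vals, step, cat_)
    data.frame(metric = m,
               effect = c("removal", "category", "interaction"),
               H = vapply(res, function(r) r$statistic, numeric(1)),
               df = vapply(res, function(r) r$df, numeric(1)),
               p_value = vapply(res, function(r) r$p_value, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(srh) <- NULL
  posthoc <- do.call(rbind, lapply(metrics, function(m) {
    gj <- traj_groups_by_step(trajs$juveniles, m)
    ga <- traj_groups_by_step(trajs$adults, m)
    steps <- intersect(names(gj), names(ga))
    steps <- setdiff(steps, "0")          # intact networks are identical
    do.call(rbind, lapply(steps, function(s) {
      res <- mann_whitney(gj[[s]], ga[[s]])
      data.frame(metric = m, step = as.integer(s), U = res$statistic,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    }))
  }))
  list(trajectories = trajs, kruskal = kw, srh = srh, posthoc = posthoc)
}

#' Aim 3: class-specific effects of juvenile removal
#'
#' Runs the class-effect knockout (per-class mean betweenness and
#' clustering trajectories), compares the fitted slopes of every class
#' pair, bootstraps class means of the two metrics before and after
#' removing all juveniles (Welch t comparisons), and tabulates betweenness
#' rank changes with the top-5 most central individuals of each network.
#'
#' @param net a `social_network` containing juveniles.
#' @param juvenile_ids the juvenile set (non-empty).
#' @param classes age-sex classes tracked (default adult males, adult
#'   females, subadult females).
#' @param n_iterations knockout iterations per step (default 50).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param alpha alpha for betweenness.
#' @return list with `trajectory`, `slopes`, `bootstrap_t`, `rank_table`.
#' @export
run_aim3 <- function(net, juvenile_ids,
                     classes = c("adult_male", "adult_female",
                                 "subadult_female"),
                     n_iterations = 50, n_boot = 1000, seed = NULL,
                     alpha = 0.5) {
  if (!length(juvenile_ids))
    stop("aim 3 requires a non-empty juvenile set")
  if (!is.null(seed)) set.seed(seed)
  traj <- knockout_class_effect(net, juvenile_ids,
                                n_iterations = n_iterations,
                                classes = classes, alpha = alpha)
  smry <- summary(traj)
  pairs <- utils::combn(classes, 2)
  slopes <- do.call(rbind, lapply(c("betweenness", "clustering"),
                                  function(m) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      c1 <- pairs[1, k]; c2 <- pairs[2, k]
      s1 <- smry[smry$metric == paste0(m, ".", c1), c("step", "mean")]
      s2 <- smry[smry$metric == paste0(m, ".", c2), c("step", "mean")]
      ok <- stats::complete.cases(s1) & stats::complete.cases(s2)
      res <- compare_slopes(s1[ok, ], s2[ok, ])
      data.frame(metric = m, class_a = c1, class_b = c2,
                 slope_a = res$slope_a, slope_b = res$slope_b,
                 F = res$statistic, df1 = res$df[1], df2 = res$df[2],
                 p_value = res$p_value, stringsAsFactors = FALSE)
    }))
  }))
  net_reduced <- remove_nodes(net, juvenile_ids)
  boot_tab <- do.call(rbind, lapply(c("betweenness", "clustering"),
                                    function(m) {
    do.call(rbind, lapply(c(full = "before", reduced = "after"),
                          function(when) {
      g <- if (when == "before") net else net_reduced
      nm <- node_metrics(g, alpha)
      v <- stats::setNames(nm[[m]], nm$id)
      boots <- lapply(classes, function(cl) {
        ids <- nm$id[nm$age_sex_class == cl & !is.na(v[nm$id])]
        if (length(ids) < 2) return(NULL)
        bootstrap_class_means(v, ids, n_boot)
      })
      names(boots) <- classes
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
        c1 <- pairs[1, k]; c2 <- pairs[2, k]
        if (is.null(boots[[c1]]) || is.null(boots[[c2]])) {
          return(data.frame(metric = m, when = when, class_a = c1,
                            class_b = c2, t = NA_real_, df = NA_real_,
                            p_value = NA_real_,
                            note = "class too small to bootstrap",
                            stringsAsFactors = FALSE))
        }
        res <- t_test_bootstrap(boots[[c1]], boots[[c2]])
        data.frame(metric = m, when = when, class_a = c1, class_b = c2,
                   t = res$statistic, df = res$df, p_value = res$p_value,
                   note = "", stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(boot_tab) <- NULL
  rank_tab <- betweenness_rank_table(net, net_reduced, alpha)
  list(trajectory = traj, slopes = slopes, bootstrap_t = boot_tab,
       rank_table = rank_tab)
}

#' Run the full pipeline from a configuration
#'
#' Configuration is a list (or a JSON file path) with optional elements:
#' `seed` (default 1), `normalization`, `gap_s`, `subset_size`, `alpha`,
#' `r_max`, `n_random`, `n_class_iterations`, `n_boot`, `output_dir`, and
#' either `roster`/`effort`/`events` file paths or `simulate = TRUE`
#' (default) to analyse a synthetic troop with the planted effect profile.
#' All tables are written as CSV under `output_dir` when it is set, along
#' with a `run_metadata.json` recording the seed and settings.
#'
#' @param config list or path to a JSON config file.
#' @return list with `networks`, `aim1`, `aim2` (per network), `aim3`
#'   (per network) and `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(seed = 1L, simulate = TRUE, normalization = "dyad_hours",
         gap_s = 30, subset_size = 5, alpha = 0.5, r_max = 10,
         n_random = 500, n_class_iterations = 50, n_boot = 1000,
         output_dir = NULL),
    config)
  set.seed(cfg$seed)
  if (!is.null(cfg$roster)) {
    roster <- read_roster(cfg$roster)
    effort <- read_effort(cfg$effort, roster)
    events <- read_events(cfg$events, roster)
  } else if (isTRUE(cfg$simulate)) {
    ds <- generate_study_dataset(seed = cfg$seed)
    roster <- ds$roster; effort <- ds$effort; events <- ds$events
  } else {
    stop("config must provide input paths or simulate = TRUE")
  }
  nets <- build_study_networks(events, effort, roster, cfg$normalization,
                               cfg$gap_s)
  juv <- roster$id[roster$age_class == "juvenile" & roster$is_study_subject]
  adu <- roster$id[roster$age_class == "adult" & roster$is_study_subject]
  aim1 <- run_aim1(nets, cfg$subset_size, cfg$alpha)
  aim2 <- lapply(nets, function(net)
    run_aim2(net, juv, adu, cfg$r_max, cfg$n_random, seed = cfg$seed))
  aim3 <- lapply(nets, function(net)
    run_aim3(net, juv, n_iterations = cfg$n_class_iterations,
             n_boot = cfg$n_boot, seed = cfg$seed, alpha = cfg$alpha))
  out <- list(networks = nets, aim1 = aim1, aim2 = aim2, aim3 = aim3,
              config = cfg)
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(out, cfg$output_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(result$aim1, file.path(dir, "aim1_class_comparison.csv"),
                   row.names = FALSE)
  for (nm in names(result$networks)) {
    write_network(result$networks[[nm]],
                  file.path(dir, paste0("network_", nm, ".csv")))
    write_graphml(result$networks[[nm]],
                  file.path(dir, paste0("network_", nm, ".graphml")))
    a2 <- result$aim2[[nm]]
    utils::write.csv(a2$kruskal,
                     file.path(dir, paste0("aim2_kruskal_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(a2$srh,
                     file.path(dir, paste0("aim2_srh_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(a2$posthoc,
                     file.path(dir, paste0("aim2_posthoc_", nm, ".csv")),
                     row.names = FALSE)
    for (sc in names(a2$trajectories))
      write_trajectory(a2$trajectories[[sc]],
                       file.path(dir, paste0("aim2_traj_", nm, "_", sc,
                                             ".csv")),
                       file.path(dir, paste0("aim2_traj_", nm, "_", sc,
                                             "_summary.csv")))
    a3 <- result$aim3[[nm]]
    utils::write.csv(a3$slopes,
                     file.path(dir, paste0("aim3_slopes_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(a3$bootstrap_t,
                     file.path(dir, paste0("aim3_bootstrap_t_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(a3$rank_table,
                     file.path(dir, paste0("aim3_rank_table_", nm, ".csv")),
                     row.names = FALSE)
    write_trajectory(a3$trajectory,
                     file.path(dir, paste0("aim3_traj_", nm, ".csv")),
                     file.path(dir, paste0("aim3_traj_", nm,
                                           "_summary.csv")))
  }
  invisible(dir)
}
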