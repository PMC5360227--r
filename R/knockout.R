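# Stepwise node-knockout simulation engine.
#
# Three removal schemes: targeted (every size-r subset of a target set,
# enumerated exhaustively), random control (500 uniform subsets per step,
# falling back to exhaustive enumeration whenever the subset space is
# smaller than the iteration budget, to avoid pseudoreplication), and
# class-effect removals (random juvenile subsets, 50 per step, tracking
# per-age-sex-class mean betweenness and clustering). Global metrics are
# recomputed from scratch on every reduced network; removal never rescales
# the surviving hourly rates.

#' Exact binomial coefficient
#'
#' `n! / (r! (n - r)!)` via the multiplicative algorithm; each intermediate
#' product is an exact integer (exactly representable as a double for all
#' troop-scale inputs).
#'
#' @param n,r non-negative integers with `r <= n`.
#' @return the number of size-`r` subsets of `n` elements.
#' @export
n_combinations <- function(n, r) {
  if (length(n) != 1 || length(r) != 1 || is.na(n) || is.na(r))
    stop("n and r must be single integers")
  if (n < 0 || r < 0 || r != round(r) || n != round(n))
    stop("n and r must be non-negative integers")
  if (r > n) stop("r must not exceed n")
  r <- min(r, n - r)
  out <- 1
  for (k in seq_len(r)) out <- out * (n - r + k) / k
  if (out > 2^53) warning("result exceeds exact double-precision range")
  round(out)
}

# All size-r subsets as a list of character vectors.
enumerate_subsets <- function(ids, r) {
  if (r == 0) return(list(character(0)))
  m <- utils::combn(ids, r)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

# n_iterations independent uniform size-r subsets (replicates may repeat,
# the subset itself is drawn without replacement).
sample_subsets <- function(ids, r, n_iterations) {
  lapply(seq_len(n_iterations), function(i) sample(ids, r))
}

min_surviving_nodes <- 3L

new_trajectory <- function(results, removed, scheme, net) {
  structure(list(results = results, removed = removed, scheme = scheme,
                 behaviour = net$behaviour),
            class = "knockout_trajectory")
}

#' @export
print.knockout_trajectory <- function(x, ...) {
  cat(sprintf("<knockout_trajectory> scheme=%s, behaviour=%s, steps %s\n",
              x$scheme, x$behaviour,
              paste(range(x$results$step), collapse = "-")))
  print(utils::head(summary(x)))
  invisible(x)
}

run_knockout <- function(net, subsets_by_step, scheme, metric_fun,
                         triplet_value = "arithmetic_mean") {
  rows <- list()
  removed <- list()
  intact <- metric_fun(net)
  rows[[1]] <- data.frame(step = 0L, replicate = 1L,
                          metric = names(intact), value = unname(intact),
                          stringsAsFactors = FALSE)
  removed[["0"]] <- list(character(0))
  n <- network_size(net)
  for (step_name in names(subsets_by_step)) {
    r <- as.integer(step_name)
    subs <- subsets_by_step[[step_name]]
    if (n - r < min_surviving_nodes) {
      warning("step ", r, " skipped: fewer than ", min_surviving_nodes,
              " nodes would survive")
      next
    }
    vals <- lapply(seq_along(subs), function(i) {
      m <- metric_fun(remove_nodes(net, subs[[i]]))
      data.frame(step = r, replicate = i, metric = names(m),
                 value = unname(m), stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- do.call(rbind, vals)
    removed[[step_name]] <- subs
  }
  new_trajectory(do.call(rbind, rows), removed, scheme, net)
}

global_metric_fun <- function(triplet_value, density_mode) {
  function(net) global_metrics(net, triplet_value, density_mode)
}

#' Targeted exhaustive knockout
#'
#' For each step `r = 1..r_max`, every size-`r` subset of the target set is
#' removed in turn from a fresh copy of the network and the global metrics
#' are recomputed, yielding `choose(length(target_ids), r)` replicates per
#' step. Step 0 (intact network) is always included.
#'
#' @param net a `social_network`.
#' @param target_ids ids eligible for removal (e.g. all juveniles).
#' @param r_max deepest removal step (default: the whole target set).
#' @param triplet_value,density_mode passed to [global_metrics()].
#' @return a `knockout_trajectory`.
#' @export
knockout_targeted <- function(net, target_ids, r_max = length(target_ids),
                              triplet_value = "arithmetic_mean",
                              density_mode = "directed") {
  stopifnot(inherits(net, "social_network"))
  unknown <- setdiff(target_ids, network_ids(net))
  if (length(unknown))
    stop("target id(s) not in network: ", paste(unknown, collapse = ", "))
  if (r_max > length(target_ids))
    stop("r_max exceeds the size of the target set")
  target_ids <- sort(target_ids)      # trajectory invariant to input order
  steps <- stats::setNames(
    lapply(seq_len(r_max), function(r) enumerate_subsets(target_ids, r)),
    seq_len(r_max))
  run_knockout(net, steps, "targeted",
               global_metric_fun(triplet_value, density_mode))
}

#' Random-control knockout
#'
#' At each step `r`, removes `n_iterations` uniformly random size-`r`
#' subsets of all nodes — except when the subset space is smaller than the
#' iteration budget (`choose(n, r) < n_iterations`), in which case all
#' subsets are enumerated exactly once to avoid pseudoreplication.
#'
#' @param net a `social_network`.
#' @param r_max deepest removal step; at least 3 nodes must survive.
#' @param n_iterations random subsets per step (default 500).
#' @param seed integer seed making the draw reproducible.
#' @param triplet_value,density_mode passed to [global_metrics()].
#' @return a `knockout_trajectory`.
#' @export
knockout_random <- function(net, r_max, n_iterations = 500, seed = NULL,
                            triplet_value = "arithmetic_mean",
                            density_mode = "directed") {
  stopifnot(inherits(net, "social_network"))
  n <- network_size(net)
  if (r_max > n - min_surviving_nodes)
    stop("r_max must leave at least ", min_surviving_nodes, " nodes")
  if (!is.null(seed)) set.seed(seed)
  ids <- network_ids(net)
  steps <- stats::setNames(lapply(seq_len(r_max), function(r) {
    if (n_combinations(n, r) < n_iterations) enumerate_subsets(ids, r)
    else sample_subsets(ids, r, n_iterations)
  }), seq_len(r_max))
  run_knockout(net, steps, "random",
               global_metric_fun(triplet_value, density_mode))
}

# Per-class mean betweenness and clustering among surviving nodes.
class_metric_fun <- function(class_map, classes, alpha, triplet_value) {
  function(net) {
    bt <- weighted_betweenness(net, alpha)
    cc <- weighted_local_clustering(net, triplet_value)
    cls <- class_map[network_ids(net)]
    out <- c()
    for (cl in classes) {
      members <- network_ids(net)[!is.na(cls) & cls == cl]
      out[paste0("betweenness.", cl)] <-
        if (length(members)) mean(bt[members]) else NA_real_
      ccm <- cc[members]
      out[paste0("clustering.", cl)] <-
        if (length(members) && any(!is.na(ccm))) mean(ccm, na.rm = TRUE)
        else NA_real_
    }
    out
  }
}

#' Class-effect knockout
#'
#' Removes random juvenile subsets stepwise (default 50 iterations per
#' step, exhaustive when the subset space is no larger than the budget) and
#' tracks, for each replicate, the mean weighted betweenness and mean
#' clustering of the surviving members of each focal age-sex class
#' (by default adult males, adult females and subadult females; singleton
#' classes such as the lone subadult male are typically excluded by the
#' caller). A class left empty after removal yields `NA`.
#'
#' @param net a `social_network`.
#' @param juvenile_ids the removable (juvenile) ids.
#' @param r_max deepest removal step (default all juveniles).
#' @param n_iterations subsets per step (default 50).
#' @param seed integer seed.
#' @param classes age-sex class labels to track.
#' @param alpha alpha for betweenness.
#' @param triplet_value clustering triplet method.
#' @return a `knockout_trajectory` with per-class metrics.
#' @export
knockout_class_effect <- function(net, juvenile_ids,
                                  r_max = length(juvenile_ids),
                                  n_iterations = 50, seed = NULL,
                                  classes = c("adult_male", "adult_female",
                                              "subadult_female"),
                                  alpha = 0.5,
                                  triplet_value = "arithmetic_mean") {
  stopifnot(inherits(net, "social_network"))
  unknown <- setdiff(juvenile_ids, network_ids(net))
  if (length(unknown))
    stop("juvenile id(s) not in network: ", paste(unknown, collapse = ", "))
  if (!length(juvenile_ids)) stop("juvenile set is empty")
  if (r_max > length(juvenile_ids))
    stop("r_max exceeds the number of juveniles")
  if (!is.null(seed)) set.seed(seed)
  juvenile_ids <- sort(juvenile_ids)
  class_map <- age_sex_class(net$roster)
  steps <- stats::setNames(lapply(seq_len(r_max), function(r) {
    if (n_combinations(length(juvenile_ids), r) <= n_iterations)
      enumerate_subsets(juvenile_ids, r)
    else sample_subsets(juvenile_ids, r, n_iterations)
  }), seq_len(r_max))
  run_knockout(net, steps, "class_effect",
               class_metric_fun(class_map, classes, alpha, triplet_value))
}

#' Summarise a knockout trajectory
#'
#' Mean and standard error (sample SD over replicates divided by the square
#' root of the replicate count) of every metric at every step.
#'
#' @param object a `knockout_trajectory`.
#' @param ... unused.
#' @return data frame with columns `step`, `metric`, `n_replicates`,
#'   `mean`, `se`.
#' @export
summary.knockout_trajectory <- function(object, ...) {
  res <- object$results
  key <- interaction(res$step, res$metric, drop = TRUE)
  agg <- lapply(split(res, key), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(step = d$step[1], metric = d$metric[1],
               n_replicates = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$metric, out$step), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a trajectory to CSV
#'
#' Long-format replicate table (`scheme, step, replicate, metric, value`)
#' plus, when `summary_path` is given, a per-step mean/SE summary.
#'
#' @param traj a `knockout_trajectory`.
#' @param path replicate-level CSV path.
#' @param summary_path optional summary CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, summary_path = NULL) {
  res <- cbind(scheme = traj$scheme, traj$results)
  utils::write.csv(res, path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(summary(traj), summary_path, row.names = FALSE)
  invisible(path)
}

#' Betweenness rank-change table
#'
#' Ranks every individual by weighted betweenness (rank 1 = most central,
#' ties share the midrank) in a network including juveniles and in the
#' corresponding network with the juveniles removed, and reports the rank
#' change of each non-juvenile together with the identity and class
#' composition of the five most central individuals in each network.
#'
#' @param net_full network including juveniles.
#' @param net_reduced the same network with the juvenile set removed (node
#'   sets may differ only by that set).
#' @param alpha alpha for betweenness.
#' @param top_n size of the most-central comparison set (default 5).
#' @return data frame with per-individual ranks and changes; the top-`n`
#'   membership of each network is attached as attributes `top_full` and
#'   `top_reduced`.
#' @export
betweenness_rank_table <- function(net_full, net_reduced, alpha = 0.5,
                                   top_n = 5) {
  stopifnot(inherits(net_full, "social_network"),
            inherits(net_reduced, "social_network"))
  ids_full <- network_ids(net_full)
  ids_red <- network_ids(net_reduced)
  if (length(setdiff(ids_red, ids_full)))
    stop("reduced network contains nodes absent from the full network")
  bt_full <- weighted_betweenness(net_full, alpha)
  bt_red <- weighted_betweenness(net_reduced, alpha)
  rank_desc <- function(x) rank(-x, ties.method = "average")
  rk_full <- rank_desc(bt_full)
  rk_red <- rank_desc(bt_red)
  cls <- age_sex_class(net_full$roster)
  out <- data.frame(id = ids_red,
                    age_sex_class = unname(cls[ids_red]),
                    betweenness_full = unname(bt_full[ids_red]),
                    betweenness_reduced = unname(bt_red[ids_red]),
                    rank_full = unname(rk_full[ids_red]),
                    rank_reduced = unname(rk_red[ids_red]),
                    stringsAsFactors = FALSE)
  out$rank_change <- out$rank_reduced - out$rank_full
  out <- out[order(out$rank_reduced), , drop = FALSE]
  rownames(out) <- NULL
  top <- function(rk) names(sort(rk))[seq_len(min(top_n, length(rk)))]
  attr(out, "top_full") <- top(rk_full)
  attr(out, "top_reduced") <- top(rk_red)
  attr(out, "top_full_classes") <- unname(cls[attr(out, "top_full")])
  attr(out, "top_reduced_classes") <- unname(cls[attr(out, "top_reduced")])
  out
}
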