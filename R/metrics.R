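# Individual and global network metrics.
#
# Binary measures (degree, density, centralisation) ignore weights; weighted
# measures follow the generalised-degree framework in which the presence of
# a tie and its strength are traded off by a tuning parameter alpha in
# [0, 1]: alpha = 0 counts partners, alpha = 1 sums weights, alpha = 0.5
# weighs both equally (the convention used for betweenness here).

binary_adj <- function(net) (net$adj > 0) * 1L

sym_binary_adj <- function(net) {
  a <- binary_adj(net)
  ((a + t(a)) > 0) * 1L
}

#' Binary degrees
#'
#' `degree` is the number of distinct partners in the symmetrised binary
#' network (reciprocal ties collapse to one partner); `in_degree` and
#' `out_degree` count distinct in- and out-neighbours of the directed
#' binary network.
#'
#' @param net a `social_network`.
#' @return data frame with columns `id`, `degree`, `in_degree`, `out_degree`.
#' @export
binary_degrees <- function(net) {
  stopifnot(inherits(net, "social_network"))
  a <- binary_adj(net)
  data.frame(id = network_ids(net),
             degree = as.integer(rowSums(sym_binary_adj(net))),
             in_degree = as.integer(colSums(a)),
             out_degree = as.integer(rowSums(a)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Node strengths
#'
#' `out_strength(i)` is the sum of weights of ties initiated by `i`;
#' `in_strength(i)` the sum over ties received. Equivalent to the
#' generalised degree at `alpha = 1`.
#'
#' @param net a `social_network`.
#' @return data frame with columns `id`, `in_strength`, `out_strength`.
#' @export
strengths <- function(net) {
  stopifnot(inherits(net, "social_network"))
  data.frame(id = network_ids(net),
             in_strength = unname(colSums(net$adj)),
             out_strength = unname(rowSums(net$adj)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generalised (alpha-tuned) degree
#'
#' `k^(1 - alpha) * s^alpha` per node, where `k` is the binary degree and
#' `s` the strength in the chosen direction. Reduces to the binary degree at
#' `alpha = 0` and to the strength at `alpha = 1`; nodes with no ties score 0.
#'
#' @param net a `social_network`.
#' @param alpha tuning parameter in `[0, 1]`.
#' @param direction `"out"`, `"in"` or `"all"` (symmetrised).
#' @return named numeric vector.
#' @export
generalized_degree <- function(net, alpha = 0.5,
                               direction = c("out", "in", "all")) {
  stopifnot(inherits(net, "social_network"), alpha >= 0, alpha <= 1)
  direction <- match.arg(direction)
  a <- binary_adj(net)
  if (direction == "out") {
    k <- rowSums(a); s <- rowSums(net$adj)
  } else if (direction == "in") {
    k <- colSums(a); s <- colSums(net$adj)
  } else {
    sym <- symmetrise(net)
    k <- rowSums(binary_adj(sym)); s <- rowSums(sym$adj)
  }
  v <- ifelse(k > 0, k^(1 - alpha) * s^alpha, 0)
  stats::setNames(v, network_ids(net))
}

# Dijkstra with multiple-predecessor bookkeeping and a relative tolerance
# for detecting cost ties (real-valued costs make exact ties fragile).
# Returns dist, sigma (shortest-path counts), preds, and finalisation order.
dijkstra_multi <- function(cost, s, tol = 1e-10) {
  n <- nrow(cost)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  preds <- vector("list", n)
  done <- rep(FALSE, n)
  order_out <- integer(0)
  dist[s] <- 0
  sigma[s] <- 1
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    order_out <- c(order_out, u)
    nbr <- which(is.finite(cost[u, ]) & !done)
    for (v in nbr) {
      alt <- dist[u] + cost[u, v]
      eps <- tol * max(1, abs(alt))
      if (!is.finite(dist[v]) || alt < dist[v] - eps) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= eps) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_out)
}

#' Weighted betweenness centrality
#'
#' Counts, for every ordered pair of other nodes, the proportion of
#' minimal-cost paths passing through each node (Brandes accumulation over
#' all minimal paths; raw, unnormalised; unreachable pairs contribute 0).
#' The cost of an edge of weight `w` is `(1 / w)^alpha`: at `alpha = 0` every
#' tie costs 1 (binary shortest paths), at `alpha = 1` cost is inverse
#' weight, and the default `alpha = 0.5` gives tie presence and tie strength
#' equal weight.
#'
#' @param net a `social_network` (directed or symmetrised).
#' @param alpha tuning parameter in `[0, 1]`.
#' @param tol relative tolerance for detecting equal-cost paths.
#' @return named numeric vector of betweenness scores.
#' @export
weighted_betweenness <- function(net, alpha = 0.5, tol = 1e-10) {
  stopifnot(inherits(net, "social_network"), alpha >= 0, alpha <= 1)
  adj <- net$adj
  if (any(adj < 0)) stop("edge weights must be positive")
  n <- nrow(adj)
  ids <- network_ids(net)
  bc <- stats::setNames(rep(0, n), ids)
  if (n < 3) return(bc)
  cost <- matrix(Inf, n, n)
  pos <- adj > 0
  cost[pos] <- (1 / adj[pos])^alpha
  diag(cost) <- Inf
  for (s in seq_len(n)) {
    sp <- dijkstra_multi(cost, s, tol)
    delta <- rep(0, n)
    for (w in rev(sp$order)) {
      for (v in sp$preds[[w]])
        delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

triplet_value_fun <- function(triplet_value) {
  switch(triplet_value,
         arithmetic_mean = function(a, b) (a + b) / 2,
         geometric_mean = function(a, b) sqrt(a * b),
         max = pmax,
         min = pmin,
         stop("unknown triplet_value '", triplet_value, "'"))
}

#' Weighted local clustering coefficient
#'
#' Computed on the symmetrised network (applied internally): for node `i`,
#' the total triplet value of closed triplets centred on `i` divided by the
#' total triplet value of all triplets centred on `i`, where a triplet's
#' value combines the weights of its two ties at `i` (default arithmetic
#' mean). Ranges in `[0, 1]`; `NA` for nodes with fewer than two partners
#' (mathematically undefined).
#'
#' @param net a `social_network`.
#' @param triplet_value `"arithmetic_mean"`, `"geometric_mean"`, `"max"` or
#'   `"min"`.
#' @return named numeric vector with `NA` where undefined.
#' @export
weighted_local_clustering <- function(net,
                                      triplet_value = c("arithmetic_mean",
                                                        "geometric_mean",
                                                        "max", "min")) {
  stopifnot(inherits(net, "social_network"))
  triplet_value <- match.arg(triplet_value)
  f <- triplet_value_fun(triplet_value)
  W <- symmetrise(net)$adj
  n <- nrow(W)
  ids <- network_ids(net)
  out <- stats::setNames(rep(NA_real_, n), ids)
  for (i in seq_len(n)) {
    nbr <- which(W[i, ] > 0)
    if (length(nbr) < 2) next
    pairs <- utils::combn(nbr, 2)
    tv <- f(W[i, pairs[1, ]], W[i, pairs[2, ]])
    closed <- W[cbind(pairs[1, ], pairs[2, ])] > 0
    out[i] <- sum(tv[closed]) / sum(tv)
  }
  out
}

#' Network density
#'
#' Number of existing binary ties over the number of possible ties. The
#' default counts directed ties over `n(n-1)` ordered pairs; `"symmetrised"`
#' counts dyads with any tie over `n(n-1)/2` unordered pairs.
#'
#' @param net a `social_network` with at least 2 nodes.
#' @param mode `"directed"` or `"symmetrised"`.
#' @return density in `[0, 1]`.
#' @export
network_density <- function(net, mode = c("directed", "symmetrised")) {
  stopifnot(inherits(net, "social_network"))
  mode <- match.arg(mode)
  n <- network_size(net)
  if (n < 2) stop("density needs at least 2 nodes")
  if (mode == "symmetrised" || !net$directed) {
    a <- sym_binary_adj(net)
    sum(a) / (n * (n - 1))          # symmetric matrix: both cells per dyad
  } else {
    sum(binary_adj(net)) / (n * (n - 1))
  }
}

#' Freeman degree centralisation
#'
#' Computed on the symmetrised binary network:
#' `sum(d_max - d_i) / ((n - 1)(n - 2))`. Ranges from 0 (all individuals
#' equally connected) to 1 (a star: one individual holds every tie).
#'
#' @param net a `social_network` with at least 3 nodes.
#' @return centralisation in `[0, 1]`.
#' @export
degree_centralization <- function(net) {
  stopifnot(inherits(net, "social_network"))
  n <- network_size(net)
  if (n < 3) stop("degree centralisation needs at least 3 nodes")
  d <- rowSums(sym_binary_adj(net))
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

#' Mean clustering coefficient
#'
#' Arithmetic mean of the defined weighted local clustering coefficients;
#' nodes with fewer than two partners are excluded rather than scored 0.
#'
#' @inheritParams weighted_local_clustering
#' @return mean clustering, or `NA` if no node has two partners.
#' @export
mean_clustering <- function(net, triplet_value = "arithmetic_mean") {
  cc <- weighted_local_clustering(net, triplet_value)
  if (all(is.na(cc))) return(NA_real_)
  mean(cc, na.rm = TRUE)
}

#' Global network metrics
#'
#' Bundles the three whole-network cohesion measures: density, Freeman
#' degree centralisation and mean weighted clustering.
#'
#' @param net a `social_network`.
#' @param triplet_value passed to [mean_clustering()].
#' @param density_mode passed to [network_density()].
#' @return named numeric vector `c(density, centralization, clustering)`.
#' @export
global_metrics <- function(net, triplet_value = "arithmetic_mean",
                           density_mode = "directed") {
  c(density = network_density(net, density_mode),
    centralization = degree_centralization(net),
    clustering = mean_clustering(net, triplet_value))
}

#' Per-individual metric table
#'
#' One row per node: binary degrees, strengths, weighted betweenness
#' (default `alpha = 0.5`) and weighted local clustering on the symmetrised
#' network, plus the age-sex class label.
#'
#' @param net a `social_network`.
#' @param alpha alpha for [weighted_betweenness()].
#' @param triplet_value passed to [weighted_local_clustering()].
#' @return data frame keyed by `id`.
#' @export
node_metrics <- function(net, alpha = 0.5,
                         triplet_value = "arithmetic_mean") {
  deg <- binary_degrees(net)
  str <- strengths(net)
  out <- merge(deg, str, by = "id", sort = FALSE)
  out$betweenness <- unname(weighted_betweenness(net, alpha)[out$id])
  out$clustering <- unname(weighted_local_clustering(net, triplet_value)[out$id])
  cls <- age_sex_class(net$roster)
  out$age_class <- net$roster$age_class[match(out$id, net$roster$id)]
  out$sex <- net$roster$sex[match(out$id, net$roster$id)]
  out$age_sex_class <- unname(cls[out$id])
  out
}
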