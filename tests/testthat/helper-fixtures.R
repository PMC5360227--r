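# Shared fixtures and independent oracles. Oracles are deliberately naive
# (exhaustive enumeration, direct formulas) and never reuse package code
# paths they are meant to check.

toy_roster <- function(ids, age_class = "adult", sex = "female") {
  as_roster(data.frame(id = ids,
                       sex = rep_len(sex, length(ids)),
                       age_class = rep_len(age_class, length(ids)),
                       is_study_subject = TRUE))
}

toy_net <- function(edges, ids = NULL, directed = TRUE) {
  edgelist_network(edges, ids = ids, directed = directed)
}

# n-node random digraph with uniform weights; returns adjacency matrix
random_digraph <- function(n, p = 0.4, wmin = 0.2, wmax = 3) {
  adj <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  for (i in 1:n) for (j in 1:n) if (i != j && stats::runif(1) < p)
    adj[i, j] <- stats::runif(1, wmin, wmax)
  adj
}

adj_to_net <- function(adj, directed = TRUE) {
  idx <- which(adj > 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(adj)[idx[, 1]],
                      target = colnames(adj)[idx[, 2]],
                      weight = adj[idx])
  edgelist_network(edges, ids = rownames(adj), directed = directed)
}

# Exhaustive-enumeration betweenness oracle: enumerates every simple path
# between each ordered pair, keeps the minimal-cost ones (relative
# tolerance), and credits interior nodes with sigma_st(v)/sigma_st.
brute_betweenness <- function(adj, alpha = 0.5, tol = 1e-9) {
  n <- nrow(adj)
  cost <- matrix(Inf, n, n)
  cost[adj > 0] <- (1 / adj[adj > 0])^alpha
  bc <- numeric(n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t) next
    paths <- list()
    rec <- function(v, visited, c) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(nodes = visited, cost = c)
        return(invisible())
      }
      for (w in which(is.finite(cost[v, ])))
        if (!(w %in% visited)) rec(w, c(visited, w), c + cost[v, w])
    }
    rec(s, s, 0)
    if (!length(paths)) next
    costs <- vapply(paths, function(p) p$cost, numeric(1))
    mn <- min(costs)
    keep <- which(abs(costs - mn) <= tol * max(1, mn))
    for (p in paths[keep]) {
      inter <- setdiff(p$nodes, c(s, t))
      bc[inter] <- bc[inter] + 1 / length(keep)
    }
  }
  stats::setNames(bc, rownames(adj))
}

# Direct rank-formula Kruskal-Wallis H (tie-corrected), independent of
# stats::kruskal.test.
kw_formula <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  Rg <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / sizes) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Small troop and dataset for pipeline tests (kept tiny for speed).
small_dataset <- function(seed = 42) {
  generate_study_dataset(seed = seed)
}
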