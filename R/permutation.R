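# Resampling nulls for class-level metric comparison: exhaustive selective
# node permutation (all fixed-size subsets of a class, each contributing its
# subset mean) and the bootstrap of class means.

#' Selective node permutation distribution
#'
#' Enumerates every size-`subset_size` combination of the class members and
#' records the mean metric value of each subset, giving the simulated
#' distribution of class-mean metrics used for between-class comparison.
#' With the canonical 10-member class and subsets of 5 this yields
#' `choose(10, 5) = 252` means. A warning is raised when the class size
#' differs from 10, since the 252-combination design assumes 10-member
#' classes.
#'
#' @param metric_values named numeric vector, individual id -> metric value.
#' @param class_ids ids of the class members.
#' @param subset_size individuals drawn per combination (default 5).
#' @return object of class `metric_distribution` with fields `values`
#'   (the subset means), `subset_size`, `exhaustive`, `class_size`.
#' @export
selective_node_permutation <- function(metric_values, class_ids,
                                       subset_size = 5) {
  class_ids <- as.character(class_ids)
  if (subset_size > length(class_ids))
    stop("subset_size exceeds the class size")
  miss <- setdiff(class_ids, names(metric_values))
  if (length(miss))
    stop("metric value missing for class member(s): ",
         paste(miss, collapse = ", "))
  if (length(class_ids) != 10)
    warning("class has ", length(class_ids),
            " members; the 252-combination design assumes 10")
  vals <- metric_values[class_ids]
  if (anyNA(vals))
    stop("metric value is NA for class member(s): ",
         paste(class_ids[is.na(vals)], collapse = ", "))
  n_comb <- n_combinations(length(class_ids), subset_size)
  if (n_comb > 1e6)
    stop("subset space too large to enumerate (", n_comb, " combinations)")
  means <- as.vector(utils::combn(unname(vals), subset_size, FUN = mean))
  structure(list(values = means, subset_size = subset_size,
                 exhaustive = TRUE, class_size = length(class_ids)),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf(
    "<metric_distribution> %d subset means (subsets of %d from %d, %s)\n",
    length(x$values), x$subset_size, x$class_size,
    if (x$exhaustive) "exhaustive" else "sampled"))
  print(summary(x$values))
  invisible(x)
}

#' Compare two permutation distributions
#'
#' Two-sided Wilcoxon rank-sum test between the simulated subset-mean
#' distributions of two classes, with a Shapiro-Wilk normality diagnostic
#' for each distribution (the simulated distributions are typically highly
#' non-normal, which motivates the rank-based comparison). Note that
#' subset means drawn from the same class are not independent observations;
#' the p-value calibrates the paper-style comparison, not a nominal-level
#' test (see [mann_whitney()] on raw values for that).
#'
#' @param dist_a,dist_b `metric_distribution` objects or numeric vectors.
#' @return a `troopnet_test` result; degenerate comparisons (both
#'   distributions a single shared constant) report `p = 1` with a note.
#' @export
compare_class_distributions <- function(dist_a, dist_b) {
  a <- if (inherits(dist_a, "metric_distribution")) dist_a$values else dist_a
  b <- if (inherits(dist_b, "metric_distribution")) dist_b$values else dist_b
  if (!length(a) || !length(b)) stop("distributions must be non-empty")
  shapiro_p <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3 || length(unique(x)) < 3) return(NA_real_)
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    stats::shapiro.test(x)$p.value
  }
  if (stats::var(c(a, b)) == 0) {
    return(new_test_result("wilcoxon_rank_sum", statistic = NA_real_,
                           df = NA_integer_, p_value = 1,
                           notes = "degenerate: both distributions constant and equal"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  new_test_result("wilcoxon_rank_sum", statistic = unname(wt$statistic),
                  df = NA_integer_, p_value = wt$p.value,
                  notes = sprintf("shapiro_p_a=%.3g; shapiro_p_b=%.3g",
                                  shapiro_p(a), shapiro_p(b)))
}

#' Bootstrap distribution of a class mean
#'
#' Resamples the class members with replacement (sample size = class size)
#' `n_boot` times, recording the mean metric value of each resample.
#'
#' @param metric_values named numeric vector, id -> metric value.
#' @param class_ids ids of the class members (at least 2).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `n_boot` bootstrap means.
#' @export
bootstrap_class_means <- function(metric_values, class_ids, n_boot = 1000,
                                  seed = NULL) {
  class_ids <- as.character(class_ids)
  if (length(class_ids) < 2) stop("class must have at least 2 members")
  miss <- setdiff(class_ids, names(metric_values))
  if (length(miss))
    stop("metric value missing for class member(s): ",
         paste(miss, collapse = ", "))
  vals <- unname(metric_values[class_ids])
  if (anyNA(vals)) stop("metric values contain NA")
  if (!is.null(seed)) set.seed(seed)
  n <- length(vals)
  vapply(seq_len(n_boot),
         function(i) mean(vals[sample.int(n, n, replace = TRUE)]),
         numeric(1))
}
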