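# Rank-based and parametric tests used across the pipeline. Every test
# returns a uniform `troopnet_test` record (name, statistic, df, p, notes).
# No multiple-testing correction is applied by default; `holm_adjust()` is
# available for users who want one.

new_test_result <- function(test, statistic, df, p_value, notes = "",
                            extra = NULL) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p_value, notes = notes), extra),
            class = "troopnet_test")
}

#' @export
print.troopnet_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ","), x$p_value))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Convert test results to a data frame
#' @param x a `troopnet_test` or list of them.
#' @param ... unused.
#' @return data frame with one row per test.
#' @export
as.data.frame.troopnet_test <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic,
             df = paste(x$df, collapse = ","), p_value = x$p_value,
             notes = x$notes, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic with `k - 1` degrees of freedom referred to the
#' chi-square distribution. Used with the number of removed nodes (steps
#' 0-10, hence df = 10) as the grouping variable and a network metric as
#' response.
#'
#' @param groups list of numeric vectors, one per group (at least 2 groups,
#'   each non-empty).
#' @return a `troopnet_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group(s): ", which(sizes == 0)[1])
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (stats::var(values) == 0)
    return(new_test_result("kruskal_wallis", 0, length(groups) - 1L, 1,
                           notes = "degenerate: all values equal"))
  kt <- stats::kruskal.test(values, g)
  new_test_result("kruskal_wallis", unname(kt$statistic),
                  unname(kt$parameter), kt$p.value)
}

#' Scheirer-Ray-Hare test
#'
#' Rank-based factorial analogue of two-way ANOVA. All values are ranked
#' jointly (midranks for ties); the two-way sums of squares are computed on
#' the ranks; each effect's statistic is `H = SS_effect / MS_total`, where
#' `MS_total` is the variance of all ranks (denominator `N - 1`), referred
#' to a chi-square distribution with the effect's degrees of freedom. With a
#' single-level second factor the main-effect H reduces exactly to the
#' tie-corrected Kruskal-Wallis H.
#'
#' @param values numeric response.
#' @param factor_a,factor_b grouping vectors (coerced to factor).
#' @return list of three `troopnet_test` results: `A`, `B`, `AB`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (length(values) != length(a) || length(values) != length(b))
    stop("values and factors must have equal length")
  if (nlevels(a) < 2 && nlevels(b) < 2)
    stop("at least one factor must have 2 or more levels")
  N <- length(values)
  r <- rank(values)
  ms_total <- stats::var(r)                  # denominator N - 1
  ss_groups <- function(f) {
    m <- tapply(r, f, mean)
    n <- tapply(r, f, length)
    sum(n * (m - mean(r))^2)
  }
  ss_a <- ss_groups(a)
  ss_b <- ss_groups(b)
  ss_cells <- ss_groups(interaction(a, b, drop = TRUE))
  ss_ab <- ss_cells - ss_a - ss_b
  dfs <- c(A = nlevels(a) - 1L, B = nlevels(b) - 1L,
           AB = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  ss <- c(A = ss_a, B = ss_b, AB = max(ss_ab, 0))
  out <- lapply(names(dfs), function(eff) {
    df <- dfs[[eff]]
    if (df == 0 || ms_total == 0)
      return(new_test_result(paste0("scheirer_ray_hare_", eff), 0, df, 1,
                             notes = if (ms_total == 0) "degenerate: constant values" else "degenerate factor"))
    H <- ss[[eff]] / ms_total
    new_test_result(paste0("scheirer_ray_hare_", eff), H, df,
                    stats::pchisq(H, df, lower.tail = FALSE))
  })
  stats::setNames(out, names(dfs))
}

#' Mann-Whitney U test
#'
#' Two-sided U statistic; the p-value is exact for small tie-free samples
#' and uses the tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return a `troopnet_test` with the U statistic for `x` as first sample.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (stats::var(c(x, y)) == 0)
    return(new_test_result("mann_whitney", length(x) * length(y) / 2,
                           NA_integer_, 1,
                           notes = "degenerate: all values equal"))
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  new_test_result("mann_whitney", unname(wt$statistic), NA_integer_,
                  wt$p.value)
}

#' Compare regression slopes of two trajectories
#'
#' Fits least-squares lines of mean metric value against removal step for
#' two series and tests slope equality through the interaction term of the
#' stacked model `value ~ step * series`, reporting F with
#' `(1, n_a + n_b - 4)` degrees of freedom.
#'
#' @param series_a,series_b data frames with columns `step` and `mean`
#'   (at least 3 points each, on a common step grid).
#' @return a `troopnet_test`; the fitted slopes are attached as fields
#'   `slope_a` and `slope_b`.
#' @export
compare_slopes <- function(series_a, series_b) {
  check <- function(s, nm) {
    s <- as.data.frame(s)
    if (is.null(s$step) || is.null(s$mean))
      stop(nm, " needs columns 'step' and 'mean'")
    if (nrow(s) < 3) stop(nm, " needs at least 3 points")
    s
  }
  series_a <- check(series_a, "series_a")
  series_b <- check(series_b, "series_b")
  if (!setequal(series_a$step, series_b$step))
    stop("series must share a common step grid")
  d <- rbind(data.frame(step = series_a$step, value = series_a$mean, g = 0),
             data.frame(step = series_b$step, value = series_b$mean, g = 1))
  fit <- stats::lm(value ~ step * g, data = d)
  co <- suppressWarnings(summary(fit)$coefficients)  # noiseless fits warn
  df2 <- nrow(d) - 4L
  slope_a <- unname(co["step", "Estimate"])
  slope_b <- slope_a + unname(co["step:g", "Estimate"])
  tval <- co["step:g", "t value"]
  Fstat <- unname(tval^2)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  new_test_result("slope_comparison_F", Fstat, c(1L, df2), p,
                  notes = sprintf("slope_a=%.4g; slope_b=%.4g",
                                  slope_a, slope_b),
                  extra = list(slope_a = slope_a, slope_b = slope_b))
}

#' Welch t-test on bootstrap distributions
#'
#' Compares two bootstrap-mean distributions with an unequal-variance
#' two-sample t-test. Because bootstrap distributions understate
#' between-class sampling variability, p-values from this procedure are
#' anti-conservative; they are reported for comparability, with a note.
#'
#' @param boot_a,boot_b numeric vectors of bootstrap means (length >= 2).
#' @return a `troopnet_test`.
#' @export
t_test_bootstrap <- function(boot_a, boot_b) {
  if (length(boot_a) < 2 || length(boot_b) < 2)
    stop("both bootstrap samples need length >= 2")
  if (stats::var(boot_a) == 0 && stats::var(boot_b) == 0) {
    equal <- isTRUE(all.equal(mean(boot_a), mean(boot_b)))
    return(new_test_result("welch_t_bootstrap",
                           if (equal) 0 else Inf, NA_real_,
                           if (equal) 1 else 0,
                           notes = "degenerate: zero variance"))
  }
  tt <- stats::t.test(boot_a, boot_b)
  new_test_result("welch_t_bootstrap", unname(tt$statistic),
                  unname(tt$parameter), tt$p.value,
                  notes = "bootstrap-distribution t-test; anti-conservative p")
}

#' Variance and normality diagnostics
#'
#' Brown-Forsythe/Levene test (absolute deviations from group medians,
#' one-way ANOVA F) for homogeneity of variances, plus a Shapiro-Wilk test
#' per group. Used to route analyses toward rank-based tests; groups too
#' small (or constant) are flagged not-computable (`NA`).
#'
#' @param groups list of numeric vectors.
#' @return list with `levene` (a `troopnet_test`) and `shapiro` (data frame
#'   of per-group W and p, `NA` where not computable).
#' @export
variance_diagnostics <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  z <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  g <- factor(rep(seq_along(groups), sizes))
  levene <- if (stats::var(z) == 0) {
    new_test_result("levene_median", 0, c(length(groups) - 1L,
                                          sum(sizes) - length(groups)), 1,
                    notes = "degenerate: zero spread in all groups")
  } else {
    av <- stats::anova(stats::lm(z ~ g))
    new_test_result("levene_median", av$`F value`[1],
                    c(av$Df[1], av$Df[2]), av$`Pr(>F)`[1])
  }
  shapiro <- do.call(rbind, lapply(seq_along(groups), function(i) {
    x <- groups[[i]]
    ok <- length(x) >= 3 && length(x) <= 5000 && stats::var(x) > 0
    if (ok) {
      sw <- stats::shapiro.test(x)
      data.frame(group = i, W = unname(sw$statistic), p_value = sw$p.value,
                 computable = TRUE)
    } else {
      data.frame(group = i, W = NA_real_, p_value = NA_real_,
                 computable = FALSE)
    }
  }))
  list(levene = levene, shapiro = shapiro)
}

#' Holm correction helper
#'
#' The analyses report unadjusted p-values by default (no correction is
#' applied anywhere in the standard pipeline); this helper lets users apply
#' a Holm adjustment to any table of results.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
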