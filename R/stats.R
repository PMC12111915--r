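# Statistical reporting: block-averaged mean +/- SEM for autocorrelated
# frame series, and distribution-aware group comparison.

#' Block-averaged mean and standard error
#'
#' Frame series from a trajectory are autocorrelated, so the naive SEM
#' understates the uncertainty. The series is split into `n_blocks`
#' contiguous blocks; the reported SEM is the standard deviation of the
#' block means divided by `sqrt(n_blocks)`.
#'
#' @param x Numeric vector, or a `"time_series"` tibble (its `value`
#'   column is used).
#' @param n_blocks Number of contiguous blocks, >= 2 (default 5).
#' @return Tibble: `mean`, `sem`, `n`, `n_blocks`.
#' @export
#' @examples
#' block_average(rnorm(1000))
block_average <- function(x, n_blocks = 5L) {
  if (is.data.frame(x)) x <- x$value
  n <- length(x)
  if (n_blocks < 2L) abort("n_blocks must be >= 2")
  if (n < n_blocks) abort("series shorter than the number of blocks")
  blocks <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- vapply(split(x, blocks), mean, numeric(1))
  tibble(mean = mean(x), sem = sd(bm) / sqrt(n_blocks), n = n,
         n_blocks = n_blocks)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the sample against a normal distribution with the
#' sample's own mean and standard deviation. Estimating the parameters
#' from the data makes the test conservative (true p-values run high);
#' it is used here only as a gate between parametric and non-parametric
#' group comparison.
#'
#' @param x Numeric sample, length >= 8.
#' @return KS p-value.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) {
    abort("normality check needs at least 8 observations")
  }
  if (sd(x) == 0) return(0)
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))$p.value
}

#' Compare groups with a distribution-aware test
#'
#' Each group is screened with [ks_normality()]; if every group passes at
#' `alpha`, a one-way ANOVA compares the groups, otherwise the
#' Kruskal-Wallis rank-sum test is used. Groups too small for the
#' normality check (n < 8) do not trigger the non-parametric branch: their
#' normality p-value is recorded as `NA` and they are treated as
#' parametric. Significance stars follow the usual thresholds (`****` for
#' p < 0.0001).
#'
#' @param data Data frame in long format, or a named list of numeric
#'   vectors.
#' @param value,group Column names when `data` is a data frame.
#' @param alpha Normality-gate level, default 0.05.
#' @return Object of class `"group_comparison"`; see
#'   [tidy.group_comparison()].
#' @export
#' @examples
#' samples <- gen_group_samples(c(0, 1), c(1, 1), 50, seed = 7)
#' compare_groups(samples)
compare_groups <- function(data, value = "value", group = "group",
                           alpha = 0.05) {
  if (is.data.frame(data)) {
    groups <- split(data[[value]], data[[group]])
  } else {
    groups <- data
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  }
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) abort("need at least 2 non-empty groups")
  norm_p <- vapply(groups, function(g) {
    if (length(g) < 8L) NA_real_ else ks_normality(g)
  }, numeric(1))
  all_normal <- all(is.na(norm_p) | norm_p > alpha)
  long <- tibble(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  if (all_normal) {
    fit <- aov(value ~ group, data = long)
    s <- summary(fit)[[1L]]
    statistic <- s[["F value"]][1L]
    p <- s[["Pr(>F)"]][1L]
    test_used <- "anova"
  } else {
    kw <- kruskal.test(value ~ group, data = long)
    statistic <- unname(kw$statistic)
    p <- kw$p.value
    test_used <- "kruskal_wallis"
  }
  per_group <- tibble(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, sd, numeric(1)),
    normality_p = norm_p
  )
  structure(
    list(
      test_used = test_used, statistic = statistic, p_value = p,
      stars = p_stars(p), per_group = per_group, alpha = alpha
    ),
    class = "group_comparison"
  )
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "# group comparison: %s, statistic = %.4g, p = %.4g %s\n",
    x$test_used, x$statistic, x$p_value, x$stars
  ))
  print(x$per_group)
  invisible(x)
}
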