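# Skin-tone bias statistics: one-way ANOVA on raw samples or on
# published group moments, and pairwise percent differences between
# tone transmission ratios.

anova_result <- function(f_stat, df_between, df_within) {
  structure(list(
    f_stat = f_stat,
    df_between = df_between,
    df_within = df_within,
    p_value = stats::pf(f_stat, df_between, df_within, lower.tail = FALSE)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.6g, p = %.3g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' One-way ANOVA on raw group samples
#'
#' Classical between/within sum-of-squares decomposition:
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)`; the p-value
#' comes from the F distribution.
#'
#' @param groups List of numeric vectors, at least 2 groups of at least 2
#'   observations each.
#' @return Object of class `anova_result` with `f_stat`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F(2,6) = 3
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    ox_stop("need at least two groups", "oxitone_input_error")
  }
  ns <- lengths(groups)
  if (any(ns < 2)) {
    ox_stop("every group needs at least 2 observations",
            "oxitone_input_error")
  }
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / sum(ns)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- sum(ns) - length(groups)
  ms_w <- ss_within / df_w
  f <- if (ms_w == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df_b) / ms_w
  }
  anova_result(f, df_b, df_w)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F statistic when only each group's size, mean and
#' standard deviation are published: the between-group mean square from
#' the means, the within-group mean square as the pooled variance. With
#' exact moments this equals [one_way_anova()] on the raw data.
#'
#' @param summaries Data frame with columns `n` (>= 2), `mean`, `sd`
#'   (>= 0), one row per group; or a list of such per-group lists.
#' @return Object of class `anova_result`.
#' @export
#' @examples
#' anova_from_summary(data.frame(n = 3, mean = c(2, 3, 4), sd = 1))
anova_from_summary <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  stopifnot(all(c("n", "mean", "sd") %in% names(summaries)))
  if (nrow(summaries) < 2) {
    ox_stop("need at least two group summaries", "oxitone_input_error")
  }
  if (any(summaries$n < 2)) {
    ox_stop("every group needs n >= 2", "oxitone_input_error")
  }
  if (any(summaries$sd < 0)) {
    ox_stop("standard deviations must be non-negative",
            "oxitone_input_error")
  }
  ns <- summaries$n; means <- summaries$mean; sds <- summaries$sd
  grand <- sum(ns * means) / sum(ns)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df_b <- nrow(summaries) - 1L
  df_w <- sum(ns) - nrow(summaries)
  ms_w <- ss_within / df_w
  f <- if (ms_w == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df_b) / ms_w
  }
  anova_result(f, df_b, as.integer(df_w))
}

#' Pairwise percent differences between tone ratios
#'
#' Symmetric matrix of `100 * |a - b| / max(a, b)` for every pair of
#' transmission ratios; the diagonal is `NA` (a ratio compared with
#' itself). The max-denominator form is used so the percentage is
#' bounded by 100 and symmetric in its arguments.
#'
#' @param ratios Named numeric vector of positive ratios (names = tone
#'   classes).
#' @return Square matrix of percents with `NA` diagonal.
#' @export
#' @examples
#' pairwise_percent_difference(c(`3` = 0.94, `2` = 0.91))
pairwise_percent_difference <- function(ratios) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    ox_stop("ratios must be positive and finite", "oxitone_domain_error")
  }
  k <- length(ratios)
  m <- 100 * abs(outer(ratios, ratios, `-`)) /
    outer(ratios, ratios, pmax)
  diag(m) <- NA_real_
  dimnames(m) <- list(names(ratios), names(ratios))
  m
}
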