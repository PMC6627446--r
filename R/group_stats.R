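#' Kruskal-Wallis rank-sum test across groups
#'
#' Thin validating wrapper over [stats::kruskal.test()] (mid-ranks, tie
#' correction, chi-square reference with k - 1 df). When every
#' observation is identical the test statistic is 0 and p = 1 by
#' convention (the rank distribution is degenerate); a message notes it.
#'
#' @param groups Named (or unnamed) list of >= 2 non-empty numeric
#'   vectors.
#' @return List of class `group_test`: `test_name`, `statistic`,
#'   `p_value`, `groups`, `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("every group must be non-empty")
  labels <- if (is.null(names(groups)))
    paste0("group", seq_along(groups)) else names(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    message("all observations identical; H = 0, p = 1 by convention")
    stat <- 0
    p <- 1
  } else {
    kt <- stats::kruskal.test(groups)
    stat <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(test_name = "Kruskal-Wallis", statistic = stat,
                 p_value = p, groups = labels,
                 n_per_group = unname(vapply(groups, length, 1L))),
            class = "group_test")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration when the combined sample size is at
#' most 12 and there are no ties (small groups need exact behaviour);
#' otherwise the normal approximation with tie and continuity correction.
#' Delegates to [stats::wilcox.test()].
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` applies the combined-n-at-most-12, tie-free rule.
#' @return List of class `group_test` with the W statistic and p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact))
    exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  structure(list(test_name = "Wilcoxon rank-sum",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 groups = c("a", "b"),
                 n_per_group = c(length(a), length(b))),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), " (n = ",
      paste(x$n_per_group, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR correction via [stats::p.adjust()] with input-range
#' validation; original order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) == 0L)
    return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
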