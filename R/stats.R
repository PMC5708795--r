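comparison_result <- function(test_name, statistic, p_value, group_labels,
                              n, adjusted = FALSE) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = min(unname(p_value), 1), group_labels = group_labels,
         n = n, adjusted = adjusted),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g%s\n",
              x$test_name, paste(x$group_labels, collapse = " vs "),
              x$statistic, x$p_value,
              if (x$adjusted) " (adjusted)" else ""))
  invisible(x)
}

#' Mann-Whitney U test (two independent samples)
#'
#' Two-sided; exact when both samples have at most 8 untied observations,
#' otherwise the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param x,y Numeric samples.
#' @param labels Group labels for reporting.
#' @param exact_max Largest per-group n for which the exact distribution is
#'   used.
#' @return A `comparison_result` (statistic = U).
#' @export
mann_whitney_u <- function(x, y, labels = c("x", "y"), exact_max = 8) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  comparison_result("Mann-Whitney U", ht$statistic, ht$p.value, labels,
                    c(length(x), length(y)))
}

#' Wilcoxon signed-rank test (paired samples)
#'
#' Two-sided; zero differences are dropped (Wilcoxon's original convention);
#' exact when at most 12 non-zero untied differences remain.
#'
#' @param pre,post Paired numeric samples of equal length.
#' @param labels Labels for reporting.
#' @param exact_max Largest n of non-zero differences for the exact
#'   distribution.
#' @return A `comparison_result` (statistic = V).
#' @export
wilcoxon_signed_rank <- function(pre, post, labels = c("pre", "post"),
                                 exact_max = 12) {
  if (length(pre) != length(post)) stop("samples must be paired (equal length)")
  d <- post - pre
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero; test degenerate")
  exact <- length(d) <= exact_max && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = FALSE)
  )
  comparison_result("Wilcoxon signed rank", ht$statistic, ht$p.value, labels,
                    length(d))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction, chi-squared p on k - 1 degrees of
#' freedom.
#'
#' @param groups List of numeric samples (>= 2 non-empty groups).
#' @return A `comparison_result` (statistic = H).
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(unlist(groups))) == 1) {
    # completely tied data: H = 0 by convention (kruskal.test gives 0/0)
    return(comparison_result("Kruskal-Wallis", 0, 1,
                             names(groups) %||% paste0("g", seq_along(groups)),
                             lengths(groups)))
  }
  ht <- stats::kruskal.test(groups)
  comparison_result("Kruskal-Wallis", ht$statistic, ht$p.value,
                    names(groups) %||% paste0("g", seq_along(groups)),
                    lengths(groups))
}

#' Dunn's multiple-comparison test
#'
#' Pairwise post-hoc comparisons after Kruskal-Wallis on the joint ranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`; two-sided normal p, optionally
#' Bonferroni-multiplied over the number of pairs and capped at 1.
#'
#' @param groups Named list of numeric samples.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A list of `comparison_result`, one per pair.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least 2 non-empty groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  grp <- rep(names(groups), lengths(groups))
  rbar <- tapply(rk, grp, mean)[names(groups)]
  n <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  n_pairs <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1)) {
    for (jj in (i + 1):k) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[jj]))
      z <- (rbar[i] - rbar[jj]) / se
      p <- 2 * stats::pnorm(-abs(z))
      if (adjust == "bonferroni") p <- min(1, p * n_pairs)
      out[[paste(names(groups)[i], names(groups)[jj], sep = "/")]] <-
        comparison_result("Dunn post hoc", z, p,
                          c(names(groups)[i], names(groups)[jj]),
                          c(n[i], n[jj]), adjusted = adjust == "bonferroni")
    }
  }
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson form without continuity correction by default (the study's
#' sex-by-group and eye-by-group tables are 2 x 3).
#'
#' @param tbl Matrix of non-negative counts.
#' @param correct Apply Yates continuity correction (2 x 2 only).
#' @return A `comparison_result` (statistic = X-squared).
#' @export
chi2_test <- function(tbl, correct = FALSE) {
  tbl <- as.matrix(tbl)
  if (any(tbl < 0)) stop("counts must be non-negative")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stop("contingency table has a zero marginal")
  }
  ht <- suppressWarnings(stats::chisq.test(tbl, correct = correct))
  comparison_result("Chi-squared", ht$statistic, ht$p.value,
                    rownames(tbl) %||% paste0("r", seq_len(nrow(tbl))),
                    rowSums(tbl))
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors (n >= 3, non-constant).
#' @param pair Label of the variable pair.
#' @return An object of class `correlation_result` with `r` and `p_value`.
#' @export
pearson_r <- function(x, y, pair = c("x", "y")) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(variable_pair = pair, r = unname(ht$estimate),
         p_value = ht$p.value, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%s) = %.3f, p = %.4g (n = %d)\n",
              paste(x$variable_pair, collapse = ", "), x$r, x$p_value, x$n))
  invisible(x)
}
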