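#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table. The two-sided p-value
#' follows the probability-mass convention: with the table margins fixed,
#' it sums the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (a relative
#' slack of 1e-7 guards against floating-point ties). This is the
#' convention used by mainstream clinical statistics software for
#' baseline-characteristics tables.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A list of class `ecm_test` with `statistic` (the odds-ratio
#'   numerator-count, i.e. the top-left cell), `p_value`, `method` and
#'   the group sizes.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 20, 8, 12), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("fisher_exact_2x2 requires a 2x2 table; use chi_square for 2xk")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  m <- sum(table[1, ])          # row 1 margin
  n <- sum(table[2, ])          # row 2 margin
  k <- sum(table[, 1])          # column 1 margin
  x <- table[1, 1]
  if (m + n == 0) stop("at least one margin must be nonzero")
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_ecm_test(statistic = x, p_value = min(1, p),
               method = "Fisher exact (two-sided, probability mass)",
               n = c(m, n))
}

#' Pearson chi-square test for a 2xk table
#'
#' @param table 2xk matrix of counts.
#' @param yates apply Yates continuity correction (2x2 only).
#' @return `ecm_test` with the Pearson statistic, degrees of freedom in
#'   `df`, and p-value.
#' @export
chi_square <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("chi_square requires a 2xk table")
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  out <- new_ecm_test(statistic = unname(res$statistic),
                      p_value = unname(res$p.value),
                      method = if (yates) "Chi-square (Yates)" else "Chi-square",
                      n = rowSums(table))
  out$df <- unname(res$parameter)
  out
}

#' Choose between chi-square and Fisher for a contingency table
#'
#' Applies the conventional rule: Fisher's exact test when any expected
#' cell count is below five, chi-square otherwise (an expected count of
#' exactly five selects chi-square). For 2x2 tables the Fisher p-value is
#' reported alongside regardless of the selection, since exact reporting
#' is common for small clinical cohorts even when expectations exceed
#' five.
#'
#' @param table 2xk count matrix.
#' @return list with `test` ("fisher" or "chi_square"), `min_expected`,
#'   `result` (the selected `ecm_test`), and for 2x2 tables `fisher_p`.
#' @export
select_test <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  choice <- if (any(expected < 5)) "fisher" else "chi_square"
  is22 <- all(dim(table) == c(2L, 2L))
  if (choice == "fisher" && !is22)
    stop("exact test selected for a table wider than 2x2; not supported")
  result <- if (choice == "fisher") fisher_exact_2x2(table) else chi_square(table)
  out <- list(test = choice, min_expected = min(expected), result = result)
  if (is22) out$fisher_p <- fisher_exact_2x2(table)$p_value
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact two-sided
#' p-value (full enumeration of the U null distribution) is used when
#' the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric vectors.
#' @return `ecm_test` with the U statistic (for `a` relative to `b`).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups need n >= 1")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  out <- new_ecm_test(statistic = unname(res$statistic),
                      p_value = unname(res$p.value),
                      method = if (exact) "Mann-Whitney U (exact)"
                               else "Mann-Whitney U (normal approximation)",
                      n = c(length(a), length(b)))
  out
}

#' Cohort characteristics summary table
#'
#' Summarises a one-row-per-patient cohort table by group: continuous
#' variables as median and interquartile range (linear-interpolation
#' quantiles) with a Mann-Whitney U p-value; binary flags as count and
#' percentage with an exact Fisher p-value (chi-square when all expected
#' counts are at least five and the table is wider than 2x2).
#'
#' @param cohort data.frame with one row per patient.
#' @param group_col name of the two-level grouping column.
#' @param digits decimals for the displayed p-value (values below
#'   10^-digits are shown as e.g. "< 0.001").
#' @return data.frame with one row per variable: per-group summary
#'   strings, the numeric p-value and its display string.
#' @export
summarise_cohort <- function(cohort, group_col = "group", digits = 3) {
  stopifnot(group_col %in% names(cohort))
  g <- factor(cohort[[group_col]])
  if (nlevels(g) != 2L) stop("summarise_cohort expects exactly two groups")
  vars <- setdiff(names(cohort), group_col)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is_binary_flag(x)) {
      xi <- as.integer(as.logical(x))
      tab <- rbind(table(factor(xi, levels = c(1, 0))[g == levels(g)[1]]),
                   table(factor(xi, levels = c(1, 0))[g == levels(g)[2]]))
      sel <- select_test(tab)
      p <- if (!is.null(sel$fisher_p)) sel$fisher_p else sel$result$p_value
      summ <- vapply(levels(g), function(gl) {
        n1 <- sum(xi[g == gl]); n <- sum(g == gl)
        sprintf("%d (%d)", n1, round(100 * n1 / n))
      }, character(1))
    } else {
      x <- as.numeric(x)
      p <- mann_whitney_u(x[g == levels(g)[1]], x[g == levels(g)[2]])$p_value
      summ <- vapply(levels(g), function(gl) {
        q <- stats::quantile(x[g == gl], c(.25, .5, .75), type = 7, names = FALSE)
        sprintf("%g [%g-%g]", signif(q[2], 3), signif(q[1], 3), signif(q[3], 3))
      }, character(1))
    }
    data.frame(variable = v, g1 = summ[1], g2 = summ[2],
               p_value = p, p_display = format_p(p, digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- levels(g)
  out
}

format_p <- function(p, digits = 3) {
  cut <- 10^-digits
  ifelse(p < cut, paste0("< ", format(cut, scientific = FALSE)),
         formatC(p, digits = digits, format = "f"))
}

is_binary_flag <- function(x) {
  is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
}

new_ecm_test <- function(statistic, p_value, method, n,
                         q_value = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 q_value = q_value, method = method, n = n),
            class = "ecm_test")
}

#' @export
print.ecm_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", signif(x$statistic, 5),
      " p =", format_p(x$p_value), "\n")
  if (!is.na(x$q_value)) cat("  q =", format_p(x$q_value), "\n")
  invisible(x)
}
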