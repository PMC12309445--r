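#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic \eqn{\sum (O-E)^2/E} with
#' \eqn{df = (r-1)(c-1)} and no continuity correction (the convention used
#' throughout the unit-proportion comparisons here).
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @return list of class `contingency_test`: `statistic`, `df`, `p.value`,
#'   `observed`, `expected`.
#' @examples
#' chi_square(rbind(c(13, 5, 112), c(1, 1, 112)))$statistic  # 11.95
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal; consider fisher_exact()")
  r <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(r$statistic), df = unname(r$parameter),
                 p.value = r$p.value, observed = table,
                 expected = r$expected),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2(%d) = %.4f, p = %.4g\n",
              x$df, x$statistic, x$p.value))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test, used for proportion comparisons with small
#' counts (n < 5). Two-sided by default.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `p.value`, `alternative`, `observed`.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("fisher_exact requires a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain nonnegative integer counts")
  r <- stats::fisher.test(table, alternative = alternative)
  list(p.value = r$p.value, alternative = alternative, observed = table)
}

#' Phi effect size for a contingency test
#'
#' \eqn{\phi = \sqrt{\chi^2 / D}}. Two denominator conventions are
#' supported: the standard total table count (`"total_N"`), and the number
#' of responsive units only (`"responsive_m"`) -- the sum of all counts
#' outside the `none` column, which is the convention behind the published
#' effect sizes this package reproduces (e.g. \eqn{\sqrt{11.95/20} = 0.77}).
#'
#' @param result a [chi_square()] result (or a bare chi-square value, in
#'   which case `m` must be given).
#' @param denominator `"responsive_m"` (default) or `"total_N"`.
#' @param m responsive-unit count; if NULL it is derived from the result's
#'   observed table by dropping `none_col`.
#' @param none_col index or name of the non-responsive column (default: the
#'   last column).
#' @return phi (numeric scalar).
#' @export
phi_effect <- function(result, denominator = c("responsive_m", "total_N"),
                       m = NULL, none_col = NULL) {
  denominator <- match.arg(denominator)
  chi2 <- if (inherits(result, "contingency_test")) result$statistic
          else as.numeric(result)
  if (denominator == "total_N") {
    d <- if (inherits(result, "contingency_test")) sum(result$observed)
         else m
  } else if (!is.null(m)) {
    d <- m
  } else {
    if (!inherits(result, "contingency_test"))
      stop("supply 'm' when 'result' is a bare statistic")
    obs <- result$observed
    nc <- none_col %||% ncol(obs)
    d <- sum(obs[, -nc, drop = FALSE])
  }
  if (is.null(d) || d <= 0) stop("undefined phi: nonpositive denominator")
  sqrt(chi2 / d)
}

#' Two-sample and paired t tests with Cohen's d
#'
#' Wraps the standard t tests and adds the effect size: pooled-SD Cohen's d
#' for independent and Welch comparisons, mean-difference SD for paired.
#' Welch's test (Satterthwaite df) is the appropriate mode when group sizes
#' or variances differ.
#'
#' @param x,y numeric vectors (equal length required for `paired`).
#' @param mode `"independent"` (pooled variance), `"welch"` or `"paired"`.
#' @param alternative passed to [stats::t.test()].
#' @return data.frame row: `t`, `df`, `p`, `cohens_d`, `mode`.
#' @export
t_tests <- function(x, y, mode = c("independent", "welch", "paired"),
                    alternative = "two.sided") {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  # degenerate zero-variance comparisons (e.g. identical vectors): report
  # t = 0 / d = 0 rather than the error stats::t.test raises
  degen <- if (mode == "paired") stats::sd(x - y) == 0 else
    stats::sd(x) == 0 && stats::sd(y) == 0
  if (degen && isTRUE(all.equal(mean(x), mean(y)))) {
    df0 <- if (mode == "paired") length(x) - 1 else length(x) + length(y) - 2
    return(data.frame(t = 0, df = df0, p = 1, cohens_d = 0, mode = mode,
                      stringsAsFactors = FALSE))
  }
  r <- switch(mode,
    independent = stats::t.test(x, y, var.equal = TRUE,
                                alternative = alternative),
    welch = stats::t.test(x, y, var.equal = FALSE, alternative = alternative),
    paired = {
      if (length(x) != length(y)) stop("paired test requires equal lengths")
      stats::t.test(x, y, paired = TRUE, alternative = alternative)
    })
  d <- if (mode == "paired") {
    dd <- x - y
    mean(dd) / stats::sd(dd)
  } else {
    n1 <- length(x); n2 <- length(y)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    (mean(x) - mean(y)) / sp
  }
  data.frame(t = unname(r$statistic), df = unname(r$parameter),
             p = r$p.value, cohens_d = d, mode = mode,
             stringsAsFactors = FALSE)
}
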