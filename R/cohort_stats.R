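# Cohort assembly and statistics: compliance ratios, paired comparisons with
# a normality gate and Holm correction, Spearman correlation matrices,
# descriptive summaries.

#' Arterial-related physiological compliance C_physio
#'
#' `C_physio = dV_ART / dP_CC`: cerebral arterial volume change over one
#' cardiac cycle divided by the amplitude of the average baseline ICP pulse.
#'
#' @param delta_v_art Arterial volume-change amplitude, mL (>= 0).
#' @param delta_p_cc ICP pulse amplitude, mmHg (> 0).
#' @return Compliance, mL/mmHg.
#' @examples
#' c_physio(6.0, 3.0)  # 2.0 mL/mmHg
#' @export
c_physio <- function(delta_v_art, delta_p_cc) {
  if (any(!is.finite(delta_v_art)) || any(!is.finite(delta_p_cc))) {
    stopf("non-finite input to c_physio")
  }
  if (any(delta_p_cc <= 0)) {
    stopf("dP_CC must be > 0 mmHg (got %s)",
          paste(format(delta_p_cc[delta_p_cc <= 0]), collapse = ", "))
  }
  if (any(delta_v_art < 0)) stopf("dV_ART must be >= 0 mL")
  delta_v_art / delta_p_cc
}

#' Coefficient of variation in percent
#'
#' `100 * SD / mean`, with the sample (n - 1) standard deviation.
#'
#' @param values Numeric vector (mean must be nonzero).
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stopf("no finite values")
  m <- mean(values)
  if (m == 0) stopf("CV%% undefined for zero mean")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  100 * s / m
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk is applied to the paired differences; if its p-value is at
#' least `alpha` a paired Student's t-test is used, otherwise a two-sided
#' Wilcoxon signed-rank test (exact for <= 25 nonzero differences, normal
#' approximation with continuity correction beyond; zero differences are
#' dropped; if all differences are zero the p-value is 1).
#'
#' @param x,y Paired numeric vectors (equal length >= 5).
#' @param alpha Normality-gate level.
#' @param label Comparison label carried into the result.
#' @return One-row `data.frame`: `label`, `test_used`, `statistic`, `p_raw`,
#'   `normality_p`. Holm adjustment across a family is added separately by
#'   [holm_adjust()].
#' @export
paired_compare <- function(x, y, alpha = 0.05, label = "x vs y") {
  if (length(x) != length(y)) stopf("paired vectors differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stopf("need at least 5 complete pairs, have %d", n)
  d <- x - y
  sw_p <- tryCatch(stats::shapiro.test(d)$p.value,
                   error = function(e) NA_real_)  # constant differences
  use_t <- !is.na(sw_p) && sw_p >= alpha
  if (use_t) {
    ht <- stats::t.test(d)
    res <- data.frame(label = label, test_used = "paired-t",
                      statistic = unname(ht$statistic),
                      p_raw = ht$p.value, normality_p = sw_p,
                      stringsAsFactors = FALSE)
  } else {
    nz <- d[d != 0]
    if (length(nz) == 0L) {
      res <- data.frame(label = label, test_used = "wilcoxon",
                        statistic = NA_real_, p_raw = 1,
                        normality_p = sw_p, stringsAsFactors = FALSE)
    } else {
      exact <- length(nz) <= 25L
      ht <- suppressWarnings(
        stats::wilcox.test(nz, exact = exact, correct = TRUE))
      res <- data.frame(label = label, test_used = "wilcoxon",
                        statistic = unname(ht$statistic),
                        p_raw = ht$p.value, normality_p = sw_p,
                        stringsAsFactors = FALSE)
    }
  }
  res
}

#' Holm step-down multiple-testing adjustment
#'
#' Sort ascending, multiply the i-th smallest of m p-values by
#' `m - i + 1`, enforce monotonicity with a running maximum, cap at 1,
#' return in the original order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Spearman rank-correlation matrix with pairwise-complete handling
#'
#' Tie-corrected (average-rank) Spearman correlation and two-sided p-value
#' for every variable pair, using pairwise-complete observations. Pairs with
#' fewer than 5 complete rows, or with a constant variable (rank correlation
#' undefined), are flagged rather than propagated as `NaN`.
#'
#' @param table A `data.frame` of per-subject metrics.
#' @param variables Column names to correlate.
#' @return An object of class `spearman_matrix`: matrices `r`, `p`,
#'   logical `flagged`, and `variables`.
#' @export
spearman_matrix <- function(table, variables) {
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars)) {
    stopf("variables not in table: %s", paste(missing_vars, collapse = ", "))
  }
  m <- length(variables)
  R <- diag(1, m)
  P <- matrix(NA_real_, m, m)
  FL <- matrix(FALSE, m, m)
  dimnames(R) <- dimnames(P) <- dimnames(FL) <- list(variables, variables)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      xi <- table[[variables[i]]]
      xj <- table[[variables[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      if (sum(ok) < 5L || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
        R[i, j] <- R[j, i] <- NA_real_
        FL[i, j] <- FL[j, i] <- TRUE
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(xi[ok], xj[ok], method = "spearman", exact = FALSE))
      R[i, j] <- R[j, i] <- unname(ct$estimate)
      P[i, j] <- P[j, i] <- ct$p.value
    }
  }
  structure(list(r = R, p = P, flagged = FL, variables = variables),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("<spearman_matrix> R:\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Descriptive cohort summary (mean, SD, quartiles, CV%)
#'
#' Per variable: n, mean, SD, Q1 and Q3 (linear-interpolation quantiles,
#' type 7) and CV%. With a single row the SD is reported as 0 with a
#' warning; CV% is `NA` for zero-mean variables.
#'
#' @param table A `data.frame` of per-subject metrics.
#' @param variables Column names to summarise; default all numeric columns.
#' @return A `data.frame` with one row per variable.
#' @export
cohort_summary <- function(table, variables = NULL) {
  if (nrow(table) == 0L) stopf("empty cohort table")
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  single <- FALSE
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n == 1L) single <<- TRUE
    s <- if (n > 1L) stats::sd(x) else 0
    m <- mean(x)
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(variable = v, n = n, mean = m, sd = s,
               q1 = q[1], q3 = q[2],
               cv_percent = if (m == 0) NA_real_ else 100 * s / m,
               stringsAsFactors = FALSE)
  })
  if (single) warnf("variable(s) with a single value: SD reported as 0")
  do.call(rbind, rows)
}
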