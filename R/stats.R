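#' One-way repeated-measures ANOVA
#'
#' Within-subject F test for a subjects x levels matrix:
#' `F = MS_condition / MS_(condition x subject)` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`. Sphericity is assumed (no correction is
#' applied by default, matching the convention of reporting uncorrected
#' within-subject F tests); a Greenhouse-Geisser epsilon correction is
#' available but off by default.
#'
#' @param values numeric matrix, rows = subjects (>= 3), columns =
#'   within-subject levels (>= 2), no missing cells.
#' @param gg apply the Greenhouse-Geisser sphericity correction.
#' @return object of class `kd_test`: `statistic` (F), `df` (length 2),
#'   `p_value`, `degenerate` flag.
#' @export
rm_anova <- function(values, gg = FALSE) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 levels")
  if (anyNA(values)) stop("missing cells are not supported")
  grand <- mean(values)
  col_m <- colMeans(values)
  row_m <- rowMeans(values)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_err <- sum((values - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  scale <- mean(values^2) + 1
  if (ss_cond / scale < 1e-12) {
    return(kd_test(statistic = 0, df = c(df1, df2), p_value = 1,
                   degenerate = ss_err / scale < 1e-12, method = "rm_anova"))
  }
  if (ss_err / scale < 1e-12) {
    return(kd_test(statistic = Inf, df = c(df1, df2), p_value = 0,
                   degenerate = TRUE, method = "rm_anova"))
  }
  f <- (ss_cond / df1) / (ss_err / df2)
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centred covariance
    s <- stats::cov(values)
    dc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) + mean(s)
    eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
    eps <- min(1, max(1 / (k - 1), eps))
  }
  kd_test(statistic = f, df = c(df1 * eps, df2 * eps),
          p_value = stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE),
          degenerate = FALSE, method = if (gg) "rm_anova_gg" else "rm_anova")
}

kd_test <- function(statistic, df, p_value, degenerate = FALSE,
                    method = "", adjusted_p = NULL, levels = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 adjusted_p = adjusted_p, degenerate = degenerate,
                 method = method, levels = levels),
            class = "kd_test")
}

#' @export
print.kd_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g",
              x$method, x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  if (!is.null(x$adjusted_p)) cat(sprintf(", adjusted p = %.4g", x$adjusted_p))
  if (isTRUE(x$degenerate)) cat("  [degenerate data]")
  cat("\n")
  invisible(x)
}

#' Bonferroni-adjusted pairwise paired t tests
#'
#' All `k(k-1)/2` two-sided paired t tests between level columns, with the
#' Bonferroni family size equal to the number of pairwise comparisons
#' within this family (6 for four flexion levels, 3 for three drill
#' angles).
#'
#' @param values numeric matrix, rows = subjects, columns = levels.
#' @return list of `kd_test` objects, one per pair, each with `levels`
#'   naming the compared columns and `adjusted_p = min(1, p * m)`.
#' @export
bonferroni_pairs <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2L) stop("need at least two levels")
  lev <- colnames(values)
  if (is.null(lev)) lev <- paste0("level", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- values[, i1] - values[, i2]
    if (stats::sd(d) < 1e-12 * (mean(abs(values)) + 1)) {
      p <- if (abs(mean(d)) < 1e-12) 1 else 0
      st <- if (p == 1) 0 else Inf
      return(kd_test(st, df = length(d) - 1, p_value = p, degenerate = TRUE,
                     method = "paired_t", levels = lev[c(i1, i2)]))
    }
    tt <- stats::t.test(values[, i1], values[, i2], paired = TRUE)
    kd_test(unname(tt$statistic), df = unname(tt$parameter),
            p_value = tt$p.value, method = "paired_t", levels = lev[c(i1, i2)])
  })
  raw <- vapply(out, function(x) x$p_value, numeric(1))
  adj <- stats::p.adjust(raw, method = "bonferroni", n = m)
  for (j in seq_len(m)) out[[j]]$adjusted_p <- adj[j]
  out
}

#' Cochran's Q test for repeated dichotomous outcomes
#'
#' `Q = k(k-1) * sum_j (C_j - T/k)^2 / (k*T - sum_i R_i^2)` with column
#' sums `C_j`, row sums `R_i` and grand total `T`, referred to a chi-square
#' distribution with `k - 1` degrees of freedom. Rows that are all 0 or
#' all 1 carry no information; if every row is constant the test is
#' degenerate and reports `Q = 0`, `p = 1`.
#'
#' @param indicators 0/1 matrix, rows = subjects, columns = levels.
#' @return a `kd_test`.
#' @export
cochran_q <- function(indicators) {
  x <- as.matrix(indicators)
  if (!all(x %in% c(0, 1))) stop("indicators must be 0/1")
  k <- ncol(x)
  if (k < 2L) stop("need at least two levels")
  Tt <- sum(x)
  Cj <- colSums(x)
  Ri <- rowSums(x)
  denom <- k * Tt - sum(Ri^2)
  if (denom <= 0) {
    return(kd_test(statistic = 0, df = k - 1, p_value = 1, degenerate = TRUE,
                   method = "cochran_q"))
  }
  q <- k * (k - 1) * sum((Cj - Tt / k)^2) / denom
  kd_test(statistic = q, df = k - 1,
          p_value = stats::pchisq(q, k - 1, lower.tail = FALSE),
          method = "cochran_q")
}
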