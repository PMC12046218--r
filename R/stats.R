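# Statistical layer: Pearson correlation, t tests, repeated-measures ANOVA
# with Bonferroni pairwise comparisons, and 2x2 chi-squared on escape counts.
# Scalar tests delegate to stats::cor.test / t.test / chisq.test; the
# within-subject ANOVA decomposition is computed directly so both error
# strata are available in a uniform result object.

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation between two samples, with the two-sided p
#' value from the t transform on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return A `correlation_result` list: `r`, `r_squared`, `p`, `n`, `df`,
#'   `statistic` (the t value).
#' @export
#' @examples
#' pearson_cor(1:10, (1:10) * 2 + rnorm(10))
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, n = n, df = unname(ct$parameter),
                 statistic = unname(ct$statistic)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (R^2 = %.4f), t(%d) = %.3f, p = %.4g, n = %d\n",
              x$r, x$r_squared, x$df, x$statistic, x$p, x$n))
  invisible(x)
}

#' Two-sample t test (pooled-variance or paired)
#'
#' Unpaired comparisons use the pooled-variance t statistic on
#' `n1 + n2 - 2` degrees of freedom (not Welch); paired comparisons use the
#' one-sample t on the differences with `n - 1` degrees of freedom. Two-sided.
#'
#' @param a,b numeric vectors; equal length required when `paired = TRUE`.
#' @param paired logical.
#' @return A `t_test_result` list: `statistic`, `df`, `p`, `paired`,
#'   `estimate` (mean difference).
#' @export
t_test2 <- function(a, b, paired = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), is.logical(paired))
  if (anyNA(a) || anyNA(b)) stop("NA values are not allowed")
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    if (length(a) < 2) stop("need n >= 2")
    if (stats::sd(a - b) == 0)
      stop("zero variance of paired differences; t statistic undefined")
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each group")
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
      stop("zero pooled variance; t statistic undefined")
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, paired = paired,
                 estimate = mean(a) - mean(b)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t(%g) = %.3f, p = %.4g\n",
              if (x$paired) "Paired" else "Pooled-variance unpaired",
              x$df, x$statistic, x$p))
  invisible(x)
}

# Within-subject sums-of-squares decomposition for a complete n x k matrix.
# Returns SS for condition, subject, error and the F/p for the condition
# effect tested against the condition x subject interaction.
.rm_oneway_ss <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  cond_means <- colMeans(mat)
  subj_means <- rowMeans(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1L
  df_err <- (k - 1L) * (n - 1L)
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       df_cond = df_cond, df_err = df_err)
}

.f_p <- function(ss_eff, df_eff, ss_err, df_err, tol = 1e-12) {
  # Degenerate data (all conditions identical per subject) have both SS at
  # zero: report a null effect rather than 0/0.
  if (ss_eff <= tol && ss_err <= tol) return(list(F = 0, p = 1))
  if (ss_err <= tol) stop("singular error term: zero within-subject residual variance")
  f <- (ss_eff / df_eff) / (ss_err / df_err)
  list(F = f, p = stats::pf(f, df_eff, df_err, lower.tail = FALSE))
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Takes a complete subject-by-condition matrix (one row per subject, one
#' column per condition cell). With no factor labels the columns form the
#' levels of a single within-subject factor; with `f1`/`f2` the columns are
#' the cells of a fully crossed two-factor within design. Each effect is
#' tested against its own subject-interaction error term with uncorrected
#' (sphericity-assumed) degrees of freedom: one-way `(k-1, (k-1)(n-1))`;
#' two-way main effects and interaction against their respective
#' `effect x subject` strata.
#'
#' Pairwise comparisons (one-way designs, or on request via `pairwise`)
#' compare each condition against a designated baseline column by paired t
#' test with Bonferroni correction: corrected p = `min(1, raw p * m)` where
#' `m` is the number of comparisons actually performed.
#'
#' @param mat numeric matrix, `n` subjects x `k` condition cells, complete
#'   (no missing values).
#' @param f1,f2 optional factors of length `ncol(mat)` assigning each column
#'   to a level of the first / second within-subject factor. Supply both or
#'   neither.
#' @param baseline column index of the baseline level for pairwise
#'   comparisons (one-way only; default 1).
#' @param pairwise logical; compute Bonferroni pairwise comparisons versus
#'   the baseline column (default `TRUE` for one-way, `FALSE` for two-way).
#' @return An `rm_anova_result` with one row per effect (`effect`, `F`,
#'   `df1`, `df2`, `p`) in `$table` and, when computed, a `$pairwise` data
#'   frame (`comparison`, `t`, `df`, `p_raw`, `p_bonferroni`).
#' @export
#' @examples
#' m <- matrix(rnorm(16 * 6), 16, 6)
#' rm_anova(m)
rm_anova <- function(mat, f1 = NULL, f2 = NULL, baseline = 1L,
                     pairwise = is.null(f1)) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("mat must be numeric")
  if (anyNA(mat)) stop("incomplete matrix: repeated-measures design requires all cells")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2) stop("need at least 2 subjects")
  if (k < 2) stop("need at least 2 condition cells")
  if (is.null(f1) != is.null(f2))
    stop("supply both f1 and f2 for a two-factor design, or neither")

  if (is.null(f1)) {
    ss <- .rm_oneway_ss(mat)
    fp <- .f_p(ss$ss_cond, ss$df_cond, ss$ss_err, ss$df_err)
    table <- data.frame(effect = "condition", F = fp$F, df1 = ss$df_cond,
                        df2 = ss$df_err, p = fp$p,
                        stringsAsFactors = FALSE)
  } else {
    f1 <- as.factor(f1); f2 <- as.factor(f2)
    if (length(f1) != k || length(f2) != k)
      stop("f1 and f2 must label every column of mat")
    a <- nlevels(f1); b <- nlevels(f2)
    if (a < 2 || b < 2) stop("need >= 2 levels per factor")
    if (k != a * b || anyDuplicated(paste(f1, f2)))
      stop("columns must form a complete a x b crossing")
    grand <- mean(mat)
    # cell means per subject rearranged to subject x A and subject x B margins
    m_a <- t(apply(mat, 1L, function(r) tapply(r, f1, mean)))  # n x a
    m_b <- t(apply(mat, 1L, function(r) tapply(r, f2, mean)))  # n x b
    subj <- rowMeans(mat)
    mean_a <- colMeans(m_a); mean_b <- colMeans(m_b)
    ss_a <- n * b * sum((mean_a - grand)^2)
    ss_b <- n * a * sum((mean_b - grand)^2)
    ss_subj <- a * b * sum((subj - grand)^2)
    ss_as <- b * sum((m_a - outer(subj, rep(1, a)) -
                        outer(rep(1, n), mean_a) + grand)^2)
    ss_bs <- a * sum((m_b - outer(subj, rep(1, b)) -
                        outer(rep(1, n), mean_b) + grand)^2)
    # interaction: cell means over subjects
    cell_mean <- colMeans(mat)
    pred_ab <- mean_a[as.integer(f1)] + mean_b[as.integer(f2)] - grand
    ss_ab <- n * sum((cell_mean - pred_ab)^2)
    ss_tot <- sum((mat - grand)^2)
    ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_subj - ss_as - ss_bs
    df_a <- a - 1L; df_b <- b - 1L; df_ab <- df_a * df_b
    df_as <- df_a * (n - 1L); df_bs <- df_b * (n - 1L)
    df_abs <- df_ab * (n - 1L)
    fa <- .f_p(ss_a, df_a, ss_as, df_as)
    fb <- .f_p(ss_b, df_b, ss_bs, df_bs)
    fab <- .f_p(ss_ab, df_ab, ss_abs, df_abs)
    table <- data.frame(
      effect = c("factor1", "factor2", "factor1:factor2"),
      F = c(fa$F, fb$F, fab$F),
      df1 = c(df_a, df_b, df_ab),
      df2 = c(df_as, df_bs, df_abs),
      p = c(fa$p, fb$p, fab$p),
      stringsAsFactors = FALSE)
  }

  pw <- NULL
  if (isTRUE(pairwise)) {
    baseline <- as.integer(baseline)
    stopifnot(baseline >= 1L, baseline <= k)
    others <- setdiff(seq_len(k), baseline)
    m <- length(others)
    labs <- colnames(mat)
    if (is.null(labs)) labs <- paste0("cond", seq_len(k))
    rows <- lapply(others, function(j) {
      d <- mat[, j] - mat[, baseline]
      if (stats::sd(d) == 0) {
        data.frame(comparison = paste(labs[j], "vs", labs[baseline]),
                   t = if (mean(d) == 0) 0 else NA_real_, df = n - 1L,
                   p_raw = if (mean(d) == 0) 1 else NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(mat[, j], mat[, baseline], paired = TRUE)
        data.frame(comparison = paste(labs[j], "vs", labs[baseline]),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value, stringsAsFactors = FALSE)
      }
    })
    pw <- do.call(rbind, rows)
    pw$p_bonferroni <- pmin(1, pw$p_raw * m)
  }

  structure(list(table = table, pairwise = pw, n_subjects = n, n_cells = k),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects, %d condition cells)\n",
              x$n_subjects, x$n_cells))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-16s F(%d,%d) = %.3f, p = %.4g\n",
                r$effect, r$df1, r$df2, r$F, r$p))
  }
  if (!is.null(x$pairwise)) {
    cat("  Bonferroni pairwise vs baseline:\n")
    for (i in seq_len(nrow(x$pairwise))) {
      r <- x$pairwise[i, ]
      cat(sprintf("    %-22s t(%g) = %.3f, p = %.4g (corrected %.4g)\n",
                  r$comparison, r$df, r$t, r$p_raw, r$p_bonferroni))
    }
  }
  invisible(x)
}

#' Chi-squared test on a 2x2 escape-count table
#'
#' Pearson chi-squared statistic without continuity correction on a 2x2
#' table of counts (e.g. escaped / did-not-escape by treatment arm), with
#' expected counts from the margin products and 1 degree of freedom. For
#' the escape counts 8-of-10 versus 1-of-8 this gives chi2 = 8.10 exactly.
#'
#' @param observed 2x2 matrix of nonnegative integer counts; all margins
#'   must be positive.
#' @return A `contingency_result`: `chi2`, `df`, `p`, `observed`,
#'   `expected`.
#' @export
#' @examples
#' chi_squared_gof(matrix(c(8, 1, 2, 7), 2))
chi_squared_gof <- function(observed) {
  observed <- as.matrix(observed)
  if (!all(dim(observed) == c(2L, 2L))) stop("observed must be a 2x2 table")
  if (anyNA(observed) || any(observed < 0) ||
      any(abs(observed - round(observed)) > 1e-8))
    stop("observed must contain nonnegative integer counts")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero margin: every row and column must have a positive total")
  # small-expected-count warnings are irrelevant here: the Pearson
  # statistic itself is the quantity of interest
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, observed = observed,
                 expected = ct$expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared (no continuity correction): chi2(%d) = %.3f, p = %.4g\n",
              x$df, x$chi2, x$p))
  invisible(x)
}
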