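#' Uncorrected Pearson chi-squared test of independence on a 2x2 table
#'
#' The Pearson statistic sum (O-E)^2/E over the four cells, *without* the
#' Yates continuity correction, referred to a chi-squared distribution with
#' one degree of freedom. No minimum-expected-count rule is enforced: tables
#' with an expected cell below 5 are tested anyway (with a warning), since
#' retrospective audits of small positive groups routinely produce them.
#' Fisher's exact test is available as an explicitly different option.
#'
#' @param a,b,c,d Cell counts: group 1 with/without the feature, group 2
#'   with/without the feature. Alternatively `a` may be a 2x2 matrix.
#' @param method `"pearson"` (default) or `"fisher"` (exact test; the
#'   statistic slot then holds the odds ratio).
#' @return An object of class `chisq_2x2`: list with `statistic`,
#'   `p_value`, `expected`, `table` and `method`.
#' @examples
#' chi_squared_2x2(38, 68, 12, 2)$statistic   # 12.6515
#' @export
chi_squared_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                            method = c("pearson", "fisher")) {
  method <- match.arg(method)
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a row or column marginal is zero")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected cell count below 5; the chi-squared approximation is rough")
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    out <- list(statistic = unname(ft$estimate), p_value = ft$p.value,
                expected = expected, table = tab, method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                expected = expected, table = tab, method = "pearson")
  }
  structure(out, class = "chisq_2x2")
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  if (x$method == "fisher") {
    cat(sprintf("Fisher's exact test: OR = %.4f, p = %.4g\n",
                x$statistic, x$p_value))
  } else {
    cat(sprintf("Pearson chi-squared (1 df, no continuity correction): X2 = %.4f, p = %.4g\n",
                x$statistic, x$p_value))
  }
  invisible(x)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is computed from rank sums with midranks for ties; the z statistic
#' uses the normal approximation with the tie-corrected variance and no
#' continuity correction. Sign convention: z < 0 when the first sample is
#' stochastically smaller than the second. The p-value is two-tailed.
#'
#' @param x,y Non-empty numeric samples.
#' @return An object of class `mann_whitney`: list with `U` (for `x`), `z`,
#'   `p_value`, sample sizes and a `ties` flag. When every pooled value is
#'   identical the variance is zero: `z` and `p_value` are `NA` and
#'   `degenerate` is `TRUE`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U   # 0
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0, is.numeric(x), is.numeric(y),
            !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))            # midranks for ties
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2   # U for the first sample
  mu <- n1 * n2 / 2
  tie_sizes <- table(c(x, y))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  degenerate <- sigma2 <= 0
  z <- if (degenerate) NA_real_ else (U - mu) / sqrt(sigma2)
  p <- if (is.na(z)) NA_real_ else min(2 * stats::pnorm(-abs(z)), 1)
  structure(list(U = U, z = z, p_value = p, n1 = n1, n2 = n2,
                 ties = tie_term > 0, degenerate = degenerate),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (normal approximation%s): U = %g, z = %.5f, p = %.4g\n",
              if (x$ties) ", tie-corrected" else "", x$U, x$z, x$p_value))
  if (x$degenerate) cat("  (all pooled values identical; z undefined)\n")
  invisible(x)
}

#' Population-SD z confidence interval for a mean
#'
#' mean +/- z * sigma / sqrt(n), with sigma the *population*
#' (divide-by-n) standard deviation and z the standard-normal quantile —
#' the convention of the simple online calculators used in clinical audits,
#' rather than a t interval with the sample SD. Display rounding (the
#' `display` element and the print method) rounds the mean to the nearest
#' integer first and forms the bounds from the rounded mean, matching how
#' such calculators chain their rounding.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `population_ci`: list with `mean`, `lower`,
#'   `upper` (unrounded), `display` (integer-rounded mean/lower/upper),
#'   `sd_population`, `n`, `confidence`.
#' @examples
#' ci <- population_z_ci(c(0, 2))
#' ci$mean                       # 1
#' ci$upper - ci$mean            # 1.959964 * 1 / sqrt(2)
#' @export
population_z_ci <- function(values, confidence = 0.95) {
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  if (n < 2) stop("population_z_ci() needs at least two values")
  m <- mean(values)
  sigma <- sqrt(mean((values - m)^2))
  zq <- stats::qnorm((1 + confidence) / 2)
  half <- zq * sigma / sqrt(n)
  rm <- round(m)
  structure(list(mean = m, lower = m - half, upper = m + half,
                 display = c(mean = rm, lower = round(rm - half),
                             upper = round(rm + half)),
                 sd_population = sigma, n = n, confidence = confidence),
            class = "population_ci")
}

#' @export
print.population_ci <- function(x, ...) {
  cat(sprintf("mean %s (%d%% CI: %s-%s), population SD, n = %d\n",
              format(x$display["mean"], big.mark = ","),
              round(100 * x$confidence),
              format(x$display["lower"], big.mark = ","),
              format(x$display["upper"], big.mark = ","), x$n))
  invisible(x)
}

#' Percent by which one group mean exceeds another
#'
#' @param mean_high,mean_low Group means.
#' @param digits Decimal places for display rounding (half up).
#' @return `(mean_high - mean_low) / mean_low * 100`, rounded.
#' @examples
#' group_mean_percent_diff(14706, 9260)   # 58.8
#' @export
group_mean_percent_diff <- function(mean_high, mean_low, digits = 1) {
  round_half_up((mean_high - mean_low) / mean_low * 100, digits)
}

#' Format a count as "k (p%)" with one decimal place
#'
#' @param k Count with the feature.
#' @param n Group size.
#' @return Character, e.g. `count_percent(38, 106)` is `"38 (35.8%)"`.
#' @export
count_percent <- function(k, n) {
  sprintf("%d (%s%%)", k, format(round_half_up(100 * k / n, 1)))
}

#' Rebuild the group-comparison table from a cohort
#'
#' Scores every patient with the HScore, splits the cohort at the cutoff,
#' and produces the audit's comparison rows: mean peak ferritin (censored
#' results at the assay ceiling) compared with the Mann-Whitney U test, and
#' eleven binary features (cytopaenias, fever, organomegalies,
#' triglycerides > 1.5 mmol/L, fibrinogen < 2.5 g/L, haemophagocytosis,
#' immunosuppression, transaminase derangement AST > 30 / ALT > 100 U/L)
#' compared with the uncorrected chi-squared test. A missing feature counts
#' as absent, so group denominators are the full group sizes, as in a
#' retrospective notes review.
#'
#' @param cohort An [hlh_cohort()].
#' @param cutoff,cutoff_rule HScore grouping cutoff (default total >= 169).
#' @return A data frame of class `hlh_table3`: one row per comparison with
#'   `label`, `summary_neg`, `summary_pos` (formatted "k (p%)" or group
#'   mean), `statistic`, `p_value`, `test`, plus numeric `value_neg`,
#'   `value_pos`.
#' @export
build_table3 <- function(cohort, cutoff = 169, cutoff_rule = "ge") {
  stopifnot(inherits(cohort, "hlh_cohort"))
  hs <- hscore(cohort, hscore_policy(cutoff = cutoff, cutoff_rule = cutoff_rule))
  pos <- hs$positive
  n_neg <- sum(!pos); n_pos <- sum(pos)
  if (n_neg == 0 || n_pos == 0) {
    stop("both HScore groups must be non-empty to build the comparison table")
  }
  ferr <- numeric_ferritin(cohort$ferritin_ugL, cohort$ferritin_censored)
  mw <- mann_whitney_u(ferr[!pos], ferr[pos])

  features <- list(
    haemoglobin_low = list("Patients with haemoglobin < 90 g/L",
                           (cohort$haemoglobin_gL < 90) %in% TRUE),
    platelets_low = list("Patients with platelets < 100e9/L",
                         (cohort$platelets_1e9L < 100) %in% TRUE),
    neutrophils_low = list("Patients with neutrophils < 1e9/L",
                           (cohort$neutrophils_1e9L < 1) %in% TRUE),
    fever = list("Patients with a fever", .has_fever(cohort) %in% TRUE),
    hepatomegaly = list("Patients with hepatomegaly",
                        cohort$hepatomegaly %in% TRUE),
    splenomegaly = list("Patients with splenomegaly",
                        cohort$splenomegaly %in% TRUE),
    triglycerides_high = list("Patients with triglycerides > 1.5 mmol/L",
                              (cohort$triglycerides_mmolL > 1.5) %in% TRUE),
    fibrinogen_low = list("Patients with fibrinogen < 2.5 g/L",
                          (cohort$fibrinogen_gL < 2.5) %in% TRUE),
    haemophagocytosis = list("Patients with haemophagocytosis recorded",
                             cohort$haemophagocytosis %in% TRUE),
    immunosuppression = list("Patients with immunosuppression",
                             cohort$immunosuppressed %in% TRUE),
    transaminase_deranged = list(
      "Patients with transaminase derangement (AST > 30 / ALT > 100)",
      ((cohort$ast_UL > 30) %in% TRUE) | ((cohort$alt_UL > 100) %in% TRUE))
  )

  rows <- list(data.frame(
    feature = "mean_ferritin",
    label = "Mean peak serum ferritin level (ug/L)",
    summary_neg = format(round(mean(ferr[!pos])), big.mark = ","),
    summary_pos = format(round(mean(ferr[pos])), big.mark = ","),
    value_neg = mean(ferr[!pos]), value_pos = mean(ferr[pos]),
    statistic = mw$z, p_value = mw$p_value, test = "mann-whitney",
    stringsAsFactors = FALSE))
  for (nm in names(features)) {
    flag <- features[[nm]][[2]]
    k_neg <- sum(flag & !pos); k_pos <- sum(flag & pos)
    ct <- suppressWarnings(
      chi_squared_2x2(k_neg, n_neg - k_neg, k_pos, n_pos - k_pos))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, label = features[[nm]][[1]],
      summary_neg = count_percent(k_neg, n_neg),
      summary_pos = count_percent(k_pos, n_pos),
      value_neg = k_neg, value_pos = k_pos,
      statistic = ct$statistic, p_value = ct$p_value, test = "chi-squared",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- c(neg = n_neg, pos = n_pos)
  class(out) <- c("hlh_table3", "data.frame")
  out
}

#' @export
print.hlh_table3 <- function(x, ...) {
  gs <- attr(x, "group_sizes")
  cat(sprintf("Comparison of patient characteristics: HScore-negative n = %d, HScore-positive n = %d\n",
              gs["neg"], gs["pos"]))
  df <- data.frame(x$label, x$summary_neg, x$summary_pos,
                   sprintf("%.4g (%s)", x$p_value, signif(x$statistic, 6)),
                   check.names = FALSE)
  names(df) <- c("", "HScore-", "HScore+", "p (statistic)")
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
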