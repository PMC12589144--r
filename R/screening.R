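#' Define a ferritin / fever / platelet screening rule
#'
#' A conjunction of up to three predicates over a patient record: peak
#' ferritin strictly above a cutoff (censored results compare as the assay
#' ceiling), documented fever, and platelets strictly below a cutoff. At
#' least one predicate must be active.
#'
#' @param ferritin_cutoff_ugL Positive ferritin cutoff in ug/L, or `NULL`
#'   to deactivate the ferritin predicate.
#' @param require_fever Logical; require a documented fever.
#' @param platelet_cutoff_1e9L Platelet cutoff in 10^9/L (rule requires
#'   platelets strictly below it), or `NULL` to deactivate.
#' @return An object of class `screening_rule`.
#' @examples
#' screening_rule(5000, require_fever = TRUE)
#' @export
screening_rule <- function(ferritin_cutoff_ugL = 5000,
                           require_fever = FALSE,
                           platelet_cutoff_1e9L = NULL) {
  if (!is.null(ferritin_cutoff_ugL))
    stopifnot(is.numeric(ferritin_cutoff_ugL), ferritin_cutoff_ugL > 0)
  if (!is.null(platelet_cutoff_1e9L))
    stopifnot(is.numeric(platelet_cutoff_1e9L), platelet_cutoff_1e9L > 0)
  if (is.null(ferritin_cutoff_ugL) && !isTRUE(require_fever) &&
      is.null(platelet_cutoff_1e9L)) {
    stop("a screening rule needs at least one active predicate")
  }
  structure(list(ferritin_cutoff_ugL = ferritin_cutoff_ugL,
                 require_fever = isTRUE(require_fever),
                 platelet_cutoff_1e9L = platelet_cutoff_1e9L),
            class = "screening_rule")
}

#' @export
print.screening_rule <- function(x, ...) {
  cat("Screening rule:", .rule_label(x), "\n")
  invisible(x)
}

.rule_label <- function(rule) {
  parts <- character()
  if (!is.null(rule$ferritin_cutoff_ugL))
    parts <- c(parts, sprintf("ferritin > %s ug/L",
                              format(rule$ferritin_cutoff_ugL, big.mark = ",")))
  if (rule$require_fever) parts <- c(parts, "fever")
  if (!is.null(rule$platelet_cutoff_1e9L))
    parts <- c(parts, sprintf("platelets < %g x10^9/L", rule$platelet_cutoff_1e9L))
  paste(parts, collapse = " AND ")
}

#' Apply a screening rule to a cohort
#'
#' @param rule A [screening_rule()].
#' @param cohort An [hlh_cohort()].
#' @param missing `"fail"` (default): a patient missing an input required by
#'   an active predicate does not satisfy the rule; `"unevaluable"`: such
#'   patients come back `NA`.
#' @return Logical vector, one entry per patient (`NA` marks unevaluable
#'   patients under `missing = "unevaluable"`).
#' @export
apply_rule <- function(rule, cohort, missing = c("fail", "unevaluable")) {
  stopifnot(inherits(rule, "screening_rule"), inherits(cohort, "hlh_cohort"))
  missing <- match.arg(missing)
  n <- nrow(cohort)
  hit <- rep(TRUE, n)
  unevaluable <- rep(FALSE, n)
  if (!is.null(rule$ferritin_cutoff_ugL)) {
    ferr <- numeric_ferritin(cohort$ferritin_ugL, cohort$ferritin_censored)
    hit <- hit & ferr > rule$ferritin_cutoff_ugL  # strict; ferritin never missing
  }
  if (rule$require_fever) {
    fev <- .has_fever(cohort)
    unevaluable <- unevaluable | is.na(fev)
    hit <- hit & (fev %in% TRUE)
  }
  if (!is.null(rule$platelet_cutoff_1e9L)) {
    plt <- cohort$platelets_1e9L
    unevaluable <- unevaluable | is.na(plt)
    hit <- hit & ((plt < rule$platelet_cutoff_1e9L) %in% TRUE)
  }
  if (missing == "unevaluable") hit[unevaluable] <- NA
  hit
}

#' Reference-standard labels for screening evaluation
#'
#' @param cohort An [hlh_cohort()].
#' @param reference `"hlh04"` (default), `"hscore"`, `"clinician"`, or a
#'   logical vector of labels (e.g. latent truth from [generate_cohort()]).
#' @return Logical vector of reference positivity.
#' @export
reference_standard <- function(cohort, reference = c("hlh04", "hscore", "clinician")) {
  if (is.logical(reference)) {
    stopifnot(length(reference) == nrow(cohort))
    return(reference)
  }
  reference <- match.arg(reference)
  switch(reference,
         hlh04 = hlh04(cohort)$positive,
         hscore = hscore(cohort)$positive,
         clinician = cohort$clinician_hlh_diagnosis %in% TRUE)
}

#' Evaluate a screening rule against a reference standard
#'
#' Crosses the per-patient rule outcome with reference positivity into a
#' 2x2 confusion matrix with sensitivity, specificity and Youden index.
#'
#' @param rule A [screening_rule()].
#' @param cohort An [hlh_cohort()].
#' @param reference See [reference_standard()]. The default reference is
#'   HLH-2004 positivity.
#' @param missing `"fail"` (default): patients missing a required input
#'   count as rule-negative; `"exclude"`: they are dropped from the table.
#' @return An object of class `confusion_matrix`: list with integer cells
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `youden`,
#'   `n_excluded`, and the rule/reference used. Sensitivity (specificity)
#'   is `NA` and flagged `undefined` when the reference has no positives
#'   (negatives).
#' @export
evaluate_rule <- function(rule, cohort, reference = "hlh04",
                          missing = c("fail", "exclude")) {
  missing <- match.arg(missing)
  ref <- reference_standard(cohort, reference)
  pred <- apply_rule(rule, cohort,
                     missing = if (missing == "fail") "fail" else "unevaluable")
  keep <- !is.na(pred)
  n_excluded <- sum(!keep)
  pred <- pred[keep]
  ref <- ref[keep]
  tp <- sum(pred & ref); fp <- sum(pred & !ref)
  tn <- sum(!pred & !ref); fn <- sum(!pred & ref)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 youden = sens + spec - 1,
                 undefined = c(sensitivity = tp + fn == 0,
                               specificity = tn + fp == 0),
                 n_excluded = n_excluded,
                 rule = rule,
                 reference = if (is.character(reference)) reference else "custom"),
            class = "confusion_matrix")
}

#' Round half away from zero (display convention for percentages)
#'
#' Unlike [round()]'s round-half-to-even, screening percentages are shown
#' rounded half up, so e.g. 94.15 displays as 94.2.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Screening rule:", .rule_label(x$rule), "\n")
  cat("Reference standard:", x$reference, "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("rule+", "rule-"), c("ref+", "ref-")))
  print(m)
  cat(sprintf("sensitivity %s%%, specificity %s%%",
              ifelse(is.na(x$sensitivity), "NA",
                     round_half_up(100 * x$sensitivity, 1)),
              ifelse(is.na(x$specificity), "NA",
                     round_half_up(100 * x$specificity, 1))))
  if (x$n_excluded > 0) cat(" (", x$n_excluded, " patient(s) excluded)", sep = "")
  cat("\n")
  invisible(x)
}

#' Evaluate a grid of screening rules
#'
#' One confusion matrix per combination of ferritin cutoff, fever
#' requirement and platelet cutoff, sorted by Youden index (descending;
#' ties by lower ferritin cutoff).
#'
#' @param cohort A non-empty [hlh_cohort()].
#' @param ferritin_cutoffs Numeric vector of ferritin cutoffs (ug/L).
#' @param with_fever Logical vector of fever requirements to cross.
#' @param platelet_cutoffs Platelet cutoffs to cross; `NA` entries mean "no
#'   platelet predicate".
#' @param reference,missing Passed to [evaluate_rule()].
#' @return A data frame with one row per rule: the rule parameters, cells
#'   `tp`/`fp`/`tn`/`fn`, `sensitivity`, `specificity` (proportions) and
#'   `youden`.
#' @export
rule_grid <- function(cohort, ferritin_cutoffs = c(5000, 7000),
                      with_fever = c(FALSE, TRUE), platelet_cutoffs = NA,
                      reference = "hlh04", missing = "fail") {
  stopifnot(inherits(cohort, "hlh_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (!length(ferritin_cutoffs) || !length(with_fever) || !length(platelet_cutoffs)) {
    stop("empty rule grid")
  }
  grid <- expand.grid(ferritin_cutoff = ferritin_cutoffs,
                      require_fever = with_fever,
                      platelet_cutoff = platelet_cutoffs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rule <- screening_rule(grid$ferritin_cutoff[i], grid$require_fever[i],
                           if (is.na(grid$platelet_cutoff[i])) NULL
                           else grid$platelet_cutoff[i])
    cm <- evaluate_rule(rule, cohort, reference = reference, missing = missing)
    data.frame(ferritin_cutoff = grid$ferritin_cutoff[i],
               require_fever = grid$require_fever[i],
               platelet_cutoff = grid$platelet_cutoff[i],
               tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               youden = cm$youden)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$youden, out$ferritin_cutoff), , drop = FALSE]
  rownames(out) <- NULL
  out
}
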