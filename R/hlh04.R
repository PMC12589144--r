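# Fever as a binary: a documented-fever flag wins; with no flag but a
# recorded temperature, anything above the afebrile band (38.4 C) counts.
# NA when neither is documented.
.has_fever <- function(cohort) {
  ifelse(!is.na(cohort$fever_documented), cohort$fever_documented,
         ifelse(!is.na(cohort$temperature_celsius),
                cohort$temperature_celsius >= 38.4, NA))
}

#' HLH-2004 scoring policy
#'
#' @param missing `"unmet"` (default): a criterion whose inputs are missing
#'   counts as not met — in a retrospective cohort where NK-cell activity
#'   and soluble CD25 were never assayed this caps the attainable count at
#'   6/8; `"error"`: stop when any criterion is unevaluable.
#' @param threshold Criteria required for positivity (default 5 of 8).
#' @return A list of class `hlh04_policy`.
#' @export
hlh04_policy <- function(missing = c("unmet", "error"), threshold = 5) {
  structure(list(missing = match.arg(missing), threshold = threshold),
            class = "hlh04_policy")
}

#' Evaluate the revised HLH-2004 criteria for every patient
#'
#' Eight criteria: fever; splenomegaly; ferritin >= 500 ug/L; cytopaenia in
#' at least two lineages (haemoglobin <= 90 g/L, platelets <= 100 x 10^9/L,
#' neutrophils <= 1 x 10^9/L); hypertriglyceridaemia (>= 3 mmol/L) *or*
#' hypofibrinogenaemia (<= 1.5 g/L), together worth one point at most;
#' haemophagocytosis in bone marrow, spleen or lymph nodes; low or absent
#' NK-cell activity; and soluble CD25 >= 2,400 U/mL. Hepatomegaly plays no
#' role. A patient is positive when at least `policy$threshold` (default 5)
#' criteria are met. Boundary values meet their criteria as printed
#' (ferritin exactly 500, triglycerides exactly 3, fibrinogen exactly 1.5,
#' sCD25 exactly 2,400 all qualify).
#'
#' @param cohort An [hlh_cohort()] (or data frame coercible to one).
#' @param policy An [hlh04_policy()].
#' @return An object of class `hlh04`: a data frame with one row per
#'   patient, logical columns `met_*` for the eight criteria, the criterion
#'   `count` (0-8) and `positive`.
#' @examples
#' p <- patient_record("x", ferritin_ugL = 9107, fever_documented = TRUE,
#'                     splenomegaly = TRUE, haemoglobin_gL = 80,
#'                     platelets_1e9L = 60, triglycerides_mmolL = 3.5)
#' hlh04(p)$count   # 5
#' @export
hlh04 <- function(cohort, policy = hlh04_policy()) {
  stopifnot(inherits(policy, "hlh04_policy"))
  if (!inherits(cohort, "hlh_cohort")) cohort <- hlh_cohort(cohort)

  if (policy$missing == "error") {
    if (any(is.na(cohort$temperature_celsius) & is.na(cohort$fever_documented))) {
      stop("missing inputs under policy missing='error': temperature/fever_documented")
    }
    needed <- c("splenomegaly", "haemoglobin_gL",
                "platelets_1e9L", "neutrophils_1e9L", "triglycerides_mmolL",
                "fibrinogen_gL", "haemophagocytosis", "nk_activity_low",
                "scd25_UmL")
    holes <- needed[vapply(needed, function(col) anyNA(cohort[[col]]), logical(1))]
    if (length(holes)) {
      stop("missing inputs under policy missing='error': ",
           paste(holes, collapse = ", "))
    }
  }

  ferr <- numeric_ferritin(cohort$ferritin_ugL, cohort$ferritin_censored)
  lineages <- ((cohort$haemoglobin_gL <= 90) %in% TRUE) +
    ((cohort$platelets_1e9L <= 100) %in% TRUE) +
    ((cohort$neutrophils_1e9L <= 1) %in% TRUE)

  out <- data.frame(
    patient_id = cohort$patient_id,
    met_fever = .has_fever(cohort) %in% TRUE,
    met_splenomegaly = cohort$splenomegaly %in% TRUE,
    met_ferritin = ferr >= 500,
    met_cytopaenia = lineages >= 2,
    met_tg_or_fibrinogen = ((cohort$triglycerides_mmolL >= 3) %in% TRUE) |
      ((cohort$fibrinogen_gL <= 1.5) %in% TRUE),
    met_haemophagocytosis = cohort$haemophagocytosis %in% TRUE,
    met_nk_low = cohort$nk_activity_low %in% TRUE,
    met_scd25 = (cohort$scd25_UmL >= 2400) %in% TRUE,
    stringsAsFactors = FALSE
  )
  out$count <- as.integer(rowSums(out[, grep("^met_", names(out))]))
  out$positive <- out$count >= policy$threshold
  attr(out, "policy") <- policy
  class(out) <- c("hlh04", "data.frame")
  out
}

#' @export
print.hlh04 <- function(x, ...) {
  cat("Revised HLH-2004 criteria for", nrow(x), "patient(s); positive at >=",
      attr(x, "policy")$threshold, "of 8\n")
  cat(sum(x$positive), "positive\n")
  print.data.frame(x[, c("patient_id", "count", "positive")], row.names = FALSE)
  invisible(x)
}

#' Cross-tabulate HScore and HLH-2004 positivity on one cohort
#'
#' Runs both scoring engines on every patient and reports the 2x2 agreement
#' table together with the discordant patients (positive under one system
#' only) — the case-finding question of which patients one system flags
#' that the other misses.
#'
#' @param cohort An [hlh_cohort()].
#' @param hscore_policy,hlh04_policy Engine policies.
#' @return An object of class `scoring_comparison`: list with `table`
#'   (2x2 integer matrix, HScore rows x HLH-2004 columns), `hscore_only`
#'   and `hlh04_only` (patient ids), and the per-patient `labels`.
#' @export
compare_scoring_systems <- function(cohort,
                                    hscore_policy = hlhscreen::hscore_policy(),
                                    hlh04_policy = hlhscreen::hlh04_policy()) {
  stopifnot(inherits(cohort, "hlh_cohort"))
  hs <- if (nrow(cohort)) hscore(cohort, hscore_policy)$positive else logical()
  h4 <- if (nrow(cohort)) hlh04(cohort, hlh04_policy)$positive else logical()
  tab <- table(factor(hs, levels = c(TRUE, FALSE), labels = c("HScore+", "HScore-")),
               factor(h4, levels = c(TRUE, FALSE), labels = c("HLH-04+", "HLH-04-")))
  structure(list(table = unclass(tab),
                 hscore_only = cohort$patient_id[hs & !h4],
                 hlh04_only = cohort$patient_id[h4 & !hs],
                 labels = data.frame(patient_id = cohort$patient_id,
                                     hscore_positive = hs,
                                     hlh04_positive = h4,
                                     stringsAsFactors = FALSE)),
            class = "scoring_comparison")
}

#' @export
print.scoring_comparison <- function(x, ...) {
  cat("Agreement between HScore and revised HLH-2004 positivity:\n")
  print(x$table)
  if (length(x$hscore_only))
    cat("HScore-positive only:", paste(x$hscore_only, collapse = ", "), "\n")
  if (length(x$hlh04_only))
    cat("HLH-2004-positive only:", paste(x$hlh04_only, collapse = ", "), "\n")
  invisible(x)
}
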