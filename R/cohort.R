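# Canonical column set of a patient cohort. Ferritin is stored as a
# value/censored pair (survival-style) because the assay reports results above
# its quantification limit only as ">ceiling".
.cohort_columns <- c(
  "patient_id", "age_years",
  "fever_documented", "temperature_celsius",
  "hepatomegaly", "splenomegaly", "immunosuppressed",
  "ferritin_ugL", "ferritin_censored",
  "haemoglobin_gL", "platelets_1e9L", "neutrophils_1e9L",
  "triglycerides_mmolL", "fibrinogen_gL", "ast_UL", "alt_UL",
  "haemophagocytosis", "nk_activity_low", "scd25_UmL",
  "clinician_hlh_diagnosis", "conditions"
)

.logical_columns <- c(
  "fever_documented", "hepatomegaly", "splenomegaly", "immunosuppressed",
  "ferritin_censored", "haemophagocytosis", "nk_activity_low",
  "clinician_hlh_diagnosis"
)

.numeric_columns <- c(
  "age_years", "temperature_celsius", "ferritin_ugL", "haemoglobin_gL",
  "platelets_1e9L", "neutrophils_1e9L", "triglycerides_mmolL",
  "fibrinogen_gL", "ast_UL", "alt_UL", "scd25_UmL"
)

#' Ferritin assay upper limit of quantification (ug/L)
#'
#' Results at or above this value are reported by the assay only as
#' ">16,500" and are stored as censored values at the ceiling.
#' @export
FERRITIN_CEILING <- 16500

#' A laboratory value subject to assay-ceiling censoring
#'
#' Represents a result such as serum ferritin that the assay can only report
#' up to an upper limit of quantification. A censored value means "at or above
#' the ceiling" and is stored *at* the ceiling.
#'
#' @param value Non-negative finite measurement.
#' @param censored Logical; `TRUE` means the true value is at or above the
#'   assay ceiling.
#' @param ceiling Assay upper limit of quantification; a censored `value`
#'   must equal it.
#' @return An object of class `censored_value` with fields `value`,
#'   `censored` and `ceiling`.
#' @examples
#' censored_value(9107)
#' censored_value(16500, censored = TRUE)
#' @export
censored_value <- function(value, censored = FALSE, ceiling = FERRITIN_CEILING) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            value >= 0, is.logical(censored), length(censored) == 1L)
  if (isTRUE(censored) && value != ceiling) {
    stop("a censored value must be stored at the assay ceiling (", ceiling, ")")
  }
  structure(list(value = value, censored = isTRUE(censored), ceiling = ceiling),
            class = "censored_value")
}

#' @export
print.censored_value <- function(x, ...) {
  cat(if (x$censored) paste0(">", format(x$value, big.mark = ",")) else
    format(x$value, big.mark = ","), "\n")
  invisible(x)
}

#' Convert a possibly censored ferritin to a plain number
#'
#' Under the default `"ceiling"` policy a censored result contributes the
#' assay ceiling (16,500 ug/L) to means and comparisons; the `"exclude"`
#' policy returns `NA` for censored results so they can be dropped.
#'
#' @param value Numeric vector of stored values, or a [censored_value()].
#' @param censored Logical vector of censoring flags (ignored when `value`
#'   is a `censored_value`).
#' @param policy `"ceiling"` (default) or `"exclude"`.
#' @return Numeric vector; `NA` marks excluded (censored) entries under the
#'   `"exclude"` policy.
#' @examples
#' numeric_ferritin(censored_value(16500, TRUE))            # 16500
#' numeric_ferritin(5150, FALSE)                            # 5150
#' numeric_ferritin(16500, TRUE, policy = "exclude")        # NA
#' @export
numeric_ferritin <- function(value, censored = FALSE,
                             policy = c("ceiling", "exclude")) {
  policy <- match.arg(policy)
  if (inherits(value, "censored_value")) {
    censored <- value$censored
    value <- value$value
  }
  stopifnot(is.numeric(value), length(censored) %in% c(1L, length(value)))
  censored <- rep_len(as.logical(censored), length(value))
  if (policy == "exclude") value[censored %in% TRUE] <- NA_real_
  value
}

#' Construct a single patient record
#'
#' All clinical flags and laboratory values other than `patient_id` and
#' ferritin may be missing (`NA`): in this retrospective setting a missing
#' flag means "not documented / test never requested", which the scoring
#' engines treat differently from a documented negative.
#'
#' @param patient_id Unique identifier (coerced to character).
#' @param ferritin_ugL Peak serum ferritin in ug/L; may be a
#'   [censored_value()].
#' @param ferritin_censored Logical; ferritin at or above the assay ceiling.
#' @param age_years,temperature_celsius,haemoglobin_gL,platelets_1e9L,neutrophils_1e9L,triglycerides_mmolL,fibrinogen_gL,ast_UL,alt_UL,scd25_UmL
#'   Numeric values (units in the argument names); `NA` when unavailable.
#' @param fever_documented,hepatomegaly,splenomegaly,immunosuppressed,haemophagocytosis,nk_activity_low
#'   Logical clinical flags; `NA` when not documented. Immunosuppression
#'   means HIV positivity or long-term immunosuppressive therapy.
#' @param clinician_hlh_diagnosis Logical; whether the treating clinicians
#'   diagnosed HLH.
#' @param conditions Free-text documented conditions (semicolon separated).
#' @return A one-row [hlh_cohort()].
#' @export
patient_record <- function(patient_id,
                           ferritin_ugL,
                           ferritin_censored = FALSE,
                           age_years = NA_real_,
                           fever_documented = NA,
                           temperature_celsius = NA_real_,
                           hepatomegaly = NA,
                           splenomegaly = NA,
                           immunosuppressed = NA,
                           haemoglobin_gL = NA_real_,
                           platelets_1e9L = NA_real_,
                           neutrophils_1e9L = NA_real_,
                           triglycerides_mmolL = NA_real_,
                           fibrinogen_gL = NA_real_,
                           ast_UL = NA_real_,
                           alt_UL = NA_real_,
                           haemophagocytosis = NA,
                           nk_activity_low = NA,
                           scd25_UmL = NA_real_,
                           clinician_hlh_diagnosis = NA,
                           conditions = NA_character_) {
  if (inherits(ferritin_ugL, "censored_value")) {
    ferritin_censored <- ferritin_ugL$censored
    ferritin_ugL <- ferritin_ugL$value
  }
  df <- data.frame(
    patient_id = as.character(patient_id),
    age_years = as.numeric(age_years),
    fever_documented = as.logical(fever_documented),
    temperature_celsius = as.numeric(temperature_celsius),
    hepatomegaly = as.logical(hepatomegaly),
    splenomegaly = as.logical(splenomegaly),
    immunosuppressed = as.logical(immunosuppressed),
    ferritin_ugL = as.numeric(ferritin_ugL),
    ferritin_censored = as.logical(ferritin_censored),
    haemoglobin_gL = as.numeric(haemoglobin_gL),
    platelets_1e9L = as.numeric(platelets_1e9L),
    neutrophils_1e9L = as.numeric(neutrophils_1e9L),
    triglycerides_mmolL = as.numeric(triglycerides_mmolL),
    fibrinogen_gL = as.numeric(fibrinogen_gL),
    ast_UL = as.numeric(ast_UL),
    alt_UL = as.numeric(alt_UL),
    haemophagocytosis = as.logical(haemophagocytosis),
    nk_activity_low = as.logical(nk_activity_low),
    scd25_UmL = as.numeric(scd25_UmL),
    clinician_hlh_diagnosis = as.logical(clinician_hlh_diagnosis),
    conditions = as.character(conditions),
    stringsAsFactors = FALSE
  )
  hlh_cohort(df)
}

#' Construct and validate a patient cohort
#'
#' A cohort is a data frame with one row per patient and the canonical
#' column set (see [patient_record()] for fields and units). Missing
#' canonical columns are added as `NA`; extra columns are preserved.
#'
#' @param x A data frame of patient records.
#' @param provenance Free-text description of where the records came from.
#' @param ceiling Ferritin assay ceiling used to check censoring consistency.
#' @return `x` with class `hlh_cohort` and a `provenance` attribute.
#' @export
hlh_cohort <- function(x, provenance = NULL, ceiling = FERRITIN_CEILING) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in setdiff(.cohort_columns, names(x))) {
    x[[col]] <- if (col %in% .logical_columns) NA else
      if (col %in% .numeric_columns) NA_real_ else NA_character_
  }
  x <- x[, c(.cohort_columns, setdiff(names(x), .cohort_columns)), drop = FALSE]
  for (col in .logical_columns) x[[col]] <- as.logical(x[[col]])
  for (col in .numeric_columns) x[[col]] <- as.numeric(x[[col]])
  x$patient_id <- as.character(x$patient_id)
  x$ferritin_censored[is.na(x$ferritin_censored)] <- FALSE
  if (anyNA(x$patient_id) || anyDuplicated(x$patient_id)) {
    stop("patient_id must be present and unique within a cohort")
  }
  if (anyNA(x$ferritin_ugL)) stop("ferritin_ugL is required for every patient")
  bad <- x$ferritin_censored & x$ferritin_ugL != ceiling
  if (any(bad)) {
    stop("censored ferritin must be stored at the assay ceiling (", ceiling,
         "); offending patient(s): ",
         paste(x$patient_id[bad], collapse = ", "))
  }
  neg <- vapply(.numeric_columns,
                function(col) any(x[[col]] < 0, na.rm = TRUE), logical(1))
  if (any(neg)) {
    stop("negative values in: ", paste(.numeric_columns[neg], collapse = ", "))
  }
  class(x) <- c("hlh_cohort", "data.frame")
  attr(x, "provenance") <- provenance %||% attr(x, "provenance")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check the study inclusion rule (ferritin above 5,000 ug/L)
#'
#' @param cohort An [hlh_cohort()].
#' @param threshold Inclusion threshold in ug/L.
#' @return Logical vector, one entry per patient.
#' @export
meets_inclusion <- function(cohort, threshold = 5000) {
  cohort$ferritin_ugL > threshold
}

#' @export
print.hlh_cohort <- function(x, ...) {
  cat("HLH cohort:", nrow(x), "patient(s)")
  if (!is.null(attr(x, "provenance"))) cat(" [", attr(x, "provenance"), "]", sep = "")
  cat("\n")
  cens <- sum(x$ferritin_censored, na.rm = TRUE)
  if (nrow(x) > 0) {
    cat(sprintf("  ferritin %s-%s ug/L (%d censored at assay ceiling)\n",
                format(min(x$ferritin_ugL), big.mark = ","),
                format(max(x$ferritin_ugL), big.mark = ","), cens))
  }
  if (nrow(x) > 0) {
    print(utils::head(as.data.frame(x)[, c("patient_id", "age_years",
                                           "ferritin_ugL", "ferritin_censored",
                                           "fever_documented", "conditions")]))
    if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more row(s)\n")
  }
  invisible(x)
}

#' Keep the presentation with the peak ferritin for each patient
#'
#' When a patient triggered several critical ferritin results, the analysis
#' uses the clinical presentation corresponding to the peak value. Censored
#' results compare as the assay ceiling; ties are broken by the earliest
#' record in the input order.
#'
#' @param records An [hlh_cohort()]-like data frame possibly holding several
#'   rows per `patient_id` (duplicate ids allowed here, unlike in a
#'   validated cohort).
#' @return An [hlh_cohort()] with one row per patient.
#' @export
select_peak_presentation <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("select_peak_presentation() requires a non-empty set of records")
  }
  idx <- unlist(lapply(split(seq_len(nrow(records)), records$patient_id), function(i) {
    i[which.max(records$ferritin_ugL[i])]  # which.max takes the first maximum
  }), use.names = FALSE)
  out <- records[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  hlh_cohort(out, provenance = attr(records, "provenance"))
}
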