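#' The published HScore-positive patients (fixture)
#'
#' The 14 patients of the study cohort who scored at or above the HScore
#' cutoff of 169, as published: documented conditions, peak serum ferritin
#' (ten at the assay ceiling of 16,500 ug/L, stored censored), the published
#' HScore total and probability band, and whether the treating clinicians
#' diagnosed HLH (six patients). Clinical flags and other laboratory values
#' were not published for these rows and are missing.
#'
#' @return An [hlh_cohort()] of 14 records, with the published scores
#'   attached as attribute `"published"` (a data frame with columns
#'   `patient_id`, `hscore`, `probability_band`).
#' @examples
#' tab2 <- table2_fixture()
#' mean(numeric_ferritin(tab2$ferritin_ugL, tab2$ferritin_censored))
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_hscore_positive.csv",
                      package = "hlhscreen", mustWork = TRUE)
  cohort <- read_cohort(path, provenance = "published HScore-positive patients")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  attr(cohort, "published") <- data.frame(
    patient_id = raw$patient_id,
    hscore = as.integer(raw$published_hscore),
    probability_band = raw$published_band,
    stringsAsFactors = FALSE
  )
  cohort
}

#' Published group-comparison counts (fixture)
#'
#' The published comparison of patient characteristics between the HScore
#' < 169 group (n = 106) and the HScore >= 169 group (n = 14): per-feature
#' counts (or, for ferritin, group means), the test used, and the published
#' statistic and p-value. These counts are the inputs from which the
#' chi-squared statistics can be recomputed; the 106 individual
#' below-cutoff records themselves were not published.
#'
#' @return A data frame with columns `feature`, `label`, `test`,
#'   `value_neg`, `value_pos` (count or mean per group), `n_neg`, `n_pos`,
#'   `printed_statistic`, `printed_p`.
#' @export
table3_counts <- function() {
  path <- system.file("extdata", "table3_counts.csv",
                      package = "hlhscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
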