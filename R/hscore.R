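# Table of HScore component points. Component maxima sum to 337:
# 49 + 38 + 18 + 50 + 34 + 64 + 30 + 19 + 35.
.hscore_points <- list(
  fever = c(0, 33, 49),
  organomegaly = c(0, 23, 38),
  immunosuppression = c(0, 18),
  ferritin = c(0, 35, 50),
  cytopaenia = c(0, 24, 34),
  triglycerides = c(0, 44, 64),
  fibrinogen = c(0, 30),
  transaminase = c(0, 19),
  haemophagocytosis = c(0, 35)
)

#' HScore scoring policy
#'
#' Bundles the configurable choices of the HScore engine. Defaults replicate
#' a retrospective audit setting: inputs a clinician never requested score
#' zero points, a documented fever without a recorded temperature scores the
#' middle (33-point) fever band, positivity is "total >= 169", and ALT
#' substitutes for AST only when AST is unavailable.
#'
#' @param missing `"zero"` (default): a missing input contributes 0 points;
#'   `"error"`: scoring stops with an error naming the missing fields.
#' @param cutoff Positivity cutoff on the total (default 169).
#' @param cutoff_rule `"ge"` (default, total >= cutoff) or `"gt"`
#'   (total > cutoff, the wording used when the score was introduced).
#' @param documented_fever_points Points awarded when only the binary
#'   "fever documented" flag is known (default 33, the middle band).
#' @param hb_cutoff,plt_cutoff,neut_cutoff Cytopaenia lineage thresholds:
#'   haemoglobin <= 90 g/L, platelets <= 100 x 10^9/L,
#'   neutrophils <= 1 x 10^9/L.
#' @param ast_cutoff,alt_cutoff Transaminase thresholds (AST >= 30 U/L;
#'   ALT >= 100 U/L when AST is unavailable).
#' @return A list of class `hscore_policy`.
#' @export
hscore_policy <- function(missing = c("zero", "error"),
                          cutoff = 169,
                          cutoff_rule = c("ge", "gt"),
                          documented_fever_points = 33,
                          hb_cutoff = 90, plt_cutoff = 100, neut_cutoff = 1,
                          ast_cutoff = 30, alt_cutoff = 100) {
  missing <- match.arg(missing)
  cutoff_rule <- match.arg(cutoff_rule)
  stopifnot(documented_fever_points %in% .hscore_points$fever)
  structure(list(missing = missing, cutoff = cutoff, cutoff_rule = cutoff_rule,
                 documented_fever_points = documented_fever_points,
                 hb_cutoff = hb_cutoff, plt_cutoff = plt_cutoff,
                 neut_cutoff = neut_cutoff, ast_cutoff = ast_cutoff,
                 alt_cutoff = alt_cutoff),
            class = "hscore_policy")
}

#' Compute the HScore for every patient in a cohort
#'
#' Nine weighted components: temperature (0/33/49), hepato-/splenomegaly
#' (0/23/38), immunosuppression (0/18), ferritin (<2,000: 0; 2,000-6,000:
#' 35; >6,000: 50, censored results counting as the assay ceiling),
#' cytopaenic lineages (<=1: 0; 2: 24; 3: 34), triglycerides (<1.5: 0;
#' 1.5-4: 44; >4: 64 mmol/L), fibrinogen (<2.5 g/L: 30), transaminases
#' (AST >= 30 U/L, or ALT >= 100 U/L when no AST result exists: 19) and
#' haemophagocytosis (35). The temperature bands are <38.4 -> 0,
#' 38.4-39.4 -> 33, >=39.4 -> 49; when only a binary "fever documented"
#' flag is available, a documented fever scores
#' `policy$documented_fever_points`.
#'
#' @param cohort An [hlh_cohort()] (or data frame coercible to one).
#' @param policy An [hscore_policy()].
#' @return An object of class `hscore`: a data frame with one row per
#'   patient holding the nine component point columns (`points_*`), the
#'   `total` (0-337), `positive` at the policy cutoff, and the
#'   `probability_band` label; per-component input notes are attached as
#'   attribute `"basis"`.
#' @examples
#' p <- patient_record("x", ferritin_ugL = 5150)
#' hscore(p)$total   # 35: ferritin band only
#' @export
hscore <- function(cohort, policy = hscore_policy()) {
  stopifnot(inherits(policy, "hscore_policy"))
  if (!inherits(cohort, "hlh_cohort")) cohort <- hlh_cohort(cohort)
  n <- nrow(cohort)

  if (policy$missing == "error") {
    needed <- c("hepatomegaly", "splenomegaly", "immunosuppressed",
                "haemoglobin_gL", "platelets_1e9L", "neutrophils_1e9L",
                "triglycerides_mmolL", "fibrinogen_gL", "haemophagocytosis")
    holes <- needed[vapply(needed, function(col) anyNA(cohort[[col]]), logical(1))]
    if (any(is.na(cohort$ast_UL) & is.na(cohort$alt_UL))) {
      holes <- c(holes, "ast_UL/alt_UL")
    }
    if (any(is.na(cohort$temperature_celsius) & is.na(cohort$fever_documented))) {
      holes <- c(holes, "temperature_celsius/fever_documented")
    }
    if (length(holes)) {
      stop("missing inputs under policy missing='error': ",
           paste(unique(holes), collapse = ", "))
    }
  }

  note <- function(cond, used, alt = "missing -> 0") ifelse(cond, used, alt)
  temp <- cohort$temperature_celsius
  fever_band <- ifelse(!is.na(temp),
                       ifelse(temp >= 39.4, 3L, ifelse(temp >= 38.4, 2L, 1L)),
                       ifelse(cohort$fever_documented %in% TRUE,
                              match(policy$documented_fever_points,
                                    .hscore_points$fever), 1L))
  points_fever <- .hscore_points$fever[fever_band]
  basis_fever <- ifelse(!is.na(temp), sprintf("temperature %.1f C", temp),
                        ifelse(cohort$fever_documented %in% TRUE,
                               "documented fever (33-point policy)",
                               ifelse(is.na(cohort$fever_documented),
                                      "missing -> 0", "no fever")))

  n_organo <- (cohort$hepatomegaly %in% TRUE) + (cohort$splenomegaly %in% TRUE)
  points_organomegaly <- .hscore_points$organomegaly[n_organo + 1L]
  basis_organo <- sprintf("%d organomegaly(ies)%s", n_organo,
                          ifelse(is.na(cohort$hepatomegaly) | is.na(cohort$splenomegaly),
                                 " (missing counted absent)", ""))

  points_immunosuppression <- ifelse(cohort$immunosuppressed %in% TRUE, 18, 0)
  basis_immuno <- note(cohort$immunosuppressed %in% TRUE, "immunosuppressed",
                       ifelse(is.na(cohort$immunosuppressed), "missing -> 0", "not immunosuppressed"))

  ferr <- numeric_ferritin(cohort$ferritin_ugL, cohort$ferritin_censored)
  points_ferritin <- ifelse(ferr > 6000, 50, ifelse(ferr >= 2000, 35, 0))
  basis_ferritin <- sprintf("ferritin %s ug/L%s", .num2chr(ferr),
                            ifelse(cohort$ferritin_censored, " (censored at ceiling)", ""))

  lineages <- (cohort$haemoglobin_gL <= policy$hb_cutoff) %in% TRUE
  lineages <- lineages + ((cohort$platelets_1e9L <= policy$plt_cutoff) %in% TRUE)
  lineages <- lineages + ((cohort$neutrophils_1e9L <= policy$neut_cutoff) %in% TRUE)
  points_cytopaenia <- ifelse(lineages >= 3, 34, ifelse(lineages == 2, 24, 0))
  basis_cyto <- sprintf("%d cytopaenic lineage(s)", lineages)

  tg <- cohort$triglycerides_mmolL
  points_triglycerides <- ifelse(is.na(tg), 0, ifelse(tg > 4, 64, ifelse(tg >= 1.5, 44, 0)))
  basis_tg <- note(!is.na(tg), sprintf("triglycerides %s mmol/L", .num2chr(tg)))

  fib <- cohort$fibrinogen_gL
  points_fibrinogen <- ifelse(!is.na(fib) & fib < 2.5, 30, 0)
  basis_fib <- note(!is.na(fib), sprintf("fibrinogen %s g/L", .num2chr(fib)))

  ast <- cohort$ast_UL
  alt <- cohort$alt_UL
  points_transaminase <- ifelse(!is.na(ast),
                                ifelse(ast >= policy$ast_cutoff, 19, 0),
                                ifelse(!is.na(alt) & alt >= policy$alt_cutoff, 19, 0))
  basis_lft <- ifelse(!is.na(ast), sprintf("AST %s U/L", .num2chr(ast)),
                      ifelse(!is.na(alt),
                             sprintf("ALT %s U/L (substituted, no AST)", .num2chr(alt)),
                             "missing -> 0"))

  points_haemophagocytosis <- ifelse(cohort$haemophagocytosis %in% TRUE, 35, 0)
  basis_hph <- note(cohort$haemophagocytosis %in% TRUE, "haemophagocytosis present",
                    ifelse(is.na(cohort$haemophagocytosis), "missing -> 0", "not seen"))

  total <- points_fever + points_organomegaly + points_immunosuppression +
    points_ferritin + points_cytopaenia + points_triglycerides +
    points_fibrinogen + points_transaminase + points_haemophagocytosis

  out <- data.frame(
    patient_id = cohort$patient_id,
    points_fever = points_fever,
    points_organomegaly = points_organomegaly,
    points_immunosuppression = points_immunosuppression,
    points_ferritin = points_ferritin,
    points_cytopaenia = points_cytopaenia,
    points_triglycerides = points_triglycerides,
    points_fibrinogen = points_fibrinogen,
    points_transaminase = points_transaminase,
    points_haemophagocytosis = points_haemophagocytosis,
    total = as.integer(total),
    positive = hscore_positive(total, policy$cutoff, policy$cutoff_rule),
    probability_band = probability_band(total),
    stringsAsFactors = FALSE
  )
  attr(out, "basis") <- data.frame(
    patient_id = cohort$patient_id, fever = basis_fever,
    organomegaly = basis_organo, immunosuppression = basis_immuno,
    ferritin = basis_ferritin, cytopaenia = basis_cyto,
    triglycerides = basis_tg, fibrinogen = basis_fib,
    transaminase = basis_lft, haemophagocytosis = basis_hph,
    stringsAsFactors = FALSE
  )
  attr(out, "policy") <- policy
  class(out) <- c("hscore", "data.frame")
  out
}

#' HScore positivity at a cutoff
#'
#' @param total Integer vector of HScore totals (0-337).
#' @param cutoff Cutoff score, default 169.
#' @param rule `"ge"` (total >= cutoff, default) or `"gt"`.
#' @return Logical vector.
#' @export
hscore_positive <- function(total, cutoff = 169, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  stopifnot(all(total >= 0 & total <= 337))
  if (rule == "ge") total >= cutoff else total > cutoff
}

#' Probability-of-sHLH band for an HScore total
#'
#' Maps totals to the published probability labels ("54" ... ">99") via a
#' calibration table of non-overlapping score intervals shipped with the
#' package. Boundaries between published (score, band) anchor pairs are
#' interpolated; scores outside the table clamp to the lowest/highest band.
#'
#' @param total Integer vector of HScore totals.
#' @param calibration Calibration table as returned by [hscore_bands()].
#' @return Character vector of band labels.
#' @examples
#' probability_band(c(174, 227, 321))   # "54" "96" ">99"
#' @export
probability_band <- function(total, calibration = hscore_bands()) {
  stopifnot(is.data.frame(calibration),
            all(c("lower", "upper", "label") %in% names(calibration)))
  calibration <- calibration[order(calibration$lower), ]
  if (any(calibration$lower[-1] <= calibration$upper[-nrow(calibration)])) {
    stop("calibration intervals overlap")
  }
  idx <- findInterval(pmax(pmin(total, max(calibration$upper)),
                           min(calibration$lower)),
                      calibration$lower)
  calibration$label[idx]
}

#' The shipped HScore probability-band calibration table
#'
#' @return A data frame with columns `lower`, `upper` (inclusive score
#'   interval), `label`, and `interpolated_upper` flagging boundaries that
#'   are interpolated between published anchor pairs rather than published
#'   themselves.
#' @export
hscore_bands <- function() {
  path <- system.file("extdata", "hscore_bands.yaml",
                      package = "hlhscreen", mustWork = TRUE)
  raw <- yaml::read_yaml(path)$bands
  do.call(rbind, lapply(raw, function(b)
    data.frame(lower = b$lower, upper = b$upper, label = b$label,
               interpolated_upper = isTRUE(b$interpolated_upper),
               stringsAsFactors = FALSE)))
}

#' @export
print.hscore <- function(x, ...) {
  cat("HScore results for", nrow(x), "patient(s); cutoff",
      attr(x, "policy")$cutoff,
      sprintf("(%s)\n", attr(x, "policy")$cutoff_rule))
  cat(sum(x$positive), "positive\n")
  print.data.frame(x[, c("patient_id", "total", "positive", "probability_band")],
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.hscore <- function(object, ...) {
  structure(list(n = nrow(object), positive = sum(object$positive),
                 totals = summary(object$total),
                 component_means = colMeans(object[grep("^points_", names(object))])),
            class = "summary.hscore")
}

#' @export
print.summary.hscore <- function(x, ...) {
  cat("HScore summary:", x$n, "patient(s),", x$positive, "positive\n")
  print(x$totals)
  cat("mean component points:\n")
  print(round(x$component_means, 1))
  invisible(x)
}
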