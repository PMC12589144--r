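test_that("rule predicates follow strict inequalities and the missing policy", {
  rule <- screening_rule(5000, require_fever = TRUE)
  hit <- patient_record("a", ferritin_ugL = 9107, fever_documented = TRUE)
  expect_true(apply_rule(rule, hit))

  boundary <- patient_record("b", ferritin_ugL = 5000, fever_documented = TRUE)
  expect_false(apply_rule(screening_rule(5000), boundary))  # strictly greater

  nofever <- patient_record("c", ferritin_ugL = 9000)
  expect_false(apply_rule(rule, nofever))                      # missing = fail
  expect_true(is.na(apply_rule(rule, nofever, missing = "unevaluable")))

  censored <- patient_record("d", ferritin_ugL = 16500, ferritin_censored = TRUE)
  expect_true(apply_rule(screening_rule(16000), censored))  # censored = ceiling

  plt <- screening_rule(5000, platelet_cutoff_1e9L = 100)
  expect_true(apply_rule(plt, patient_record("e", ferritin_ugL = 6000,
                                             platelets_1e9L = 99)))
  expect_false(apply_rule(plt, patient_record("f", ferritin_ugL = 6000,
                                              platelets_1e9L = 100)))
  expect_error(screening_rule(NULL), "at least one")
})

test_that("confusion matrices handle degenerate and textbook cases", {
  cohort <- generate_cohort(generator_config(n = 60), seed = 5)
  truth <- attr(cohort, "truth")$group == "positive"

  all_flag <- evaluate_rule(screening_rule(1), cohort, reference = truth)
  expect_equal(all_flag$sensitivity, 1)
  expect_equal(all_flag$specificity, 0)

  none_flag <- evaluate_rule(screening_rule(1e9), cohort, reference = truth)
  expect_equal(none_flag$sensitivity, 0)
  expect_equal(none_flag$specificity, 1)
  expect_equal(none_flag$tn + none_flag$fp, sum(!truth))

  no_pos <- evaluate_rule(screening_rule(5000), cohort,
                          reference = rep(FALSE, nrow(cohort)))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(no_pos$undefined[["sensitivity"]])
})

test_that("a rule catching 16 of 17 reference positives shows 94.1% sensitivity", {
  # 16 positives with fever, 1 without; rule = ferritin > 5,000 AND fever
  pos <- lapply(1:16, function(i) patient_record(
    paste0("p", i), ferritin_ugL = 8000, fever_documented = TRUE))
  miss <- list(patient_record("p17", ferritin_ugL = 8000, fever_documented = FALSE))
  neg <- lapply(1:20, function(i) patient_record(
    paste0("n", i), ferritin_ugL = 6000, fever_documented = i <= 5))
  cohort <- bind_cohort(c(pos, miss, neg))
  truth <- c(rep(TRUE, 17), rep(FALSE, 20))
  cm <- evaluate_rule(screening_rule(5000, TRUE), cohort, reference = truth)
  expect_equal(cm$tp, 16L)
  expect_equal(cm$fn, 1L)
  expect_equal(round_half_up(100 * cm$sensitivity, 1), 94.1)
})

test_that("cell totals are conserved across reference standards", {
  cohort <- generate_cohort(generator_config(n = 80), seed = 9)
  rule <- screening_rule(7000, TRUE)
  for (ref in c("hlh04", "hscore", "clinician")) {
    cm <- evaluate_rule(rule, cohort, reference = ref)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, nrow(cohort))
  }
})

test_that("stricter rules trade sensitivity for specificity", {
  cohort <- generate_cohort(generator_config(n = 2000), seed = 31)
  truth <- attr(cohort, "truth")$group == "positive"
  cuts <- c(5000, 6000, 7000, 9000, 12000)
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    cm <- evaluate_rule(screening_rule(cuts[i], TRUE), cohort, reference = truth)
    sens[i] <- cm$sensitivity
    spec[i] <- cm$specificity
  }
  expect_true(all(diff(sens) <= 0))  # raising the cutoff never gains sensitivity
  expect_true(all(diff(spec) >= 0))  # and never loses specificity

  # adding a predicate never increases sensitivity
  base <- evaluate_rule(screening_rule(5000), cohort, reference = truth)
  plus_fever <- evaluate_rule(screening_rule(5000, TRUE), cohort, reference = truth)
  plus_plt <- evaluate_rule(screening_rule(5000, TRUE, 100), cohort, reference = truth)
  expect_lte(plus_fever$sensitivity, base$sensitivity)
  expect_lte(plus_plt$sensitivity, plus_fever$sensitivity)
})

test_that("the rule grid enumerates combinations sorted by Youden index", {
  cohort <- generate_cohort(generator_config(n = 300), seed = 12)
  grid <- rule_grid(cohort, ferritin_cutoffs = c(5000, 7000),
                    with_fever = TRUE, platelet_cutoffs = NA)
  expect_equal(nrow(grid), 2L)
  grid2 <- rule_grid(cohort, c(5000, 7000), c(FALSE, TRUE), c(NA, 100))
  expect_equal(nrow(grid2), 8L)
  expect_true(all(diff(grid2$youden) <= 0))
  # ties (if any) are ordered by lower ferritin cutoff
  dup <- duplicated(grid2$youden) | duplicated(grid2$youden, fromLast = TRUE)
  if (any(dup)) {
    for (y in unique(grid2$youden[dup])) {
      expect_false(is.unsorted(grid2$ferritin_cutoff[grid2$youden == y]))
    }
  }
  empty <- hlh_cohort(as.data.frame(cohort)[0, ])
  expect_error(rule_grid(empty, 5000, TRUE, NA), "empty cohort")
})
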