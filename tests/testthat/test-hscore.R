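test_that("single-component and maximal records score as tabulated", {
  # ferritin in the 2,000-6,000 band is the only contributing component
  expect_equal(hscore(patient_record("a", ferritin_ugL = 5150))$total, 35L)

  maximal <- patient_record("m", ferritin_ugL = 16500, ferritin_censored = TRUE,
                            temperature_celsius = 39.6, hepatomegaly = TRUE,
                            splenomegaly = TRUE, immunosuppressed = TRUE,
                            haemoglobin_gL = 70, platelets_1e9L = 40,
                            neutrophils_1e9L = 0.5, triglycerides_mmolL = 4.5,
                            fibrinogen_gL = 1.0, alt_UL = 150,
                            haemophagocytosis = TRUE)
  res <- hscore(maximal)
  expect_equal(res$total, 337L)  # 49+38+18+50+34+64+30+19+35
  expect_true(res$positive)
  # ALT substitution applies because no AST result exists
  expect_equal(res$points_transaminase, 19)
})

test_that("component band boundaries follow the published table", {
  base <- list(patient_id = "b", ferritin_ugL = 1000)
  total_of <- function(...) hscore(do.call(patient_record, modifyList(base, list(...))))$total

  expect_equal(total_of(temperature_celsius = 38.3), 0L)
  expect_equal(total_of(temperature_celsius = 38.4), 33L)
  expect_equal(total_of(temperature_celsius = 39.4), 49L)
  # documented fever without a recorded temperature scores the middle band
  expect_equal(total_of(fever_documented = TRUE), 33L)
  expect_equal(total_of(fever_documented = FALSE), 0L)

  expect_equal(hscore(patient_record("f", ferritin_ugL = 1999))$total, 0L)
  expect_equal(hscore(patient_record("f", ferritin_ugL = 2000))$total, 35L)
  expect_equal(hscore(patient_record("f", ferritin_ugL = 6000))$total, 35L)
  expect_equal(hscore(patient_record("f", ferritin_ugL = 6001))$total, 50L)

  expect_equal(total_of(triglycerides_mmolL = 1.49), 0L)
  expect_equal(total_of(triglycerides_mmolL = 1.5), 44L)
  expect_equal(total_of(triglycerides_mmolL = 4), 44L)
  expect_equal(total_of(triglycerides_mmolL = 4.01), 64L)

  expect_equal(total_of(fibrinogen_gL = 2.5), 0L)
  expect_equal(total_of(fibrinogen_gL = 2.49), 30L)

  # cytopaenia lineages at their thresholds: <=90, <=100, <=1 all count
  expect_equal(total_of(haemoglobin_gL = 90, platelets_1e9L = 100), 24L)
  expect_equal(total_of(haemoglobin_gL = 90, platelets_1e9L = 100,
                        neutrophils_1e9L = 1), 34L)
  expect_equal(total_of(haemoglobin_gL = 90), 0L)  # a single lineage scores 0

  expect_equal(total_of(ast_UL = 30), 19L)
  expect_equal(total_of(ast_UL = 29, alt_UL = 400), 0L)  # AST present wins
  expect_equal(total_of(alt_UL = 100), 19L)
  expect_equal(total_of(alt_UL = 99), 0L)
})

test_that("records realising each published total reproduce it", {
  enum <- hscore_enumeration()
  totals <- hscore(enum$cohort)$total
  published <- c(174, 177, 181, 193, 194, 202, 205, 227, 241, 267, 291, 321)
  for (target in published) {
    idx <- which(enum$expected == target)
    expect_gt(length(idx), 0)
    expect_true(all(totals[idx] == target))
  }
})

test_that("positivity cutoff behaves at the boundary under both rules", {
  expect_true(hscore_positive(169))
  expect_false(hscore_positive(168))
  expect_true(hscore_positive(337))
  expect_false(hscore_positive(169, rule = "gt"))
  expect_true(hscore_positive(170, rule = "gt"))
  expect_error(hscore_positive(400))
})

test_that("probability bands honour every published (score, band) pair", {
  anchors <- data.frame(score = c(174, 174, 177, 177, 181, 193, 194, 202,
                                  205, 227, 241, 267, 291, 321),
                        band = c("54", "54", "54", "54", "70", "80", "80",
                                 "88", "88", "96", ">99", ">99", ">99", ">99"))
  anchors$band[anchors$score == 241] <- "99"
  expect_equal(probability_band(anchors$score), anchors$band)
  # out-of-range scores clamp to the extreme bands
  expect_equal(probability_band(c(0, 150)), c("54", "54"))
  expect_equal(probability_band(337), ">99")
  expect_error(probability_band(200, calibration = data.frame(
    lower = c(0, 100), upper = c(150, 337), label = c("a", "b"))), "overlap")
})

test_that("worsening any single input never decreases the total", {
  set.seed(202)
  enum_names <- names(hscore_band_points)
  for (rep in 1:40) {
    bands <- lapply(hscore_band_points, function(p) sample(seq_along(p), 1))
    base_total <- hscore(record_from_bands(bands))$total
    comp <- sample(enum_names, 1)
    if (bands[[comp]] < length(hscore_band_points[[comp]])) {
      worse <- bands
      worse[[comp]] <- worse[[comp]] + 1L
      expect_gte(hscore(record_from_bands(worse))$total, base_total)
    }
  }
})

test_that("a missing field scores no more than the same record at its worst band", {
  worst <- list(fever = 3, organomegaly = 3, immunosuppression = 2,
                ferritin = 3, cytopaenia = 3, triglycerides = 3,
                fibrinogen = 2, transaminase = 2, haemophagocytosis = 2)
  full <- hscore(record_from_bands(worst))$total
  droppable <- list(
    fever = c("temperature_celsius", "fever_documented"),
    organomegaly = c("hepatomegaly", "splenomegaly"),
    immunosuppression = "immunosuppressed",
    cytopaenia = c("haemoglobin_gL", "platelets_1e9L", "neutrophils_1e9L"),
    triglycerides = "triglycerides_mmolL",
    fibrinogen = "fibrinogen_gL",
    transaminase = c("ast_UL", "alt_UL"),
    haemophagocytosis = "haemophagocytosis")
  for (comp in names(droppable)) {
    rec <- as.data.frame(record_from_bands(worst))
    rec[droppable[[comp]]] <- NA
    expect_lte(hscore(hlh_cohort(rec))$total, full)
  }
})

test_that("the strict missing-data policy refuses incomplete records", {
  rec <- patient_record("x", ferritin_ugL = 9000, fever_documented = TRUE)
  expect_error(hscore(rec, hscore_policy(missing = "error")), "missing inputs")
  enum <- hscore_enumeration()
  expect_silent(hscore(enum$cohort[1, ], hscore_policy(missing = "error")))
})
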