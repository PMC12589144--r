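test_that("reading parses censoring markers, thousands separators and blanks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,ferritin_ugL,triglycerides_mmolL,fever_documented",
    "A,\">16,500\",,yes",
    "B,\"9,107\",2.5,no",
    "C,16500,1.1,"
  ), path)
  co <- read_cohort(path)
  expect_equal(co$ferritin_ugL, c(16500, 9107, 16500))
  # ">"-prefixed and at-ceiling cells are censored; 9,107 is not
  expect_equal(co$ferritin_censored, c(TRUE, FALSE, TRUE))
  expect_equal(co$triglycerides_mmolL, c(NA, 2.5, 1.1))
  expect_equal(co$fever_documented, c(TRUE, FALSE, NA))
})

test_that("schema mapping renames columns, from a vector or a YAML file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,peak_ferritin", "A,6000", "B,>16500"), path)
  co <- read_cohort(path, schema = c(patient_id = "id",
                                     ferritin_ugL = "peak_ferritin"))
  expect_equal(co$patient_id, c("A", "B"))
  expect_equal(co$ferritin_ugL, c(6000, 16500))

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("patient_id: id", "ferritin_ugL: peak_ferritin"), yml)
  expect_identical(read_cohort(path, schema = yml)$ferritin_ugL, co$ferritin_ugL)
})

test_that("malformed cells and missing required columns are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,ferritin_ugL,platelets_1e9L",
               "A,6000,lots", "B,high,40"), path)
  expect_error(read_cohort(path), "row 1, column 'platelets_1e9L'")
  expect_error(read_cohort(path), "row 2, column 'ferritin_ugL'")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age_years", "A,50"), path2)
  expect_error(read_cohort(path2), "required column")
  expect_error(read_cohort(path, schema = c(bogus_field = "x")), "unknown field")
})

test_that("a written cohort reads back field-for-field identical", {
  co <- generate_cohort(generator_config(n = 40), seed = 11)
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cohort(co, path)
    back <- read_cohort(path)
    expect_equal(as.data.frame(back)[names(as.data.frame(co))],
                 as.data.frame(co), ignore_attr = TRUE)
  }
})

test_that("cohort validation enforces ids, censoring consistency and sign", {
  expect_error(hlh_cohort(data.frame(patient_id = c("A", "A"),
                                     ferritin_ugL = c(6000, 7000))),
               "unique")
  expect_error(patient_record("A", ferritin_ugL = 12000,
                              ferritin_censored = TRUE),
               "assay ceiling")
  expect_error(patient_record("A", ferritin_ugL = 6000, platelets_1e9L = -5),
               "negative")
  expect_silent(patient_record("A", ferritin_ugL = 16500,
                               ferritin_censored = TRUE))
})

test_that("peak presentation keeps the maximal ferritin, censored at ceiling", {
  multi <- rbind(
    data.frame(patient_id = "A", ferritin_ugL = 6000, ferritin_censored = FALSE,
               fibrinogen_gL = 1.0),
    data.frame(patient_id = "A", ferritin_ugL = 9107, ferritin_censored = FALSE,
               fibrinogen_gL = 3.0),
    data.frame(patient_id = "B", ferritin_ugL = 16500, ferritin_censored = TRUE,
               fibrinogen_gL = NA),
    data.frame(patient_id = "B", ferritin_ugL = 12273, ferritin_censored = FALSE,
               fibrinogen_gL = 2.0),
    data.frame(patient_id = "C", ferritin_ugL = 5150, ferritin_censored = FALSE,
               fibrinogen_gL = NA)
  )
  peak <- select_peak_presentation(multi)
  expect_equal(nrow(peak), 3L)
  expect_equal(peak$fibrinogen_gL[peak$patient_id == "A"], 3.0)  # row with 9,107
  expect_true(peak$ferritin_censored[peak$patient_id == "B"])   # >16,500 outranks 12,273
  expect_equal(peak$ferritin_ugL[peak$patient_id == "C"], 5150) # singleton passthrough

  # output ferritin dominates every input ferritin for that patient
  for (id in unique(multi$patient_id)) {
    expect_gte(peak$ferritin_ugL[peak$patient_id == id],
               max(multi$ferritin_ugL[multi$patient_id == id]))
  }

  # ties broken by earliest record order
  tie <- rbind(data.frame(patient_id = "T", ferritin_ugL = 8000,
                          ferritin_censored = FALSE, fibrinogen_gL = 1.0),
               data.frame(patient_id = "T", ferritin_ugL = 8000,
                          ferritin_censored = FALSE, fibrinogen_gL = 9.0))
  expect_equal(select_peak_presentation(tie)$fibrinogen_gL, 1.0)

  expect_error(select_peak_presentation(multi[0, ]), "non-empty")
})

test_that("censored ferritin converts per policy", {
  expect_equal(numeric_ferritin(censored_value(16500, TRUE)), 16500)
  expect_equal(numeric_ferritin(5150, FALSE), 5150)
  expect_true(is.na(numeric_ferritin(16500, TRUE, policy = "exclude")))
  expect_equal(numeric_ferritin(c(9107, 16500), c(FALSE, TRUE),
                                policy = "exclude"),
               c(9107, NA))
  expect_error(numeric_ferritin(16500, TRUE, policy = "midpoint"))
  expect_error(censored_value(12000, censored = TRUE), "ceiling")
})

test_that("the published positive-patient fixture matches its source", {
  tab2 <- table2_fixture()
  expect_equal(nrow(tab2), 14L)
  expect_equal(tab2$ferritin_ugL[1], 9107)
  expect_false(tab2$ferritin_censored[1])
  expect_equal(sum(tab2$ferritin_censored), 10L)
  expect_equal(sum(tab2$clinician_hlh_diagnosis), 6L)
  expect_true(all(meets_inclusion(tab2)))

  pub <- attr(tab2, "published")
  expect_equal(nrow(pub), 14L)
  expect_equal(range(pub$hscore), c(174L, 321L))
})
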