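# Shared builders for records exercising the scoring engines.

# Stack one-row records built by patient_record() into one cohort.
bind_cohort <- function(...) {
  rows <- list(...)
  if (length(rows) == 1L && is.list(rows[[1]]) && !is.data.frame(rows[[1]])) {
    rows <- rows[[1]]
  }
  hlh_cohort(do.call(rbind, lapply(rows, as.data.frame)))
}

# Inputs realising each HScore component band (index 1 = 0-point band).
# Used to build records for a given component-band combination.
hscore_band_inputs <- list(
  fever = list(list(temperature_celsius = 37),
               list(temperature_celsius = 38.6),
               list(temperature_celsius = 39.6)),
  organomegaly = list(list(hepatomegaly = FALSE, splenomegaly = FALSE),
                      list(hepatomegaly = TRUE, splenomegaly = FALSE),
                      list(hepatomegaly = TRUE, splenomegaly = TRUE)),
  immunosuppression = list(list(immunosuppressed = FALSE),
                           list(immunosuppressed = TRUE)),
  ferritin = list(list(ferritin_ugL = 1000),
                  list(ferritin_ugL = 3000),
                  list(ferritin_ugL = 9000)),
  cytopaenia = list(list(haemoglobin_gL = 120, platelets_1e9L = 200, neutrophils_1e9L = 2),
                    list(haemoglobin_gL = 80, platelets_1e9L = 60, neutrophils_1e9L = 2),
                    list(haemoglobin_gL = 80, platelets_1e9L = 60, neutrophils_1e9L = 0.5)),
  triglycerides = list(list(triglycerides_mmolL = 1.0),
                       list(triglycerides_mmolL = 2.0),
                       list(triglycerides_mmolL = 5.0)),
  fibrinogen = list(list(fibrinogen_gL = 3.0),
                    list(fibrinogen_gL = 1.0)),
  transaminase = list(list(ast_UL = 20),
                      list(ast_UL = 40)),
  haemophagocytosis = list(list(haemophagocytosis = FALSE),
                           list(haemophagocytosis = TRUE))
)

hscore_band_points <- list(
  fever = c(0, 33, 49), organomegaly = c(0, 23, 38),
  immunosuppression = c(0, 18), ferritin = c(0, 35, 50),
  cytopaenia = c(0, 24, 34), triglycerides = c(0, 44, 64),
  fibrinogen = c(0, 30), transaminase = c(0, 19),
  haemophagocytosis = c(0, 35)
)

# Build a one-row cohort realising the given band index per component.
record_from_bands <- function(bands, id = "b") {
  args <- list(patient_id = id)
  for (comp in names(bands)) {
    args <- c(args, hscore_band_inputs[[comp]][[bands[[comp]]]])
  }
  do.call(patient_record, args)
}

# Every component-band combination, its realised cohort and expected totals.
hscore_enumeration <- function() {
  grid <- do.call(expand.grid, lapply(hscore_band_points, seq_along))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    as.data.frame(record_from_bands(as.list(grid[i, ]), id = paste0("e", i)))
  })
  expected <- rowSums(mapply(function(comp, idx) hscore_band_points[[comp]][idx],
                             names(grid), grid))
  list(cohort = hlh_cohort(do.call(rbind, rows)), expected = as.integer(expected))
}
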