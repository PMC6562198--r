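test_that("GCS converts to AVPU per the configured mapping", {
  expect_identical(gcs_to_avpu(c(15, 14, 13, 12, 9, 8, 3)),
                   c("A", "V", "V", "P", "P", "U", "U"))
  expect_error(gcs_to_avpu(16), "3, 15")
  expect_error(gcs_to_avpu(2), "3, 15")
  expect_error(gcs_to_avpu(12.5), "integer")
  expect_identical(gcs_to_avpu(NA), NA_character_)
})

test_that("single NEWS components score as tabulated", {
  expect_equal(news_component_weight("heart_rate", 75), 0)
  expect_equal(news_component_weight("supplemental_oxygen", TRUE), 2)
  expect_equal(news_component_weight("consciousness", "V"), 3)
  expect_equal(news_component_weight("consciousness", "A"), 0)
  expect_error(news_component_weight("pulse", 75), "unknown NEWS component")
  expect_error(news_component_weight("consciousness", "Q"), "AVPU")
})

test_that("aggregate NEWS covers the zero, maximal and single-term cases", {
  expect_equal(score_news(baseline_vitals())$news, 0L)
  worst <- baseline_vitals(heart_rate = 140, systolic_bp = 60,
                           respiratory_rate = 30, temperature = 34.0,
                           spo2 = 85, supplemental_oxygen = TRUE,
                           avpu = "U")
  expect_equal(score_news(worst)$news, 20L)
  expect_equal(score_news(baseline_vitals(heart_rate = 135))$news, 3L)
  expect_error(score_news(baseline_vitals(heart_rate = NA_real_)),
               "incomplete")
  expect_error(score_news(dplyr::select(baseline_vitals(), -"spo2")),
               "missing columns")
})

test_that("missing analytes score zero and hand-picked lookups match", {
  for (an in ldtews_analytes()) {
    expect_equal(ldtews_component_weight(an, NA, sex = "male"), 0,
                 info = an)
  }
  # one hand-picked (analyte, value, sex) triple per analyte, recorded
  # from the shipped table before the band machinery was wired up
  expect_equal(ldtews_component_weight("albumin", 17), 3)
  expect_equal(ldtews_component_weight("urea", 25), 2)
  expect_equal(ldtews_component_weight("sodium", 126), 1)
  expect_equal(ldtews_component_weight("potassium", 6.2), 2)
  expect_equal(ldtews_component_weight("wcc", 15), 1)
  expect_equal(ldtews_component_weight("haemoglobin", 110, sex = "male"), 1)
  expect_equal(ldtews_component_weight("haemoglobin", 110, sex = "female"), 0)
  expect_equal(ldtews_component_weight("creatinine", 160, sex = "male"), 0)
  expect_equal(ldtews_component_weight("creatinine", 160, sex = "female"), 1)
  # zero bands
  expect_equal(ldtews_component_weight("albumin", 40), 0)
  expect_error(ldtews_component_weight("platelets", 100), "unknown")
  expect_error(ldtews_component_weight("haemoglobin", 110), "sex")
})

test_that("aggregate LDT-EWS covers all-missing, maximal and single cases", {
  linked <- tibble::tibble(sex = "male")
  for (an in ldtews_analytes()) linked[[paste0(an, "_value")]] <- NA_real_
  expect_equal(score_ldtews(linked)$ldtews, 0L)

  worst <- tibble::tibble(sex = "female", albumin_value = 10,
                          creatinine_value = 400, haemoglobin_value = 60,
                          potassium_value = 7, sodium_value = 115,
                          urea_value = 40, wcc_value = 30)
  expect_equal(score_ldtews(worst)$ldtews, 15L)

  single <- linked
  single$urea_value <- 25
  expect_equal(score_ldtews(single)$ldtews, 2L)
})

test_that("aggregates equal an independent brute-force transcription", {
  withr::with_seed(101, {
    v <- random_vitals(2500)
    expected_news <- mapply(oracle_news, v$heart_rate, v$systolic_bp,
                            v$respiratory_rate, v$temperature, v$spo2,
                            v$supplemental_oxygen, v$avpu)
    expect_equal(score_news(v)$news, as.integer(expected_news))

    lv <- random_lab_values(2500)
    # sprinkle missingness across analytes
    for (an in ldtews_analytes()) {
      lv[[an]][runif(2500) < 0.15] <- NA
    }
    linked <- lv
    names(linked)[seq_len(7)] <- paste0(ldtews_analytes(), "_value")
    got <- score_ldtews(linked)$ldtews
    expected_ldt <- mapply(oracle_ldtews, lv$albumin, lv$creatinine,
                           lv$haemoglobin, lv$potassium, lv$sodium,
                           lv$urea, lv$wcc, lv$sex)
    expect_equal(got, as.integer(expected_ldt))
  })
})

test_that("sex only matters for the sex-specific analytes", {
  withr::with_seed(7, {
    lv <- random_lab_values(500)
    linked_m <- linked_f <- lv
    names(linked_m)[seq_len(7)] <- paste0(ldtews_analytes(), "_value")
    linked_f <- linked_m
    linked_m$sex <- "male"
    linked_f$sex <- "female"
    keep <- c("albumin", "potassium", "sodium", "urea", "wcc")
    m <- score_ldtews(linked_m, keep_components = TRUE)
    f <- score_ldtews(linked_f, keep_components = TRUE)
    for (an in keep) {
      expect_equal(m[[paste0("ldtews_", an)]], f[[paste0("ldtews_", an)]],
                   info = an)
    }
  })
})
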