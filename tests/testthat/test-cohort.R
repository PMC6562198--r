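make_trio <- function() {
  adm <- dplyr::bind_rows(
    baseline_admission(admission_id = "young", age = 15L),
    baseline_admission(admission_id = "elective",
                       admission_method = "elective"),
    baseline_admission(admission_id = "surgical", specialty = "orthopaedics"),
    baseline_admission(admission_id = "novitals"),
    baseline_admission(admission_id = "ok")
  )
  vit <- dplyr::bind_rows(
    baseline_vitals(admission_id = "young"),
    baseline_vitals(admission_id = "elective"),
    baseline_vitals(admission_id = "surgical"),
    baseline_vitals(admission_id = "ok"),
    baseline_vitals(admission_id = "ok", obs_time = ts("2023-03-02 10:00")),
    baseline_vitals(admission_id = "ok", obs_time = ts("2023-03-06 10:00"))
  )
  list(adm = adm, vit = vit)
}

test_that("inclusion keeps adult emergency medical admissions with vitals", {
  d <- make_trio()
  res <- apply_inclusion(d$adm, d$vit)
  expect_identical(res$admissions$admission_id, "ok")
  flow <- res$flow
  expect_equal(flow$excluded_n[flow$step == "age"], 1L)
  expect_equal(flow$excluded_n[flow$step == "admission method"], 1L)
  expect_equal(flow$excluded_n[flow$step == "specialty"], 1L)
  expect_equal(flow$excluded_n[flow$step == "no complete vital signs"], 1L)
})

test_that("audit counts sum to the input with first-failure attribution", {
  # an admission failing several criteria is counted once, at the first
  adm <- dplyr::bind_rows(
    baseline_admission(admission_id = "multi", age = 12L,
                       admission_method = "elective"),
    baseline_admission(admission_id = "ok")
  )
  vit <- baseline_vitals(admission_id = "ok")
  res <- apply_inclusion(adm, vit)
  flow <- res$flow[res$flow$step != "considered", ]
  expect_equal(sum(flow$excluded_n) + nrow(res$admissions), nrow(adm))
  expect_equal(flow$excluded_n[flow$step == "age"], 1L)
  expect_equal(flow$excluded_n[flow$step == "admission method"], 0L)
})

test_that("exclusions drop same-day alive discharges and end-of-life stays", {
  adm <- dplyr::bind_rows(
    # admitted 09:00, discharged alive 20:00 the same day -> (a)
    baseline_admission(admission_id = "sameday",
                       admit_time = ts("2023-03-01 09:00"),
                       discharge_time = ts("2023-03-01 20:00")),
    # died with last vitals 30 h before death -> (b)
    baseline_admission(admission_id = "eol",
                       death_time = ts("2023-03-04 12:00"),
                       discharge_time = ts("2023-03-04 12:00")),
    # died with vitals 2 h before death -> retained
    baseline_admission(admission_id = "monitored",
                       death_time = ts("2023-03-04 12:00"),
                       discharge_time = ts("2023-03-04 12:00")),
    # discharged alive same calendar day as admitted but after midnight
    baseline_admission(admission_id = "overnight",
                       admit_time = ts("2023-03-01 23:00"),
                       discharge_time = ts("2023-03-02 01:00"))
  )
  vit <- dplyr::bind_rows(
    baseline_vitals(admission_id = "sameday"),
    baseline_vitals(admission_id = "eol",
                    obs_time = ts("2023-03-03 06:00")),
    baseline_vitals(admission_id = "monitored",
                    obs_time = ts("2023-03-04 10:00")),
    baseline_vitals(admission_id = "overnight",
                    obs_time = ts("2023-03-01 23:30"))
  )
  res <- apply_exclusions(adm, vit)
  expect_setequal(res$admissions$admission_id, c("monitored", "overnight"))
  expect_equal(res$flow$excluded_n[1], 1L)
  expect_equal(res$flow$excluded_n[2], 1L)
})

test_that("24 h outcome labels follow the first-event, half-open window", {
  obs <- tibble::tibble(admission_id = "a1",
                        obs_time = ts("2023-03-02 10:00"))
  # death at +23.5 h
  adm <- baseline_admission(death_time = ts("2023-03-03 09:30"),
                            discharge_time = ts("2023-03-03 09:30"))
  lab1 <- label_outcomes(obs, adm)
  expect_true(lab1$outcome_primary_24h)
  expect_true(lab1$outcome_death_24h)
  expect_false(lab1$outcome_icu_24h)

  # ICU at +2 h, death at +40 h: primary via ICU, death label false
  adm2 <- baseline_admission(icu_admission_time = ts("2023-03-02 12:00"),
                             death_time = ts("2023-03-04 02:00"),
                             discharge_time = ts("2023-03-04 02:00"))
  lab2 <- label_outcomes(obs, adm2)
  expect_true(lab2$outcome_primary_24h)
  expect_true(lab2$outcome_icu_24h)
  expect_false(lab2$outcome_death_24h)

  # no events
  lab3 <- label_outcomes(obs, baseline_admission())
  expect_false(any(lab3$outcome_primary_24h, lab3$outcome_death_24h,
                   lab3$outcome_icu_24h))

  # event at exactly +24 h counts; just beyond does not
  adm4 <- baseline_admission(death_time = ts("2023-03-03 10:00"),
                             discharge_time = ts("2023-03-03 10:00"))
  expect_true(label_outcomes(obs, adm4)$outcome_primary_24h)
  adm5 <- baseline_admission(death_time = ts("2023-03-03 10:01"),
                             discharge_time = ts("2023-03-03 10:01"))
  expect_false(label_outcomes(obs, adm5)$outcome_primary_24h)
})

test_that("primary equals death OR icu when both events fall in-window", {
  obs <- tibble::tibble(admission_id = "a1",
                        obs_time = ts("2023-03-02 10:00"))
  adm <- baseline_admission(icu_admission_time = ts("2023-03-02 14:00"),
                            death_time = ts("2023-03-02 20:00"),
                            discharge_time = ts("2023-03-02 20:00"))
  lab <- label_outcomes(obs, adm)
  expect_true(lab$outcome_primary_24h)
  expect_identical(lab$outcome_primary_24h,
                   lab$outcome_death_24h | lab$outcome_icu_24h)
})

test_that("observations at or after the first event are dropped", {
  obs <- tibble::tibble(
    admission_id = "a1",
    obs_time = c(ts("2023-03-02 10:00"), ts("2023-03-02 14:00"),
                 ts("2023-03-02 16:00"))
  )
  adm <- baseline_admission(icu_admission_time = ts("2023-03-02 14:00"),
                            discharge_time = ts("2023-03-05 10:00"))
  lab <- label_outcomes(obs, adm)
  expect_equal(nrow(lab), 1L)
  expect_equal(lab$obs_time, ts("2023-03-02 10:00"))
})
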