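# shared builders and independent oracles used across test files

ts <- function(x) as.POSIXct(x, format = "%Y-%m-%d %H:%M", tz = "UTC")

# a complete, all-zero-weight vital-sign set; override fields as needed
baseline_vitals <- function(..., admission_id = "a1",
                            obs_time = ts("2023-03-01 10:00")) {
  out <- tibble::tibble(
    admission_id = admission_id, obs_time = obs_time,
    heart_rate = 75, systolic_bp = 120, respiratory_rate = 16,
    temperature = 37.0, spo2 = 98, supplemental_oxygen = FALSE,
    avpu = "A", gcs = NA_real_
  )
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

baseline_admission <- function(..., admission_id = "a1") {
  out <- tibble::tibble(
    admission_id = admission_id, age = 70L, sex = "female",
    admit_time = ts("2023-03-01 09:00"),
    discharge_time = ts("2023-03-06 12:00"),
    admission_method = "emergency", specialty = "acute_medicine",
    death_in_hospital = FALSE,
    death_time = .POSIXct(NA_real_, tz = "UTC"),
    icu_admission_time = .POSIXct(NA_real_, tz = "UTC")
  )
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out$death_in_hospital <- !is.na(out$death_time)
  out
}

lab_row <- function(admission_id, received_time, analyte, value) {
  tibble::tibble(admission_id = admission_id,
                 received_time = received_time,
                 analyte = analyte, value = value)
}

# independent brute-force NEWS: direct if/else transcription, written
# separately from the banded table machinery; uses the same resolved
# lower-inclusive convention for values between printed integer cut-offs
oracle_news <- function(hr, sbp, rr, temp, spo2, oxygen, avpu) {
  w <- 0
  w <- w + if (rr < 9) 3 else if (rr < 12) 1 else if (rr < 21) 0 else
    if (rr < 25) 2 else 3
  w <- w + if (spo2 < 92) 3 else if (spo2 < 94) 2 else if (spo2 < 96) 1 else 0
  w <- w + if (oxygen) 2 else 0
  t <- round(temp, 1)
  w <- w + if (t < 35.1) 3 else if (t < 36.1) 1 else if (t < 38.1) 0 else
    if (t < 39.1) 1 else 2
  w <- w + if (sbp < 91) 3 else if (sbp < 101) 2 else if (sbp < 111) 1 else
    if (sbp < 220) 0 else 3
  w <- w + if (hr < 41) 3 else if (hr < 51) 1 else if (hr < 91) 0 else
    if (hr < 111) 1 else if (hr < 131) 2 else 3
  w <- w + if (avpu == "A") 0 else 3
  w
}

# independent brute-force LDT-EWS against the shipped reconstruction
oracle_ldtews <- function(albumin, creatinine, haemoglobin, potassium,
                          sodium, urea, wcc, sex) {
  sc <- function(v, f) if (is.na(v)) 0 else f(v)
  w <- 0
  w <- w + sc(albumin, function(v) if (v < 18) 3 else if (v < 25) 2 else
    if (v < 33) 1 else 0)
  w <- w + sc(urea, function(v) if (v < 12) 0 else if (v < 20) 1 else
    if (v < 30) 2 else 3)
  w <- w + sc(sodium, function(v) if (v < 125) 2 else if (v < 132) 1 else
    if (v < 146) 0 else if (v < 150) 1 else 2)
  w <- w + sc(potassium, function(v) if (v < 3) 2 else if (v < 3.5) 1 else
    if (v < 5.5) 0 else if (v < 6) 1 else 2)
  w <- w + sc(wcc, function(v) if (v < 2) 2 else if (v < 4) 1 else
    if (v < 12) 0 else if (v < 20) 1 else 2)
  w <- w + sc(haemoglobin, function(v) {
    if (sex == "male") {
      if (v < 85) 2 else if (v < 115) 1 else 0
    } else {
      if (v < 80) 2 else if (v < 105) 1 else 0
    }
  })
  w <- w + sc(creatinine, function(v) {
    cut <- if (sex == "male") 170 else 150
    if (v < cut) 0 else 1
  })
  w
}

# O(n^2) pairwise concordance oracle for the c-statistic
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == TRUE]
  neg <- scores[!(labels == 1 | labels == TRUE)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random complete vitals rows spanning all bands
random_vitals <- function(n) {
  tibble::tibble(
    admission_id = sprintf("r%04d", seq_len(n)),
    obs_time = ts("2023-03-01 10:00") + seq_len(n) * 60,
    heart_rate = runif(n, 20, 200),
    systolic_bp = runif(n, 50, 260),
    respiratory_rate = runif(n, 4, 40),
    temperature = round(runif(n, 33, 41), 1),
    spo2 = runif(n, 80, 100),
    supplemental_oxygen = runif(n) < 0.3,
    avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE),
    gcs = NA_real_
  )
}

random_lab_values <- function(n) {
  tibble::tibble(
    albumin = runif(n, 10, 50),
    creatinine = runif(n, 30, 400),
    haemoglobin = runif(n, 50, 180),
    potassium = runif(n, 2, 7),
    sodium = runif(n, 115, 160),
    urea = runif(n, 1, 45),
    wcc = runif(n, 0.5, 30),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}
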