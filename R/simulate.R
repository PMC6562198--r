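#' Synthetic cohort generator settings
#'
#' Defaults emulate an emergency medical admissions cohort: age centred
#' near a median of 73 years, roughly even sex ratio, right-skewed length
#' of stay with median about 3.7 days, vital-sign sets every ~6 h
#' (lognormal intervals), laboratory panels roughly daily with declining
#' probability over the stay, and adverse-event rates targeting about 4.8%
#' in-hospital mortality and 1.1% unanticipated ICU admission. A latent
#' per-admission severity random walk (reflected into `[0, 1]`) shifts
#' vital signs into higher-weight NEWS bands and laboratory values into
#' higher-weight LDT-EWS bands ahead of events.
#'
#' With `planted_beta = NULL` (the default) the per-observation event
#' hazard is a logistic function of the normalised NEWS aggregate alone.
#' With `planted_beta` set, the hazard is a logistic function of the
#' combined risk index computed with that coefficient through the
#' package's own linkage, scoring and decay-weight code, enabling
#' parameter-recovery experiments with [fit_beta()].
#'
#' The logistic intercept and slope were calibrated once, by pilot
#' simulation under these defaults, to land the admission-level event
#' rates near their targets; they are ordinary config fields.
#'
#' @param age_meanlog,age_sdlog,age_range Lognormal adult age model
#'   (years), truncated to `age_range`.
#' @param prop_child Fraction of admissions aged under 16 (exercises the
#'   age inclusion criterion).
#' @param prop_male Fraction male.
#' @param prop_elective Fraction with elective admission method.
#' @param prop_other_specialty Fraction admitted under a non-qualifying
#'   specialty.
#' @param qualifying_specialty,other_specialty Specialty codes used.
#' @param los_meanlog,los_sdlog,los_range_hours Lognormal length-of-stay
#'   model in hours, truncated to `los_range_hours`.
#' @param vitals_interval_meanlog,vitals_interval_sdlog,vitals_interval_range
#'   Lognormal inter-observation interval model in hours.
#' @param severity_start_range,severity_step_sd Latent severity walks:
#'   uniform start and Gaussian step SD per observation epoch, reflected
#'   into `[0, 1]`. Each admission carries two correlated severity
#'   components: one read by the vital signs and one by the laboratory
#'   channel (organ dysfunction seen in bloods is not the same thing as
#'   haemodynamic derangement).
#' @param lab_severity_mix Weight of the vitals severity component inside
#'   the laboratory severity: `s_lab = mix * s_vitals + (1 - mix) *
#'   s_own`, so 1 collapses the two channels onto one latent dimension
#'   and 0 makes them independent.
#' @param lab_panel_prob_day1 Probability of a laboratory panel on the day
#'   of admission.
#' @param lab_panel_decay Daily multiplicative decline of the panel
#'   probability.
#' @param lab_prearrival_prob Probability of a panel received 1--10 h
#'   before the admission time (emergency-department bloods).
#' @param analyte_missing_prob Per-analyte dropout within a panel.
#' @param gcs_record_prob Fraction of observation sets recording
#'   consciousness as a GCS total rather than an AVPU level.
#' @param vitals_noise_scale,lab_noise_scale Multipliers on the
#'   measurement-noise SDs of the vital-sign and laboratory channels.
#' @param event_intercept,event_intercept_planted,event_slope Logistic
#'   hazard coefficients on the risk driver. The two drivers live on
#'   different scales (the combined index down-weights its terms relative
#'   to NEWS/20), so each mode carries its own intercept, both calibrated
#'   by pilot simulation to the same cohort event-rate targets:
#'   `event_intercept` applies when the driver is normalised NEWS,
#'   `event_intercept_planted` when it is the planted-coefficient index.
#' @param event_death_frac Fraction of events that are deaths (the rest
#'   are unanticipated ICU admissions).
#' @param event_lag_range Uniform range (hours, within the 24 h outcome
#'   window) between the observation whose hazard draw fires and the
#'   placed event time.
#' @param planted_beta Optional decay coefficient in (0, 1) for the
#'   planted-coefficient mode.
#' @param horizon_hours Carry-forward/decay horizon.
#' @param start Calendar origin; admissions are spread uniformly over the
#'   following year.
#' @return A list of class `ldtnews_generator_config`.
#' @export
generator_config <- function(age_meanlog = log(72), age_sdlog = 0.28,
                             age_range = c(16, 105),
                             prop_child = 0.02, prop_male = 0.49,
                             prop_elective = 0.08,
                             prop_other_specialty = 0.05,
                             qualifying_specialty = "acute_medicine",
                             other_specialty = "general_surgery",
                             los_meanlog = log(3.7 * 24), los_sdlog = 1.2,
                             los_range_hours = c(2, 1440),
                             vitals_interval_meanlog = log(6),
                             vitals_interval_sdlog = 0.45,
                             vitals_interval_range = c(0.5, 48),
                             severity_start_range = c(0.05, 0.55),
                             severity_step_sd = 0.02,
                             lab_severity_mix = 0.15,
                             lab_panel_prob_day1 = 0.9,
                             lab_panel_decay = 0.75,
                             lab_prearrival_prob = 0.35,
                             analyte_missing_prob = 0.08,
                             gcs_record_prob = 0.2,
                             vitals_noise_scale = 1,
                             lab_noise_scale = 1,
                             event_intercept = -15.4,
                             event_intercept_planted = -14.6,
                             event_slope = 22,
                             event_death_frac = 0.81,
                             event_lag_range = c(0.5, 24),
                             planted_beta = NULL,
                             horizon_hours = 120,
                             start = as.POSIXct("2023-01-01 00:00:00",
                                                tz = "UTC")) {
  cfg <- as.list(environment())
  stopifnot(is.null(cfg$planted_beta) ||
              (cfg$planted_beta > 0 && cfg$planted_beta < 1))
  probs <- c(prop_child, prop_male, prop_elective, prop_other_specialty,
             lab_panel_prob_day1, lab_panel_decay, lab_prearrival_prob,
             analyte_missing_prob, gcs_record_prob, event_death_frac)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(cfg, class = "ldtnews_generator_config")
}

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, tz = "UTC",
             origin = "1970-01-01")
}

# fold a real number into [0, 1] by reflection at both boundaries
reflect01 <- function(x) {
  r <- x %% 2
  ifelse(r > 1, 2 - r, r)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stationary AR(1) noise: persistent measurement context (observer, device,
# therapy) rather than independent per-observation error
ar1_noise <- function(n, sd, phi = 0.9) {
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  }
  x
}

# one admission's demographics, vitals and labs (no events yet); runs
# inside an isolated RNG state
simulate_admission_structure <- function(i, cfg) {
  id <- sprintf("adm%05d", i)
  child <- runif(1) < cfg$prop_child
  age <- if (child) {
    sample(1:15, 1)
  } else {
    clamp(round(rlnorm(1, cfg$age_meanlog, cfg$age_sdlog)),
          cfg$age_range[1], cfg$age_range[2])
  }
  sex <- if (runif(1) < cfg$prop_male) "male" else "female"
  method <- if (runif(1) < cfg$prop_elective) "elective" else "emergency"
  specialty <- if (runif(1) < cfg$prop_other_specialty) {
    cfg$other_specialty
  } else {
    cfg$qualifying_specialty
  }
  admit <- round_minute(cfg$start + runif(1, 0, 365 * 86400))
  los <- clamp(rlnorm(1, cfg$los_meanlog, cfg$los_sdlog),
               cfg$los_range_hours[1], cfg$los_range_hours[2])
  discharge <- round_minute(admit + los * 3600)

  # observation epochs: first within an hour of arrival, then lognormal
  # gaps until discharge (capped for pathological draws)
  t <- as.numeric(admit) + runif(1, 0, 1) * 3600
  times <- numeric(0)
  while (t < as.numeric(discharge) && length(times) < 400) {
    times <- c(times, t)
    gap <- clamp(rlnorm(1, cfg$vitals_interval_meanlog,
                        cfg$vitals_interval_sdlog),
                 cfg$vitals_interval_range[1], cfg$vitals_interval_range[2])
    t <- t + gap * 3600
  }
  if (length(times) == 0) times <- as.numeric(admit) + 600
  obs_time <- round_minute(as.POSIXct(times, tz = "UTC",
                                      origin = "1970-01-01"))
  n <- length(obs_time)

  walk <- function() {
    reflect01(cumsum(c(runif(1, cfg$severity_start_range[1],
                             cfg$severity_start_range[2]),
                       rnorm(n - 1, 0, cfg$severity_step_sd))))
  }
  sev <- walk()
  sev_lab <- cfg$lab_severity_mix * sev + (1 - cfg$lab_severity_mix) * walk()

  tdir <- sample(c(1, -1), 1, prob = c(0.8, 0.2))
  ndir <- sample(c(1, -1), 1, prob = c(0.75, 0.25))
  kdir <- sample(c(1, -1), 1)

  avpu_cut <- sev + rnorm(1, 0, 0.04) + ar1_noise(n, 0.03)
  avpu <- cut(avpu_cut, c(-Inf, 0.55, 0.75, 0.9, Inf),
              labels = c("A", "V", "P", "U"))
  avpu <- as.character(avpu)
  as_gcs <- runif(n) < cfg$gcs_record_prob
  gcs <- rep(NA_real_, n)
  gcs_rng <- list(A = 15L, V = 13:14, P = 9:12, U = 3:8)
  for (j in which(as_gcs)) {
    rng <- gcs_rng[[avpu[j]]]
    gcs[j] <- if (length(rng) == 1) rng else sample(rng, 1)
  }

  vn <- cfg$vitals_noise_scale
  vitals <- list(
    admission_id = rep(id, n),
    obs_time = as.numeric(obs_time),
    heart_rate = round(clamp(72 + 55 * sev + ar1_noise(n, 7 * vn), 25, 220)),
    systolic_bp = round(clamp(128 - 50 * sev + ar1_noise(n, 9 * vn),
                              50, 230)),
    respiratory_rate = round(clamp(15 + 14 * sev + ar1_noise(n, 2 * vn),
                                   6, 50)),
    temperature = round(clamp(36.8 + 1.4 * tdir * sev +
                                ar1_noise(n, 0.3 * vn), 33, 41), 1),
    spo2 = round(clamp(97.5 - 9 * sev + ar1_noise(n, 1.2 * vn), 70, 100)),
    # one latent propensity per admission: oxygen therapy switches with
    # severity rather than flickering between observations
    supplemental_oxygen = runif(1) < plogis(-3.5 + 6 * sev),
    avpu = avpu,
    gcs = gcs
  )

  # laboratory panels: optional pre-arrival bloods, then daily draws with
  # declining probability; severity at the panel time sets the derangement
  panel_times <- numeric(0)
  if (runif(1) < cfg$lab_prearrival_prob) {
    panel_times <- c(panel_times, as.numeric(admit) - runif(1, 1, 10) * 3600)
  }
  n_days <- floor(as.numeric(difftime(discharge, admit, units = "days")))
  for (d in 0:n_days) {
    p_d <- cfg$lab_panel_prob_day1 * cfg$lab_panel_decay^d
    if (runif(1) < p_d) {
      pt <- if (d == 0) {
        as.numeric(admit) + runif(1, 0.5, 6) * 3600
      } else {
        as.numeric(floor_date(admit, "day")) + d * 86400 +
          (6 + runif(1, 0, 4)) * 3600
      }
      if (pt <= as.numeric(discharge)) panel_times <- c(panel_times, pt)
    }
  }
  labs <- NULL
  if (length(panel_times) > 0) {
    panel_times <- sort(panel_times)
    sevL <- if (n >= 2) {
      approx(as.numeric(obs_time), sev_lab, xout = panel_times, rule = 2)$y
    } else {
      rep(sev_lab, length(panel_times))
    }
    np <- length(panel_times)
    s <- sevL
    male <- sex == "male"
    ln <- cfg$lab_noise_scale
    vals <- cbind(
      albumin = round(clamp(42 - 24 * s + rnorm(np, 0, 2 * ln), 8, 55)),
      creatinine = round(clamp((if (male) 90 else 70) +
                                 300 * s^1.5 + rnorm(np, 0, 10 * ln),
                               20, 900)),
      haemoglobin = round(clamp((if (male) 145 else 128) -
                                  60 * s + rnorm(np, 0, 6 * ln), 40, 200)),
      potassium = round(clamp(4.0 + 2.2 * kdir * s + rnorm(np, 0, 0.2 * ln),
                              1.8, 8.5), 1),
      sodium = round(clamp(140 - 16 * ndir * s + rnorm(np, 0, 1.8 * ln),
                           110, 165)),
      urea = round(clamp(3.5 + 40 * s^1.5 + rnorm(np, 0, 1 * ln), 0.8, 60),
                   1),
      wcc = round(clamp(7 + 22 * s^1.3 + rnorm(np, 0, 1.5 * ln), 0.3, 80),
                  1)
    )
    present <- matrix(runif(7 * np) >= cfg$analyte_missing_prob,
                      nrow = np, byrow = TRUE)
    if (any(present)) {
      panel_of <- rep(seq_len(np), times = rowSums(present))
      an_idx <- unlist(apply(present, 1, which, simplify = FALSE))
      labs <- list(
        admission_id = rep(id, length(panel_of)),
        received_time = round(panel_times[panel_of] / 60) * 60,
        analyte = colnames(vals)[an_idx],
        value = unname(vals[cbind(panel_of, an_idx)])
      )
    }
  }
  if (is.null(labs)) {
    labs <- list(admission_id = character(), received_time = numeric(),
                 analyte = character(), value = numeric())
  }

  admission <- list(
    admission_id = id, age = as.integer(age), sex = sex,
    admit_time = as.numeric(admit), discharge_time = as.numeric(discharge),
    admission_method = method, specialty = specialty
  )
  list(admission = admission, vitals = vitals, labs = labs, severity = sev)
}

#' Simulate a synthetic admissions cohort
#'
#' Generates the three standard tables (admissions, vital-sign sets,
#' laboratory results) plus a ground-truth table, deterministically under
#' `seed`. Randomness is organised as one master stream split by admission
#' index, so increasing `n_admissions` leaves earlier admissions unchanged.
#' See [generator_config()] for the data-generating model, including the
#' planted-coefficient mode.
#'
#' @param n_admissions Number of admissions to generate.
#' @param seed Integer seed.
#' @param config A [generator_config()].
#' @param scoring_table Scoring table used to drive the event hazard (and,
#'   in planted mode, the risk index).
#' @return A list with tibbles `admissions`, `vitals`, `labs` and `truth`
#'   (`admission_id`, `obs_time`, `severity`, `risk_driver`, `p_event`),
#'   plus the `config` used.
#' @export
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' nrow(cohort$admissions)
simulate_cohort <- function(n_admissions, seed,
                            config = generator_config(),
                            scoring_table = default_scoring_table()) {
  stopifnot(n_admissions >= 1)
  cfg <- config
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max,
                                       2 * n_admissions))
  s_structure <- seeds[seq(1, 2 * n_admissions, by = 2)]
  s_events <- seeds[seq(2, 2 * n_admissions, by = 2)]

  parts <- vector("list", n_admissions)
  for (i in seq_len(n_admissions)) {
    parts[[i]] <- withr::with_seed(s_structure[i],
                                   simulate_admission_structure(i, cfg))
  }
  gather <- function(section, field) {
    unlist(lapply(parts, function(p) p[[section]][[field]]),
           use.names = FALSE)
  }
  as_time <- function(x) .POSIXct(x, tz = "UTC")
  admissions <- tibble(
    admission_id = gather("admission", "admission_id"),
    age = gather("admission", "age"),
    sex = gather("admission", "sex"),
    admit_time = as_time(gather("admission", "admit_time")),
    discharge_time = as_time(gather("admission", "discharge_time")),
    admission_method = gather("admission", "admission_method"),
    specialty = gather("admission", "specialty"),
    death_in_hospital = FALSE,
    death_time = as_time(rep(NA_real_, n_admissions)),
    icu_admission_time = as_time(rep(NA_real_, n_admissions))
  )
  vitals <- tibble(
    admission_id = gather("vitals", "admission_id"),
    obs_time = as_time(gather("vitals", "obs_time")),
    heart_rate = gather("vitals", "heart_rate"),
    systolic_bp = gather("vitals", "systolic_bp"),
    respiratory_rate = gather("vitals", "respiratory_rate"),
    temperature = gather("vitals", "temperature"),
    spo2 = gather("vitals", "spo2"),
    supplemental_oxygen = gather("vitals", "supplemental_oxygen"),
    avpu = gather("vitals", "avpu"),
    gcs = gather("vitals", "gcs")
  )
  labs <- tibble(
    admission_id = gather("labs", "admission_id"),
    received_time = as_time(gather("labs", "received_time")),
    analyte = gather("labs", "analyte"),
    value = gather("labs", "value")
  )
  severity <- unlist(lapply(parts, `[[`, "severity"), use.names = FALSE)

  # risk driver per observation: normalised NEWS, or in planted mode the
  # combined index computed through the package's own linkage and decay
  if (is.null(cfg$planted_beta)) {
    driver <- score_news(vitals, table = scoring_table)$news / 20
  } else {
    linked <- link_labs(vitals, labs, admissions = admissions,
                        horizon_hours = cfg$horizon_hours)
    scored <- score_ldtews(score_news(linked, table = scoring_table),
                           admissions = admissions, table = scoring_table)
    scored <- add_risk_index(scored, beta = cfg$planted_beta,
                             horizon_hours = cfg$horizon_hours)
    driver <- scored$risk_index
  }
  intercept <- if (is.null(cfg$planted_beta)) {
    cfg$event_intercept
  } else {
    cfg$event_intercept_planted
  }
  p_event <- plogis(intercept + cfg$event_slope * driver)

  truth <- tibble(admission_id = vitals$admission_id,
                  obs_time = vitals$obs_time,
                  severity = severity,
                  risk_driver = driver, p_event = p_event)

  # event pass: per admission, the first observation whose draw fires
  # places an event uniformly in the following 24 h
  idx_by_adm <- split(seq_len(nrow(vitals)), vitals$admission_id)
  keep_vitals <- rep(TRUE, nrow(vitals))
  keep_labs <- rep(TRUE, nrow(labs))
  for (i in seq_len(n_admissions)) {
    id <- admissions$admission_id[i]
    rows <- idx_by_adm[[id]]
    ev <- withr::with_seed(s_events[i], {
      u <- runif(length(rows))
      j <- which(u < p_event[rows])[1]
      if (is.na(j)) {
        NULL
      } else {
        list(j = j,
             death = runif(1) < cfg$event_death_frac,
             lag_h = runif(1, cfg$event_lag_range[1],
                           cfg$event_lag_range[2]),
             icu_extra_h = runif(1, 6, 72))
      }
    })
    if (is.null(ev)) next
    etime <- round_minute(vitals$obs_time[rows[ev$j]] + ev$lag_h * 3600)
    if (ev$death) {
      admissions$death_time[i] <- etime
      admissions$death_in_hospital[i] <- TRUE
      admissions$discharge_time[i] <- etime
      keep_labs[labs$admission_id == id & labs$received_time > etime] <- FALSE
    } else {
      admissions$icu_admission_time[i] <- etime
      admissions$discharge_time[i] <-
        max(admissions$discharge_time[i],
            round_minute(etime + ev$icu_extra_h * 3600))
    }
    keep_vitals[rows][vitals$obs_time[rows] >= etime] <- FALSE
  }
  truth <- truth[keep_vitals, , drop = FALSE]
  vitals <- vitals[keep_vitals, , drop = FALSE]
  labs <- labs[keep_labs, , drop = FALSE]

  list(admissions = admissions, vitals = vitals, labs = labs,
       truth = truth, config = cfg)
}
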