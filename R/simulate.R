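# Synthetic primary-care EHR generator. Emulates the structure of a
# CPRD-style extract: an age-sex stratified patient panel across practices,
# face-to-face GP consultations with durations, coded clinical events and
# prescriptions. Durations follow
#   baseline + sum_f effect_f * flag_f + u_practice + v_patient + eps
# with Normal random intercepts, truncated below at a configurable floor.

#' Default age-sex sampling weights
#'
#' A plausible general-practice age-sex distribution over ten-year bands
#' (finer at the young end), normalised to 1. These are package defaults,
#' not an attempt to reproduce any real registry's distribution; supply
#' your own table to [simulation_config()] to change them.
#'
#' @return data.table with columns age_band, age_min, age_max, sex, weight.
#' @export
default_age_sex_weights <- function() {
  bands <- data.table::data.table(
    age_band = c("0-4", "5-14", "15-24", "25-34", "35-44", "45-54",
                 "55-64", "65-74", "75-84", "85+"),
    age_min = c(0, 5, 15, 25, 35, 45, 55, 65, 75, 85),
    age_max = c(4, 14, 24, 34, 44, 54, 64, 74, 84, 99),
    w = c(0.05, 0.10, 0.11, 0.13, 0.13, 0.14, 0.13, 0.11, 0.07, 0.03))
  out <- data.table::rbindlist(list(
    data.table::copy(bands)[, "sex" := "F"],
    data.table::copy(bands)[, "sex" := "M"]))
  out[, "weight" := out$w / sum(out$w)][, "w" := NULL]
  out[]
}

#' Default per-factor prevalences and duration effects
#'
#' `default_factor_prevalence()` returns the generator's stated-world
#' prevalence for each plantable factor in the registry (per consultation
#' for consultation factors, per patient for patient factors); factors
#' whose trigger is derived from the consultation table itself (e.g. the
#' frequent-attender count) are never planted and get no entry.
#' `default_factor_effects()` returns each registry factor's duration
#' effect in minutes, taken from the final development-cohort model
#' ([development_coefficients()]) where the factor appears there and 0
#' otherwise.
#'
#' @param registry A `codeset_registry`.
#' @return Named numeric vector keyed by factor_id.
#' @export
default_factor_prevalence <- function(registry = measure_codesets()) {
  known <- c(
    c_drug_alcohol = 0.005, c_chronic_pain = 0.04, c_dementia = 0.003,
    c_emergency_admission = 0.002, c_learning_disability = 0.004,
    c_mental_health = 0.10, c_multi_diagnoses = 0.15, c_many_drugs = 0.20,
    c_preventive_tasks = 0.05, c_first_diabetes = 0.003,
    c_homeless = 5e-4, c_safeguarding = 1e-3, c_domestic_violence = 5e-4,
    c_end_of_life = 2e-3, c_first_cancer = 2e-3, c_mus = 2e-4,
    c_urgent_secondary = 3e-4,
    p_drug_alcohol = 0.01, p_chronic_pain = 0.05,
    p_domestic_violence = 0.005, p_homelessness = 0.003,
    p_no_english = 0.01, p_multimorbidity = 0.05,
    p_personality_disorder = 0.005, p_safeguarding = 0.005,
    p_learning_disability = 0.005, p_dementia = 0.008, p_palliative = 0.004,
    p_severe_mental_illness = 0.008, p_paraplegia = 2e-4,
    p_housebound = 0.01, p_mus_year = 3e-4, p_polypharmacy = 0.01)
  ids <- registry_ids(registry)
  plantable <- ids[vapply(registry, function(d) d$source_domain != "consultations",
                          logical(1))]
  out <- ifelse(plantable %in% names(known), known[plantable], 0.01)
  names(out) <- plantable
  out
}

#' @rdname default_factor_prevalence
#' @export
default_factor_effects <- function(registry = measure_codesets()) {
  ref <- rbind(development_coefficients("final", "consultation"),
               development_coefficients("final", "patient"))
  ids <- registry_ids(registry)
  out <- rep(0, length(ids)); names(out) <- ids
  hit <- match(ids, ref$factor_id)
  out[!is.na(hit)] <- ref$estimate[hit[!is.na(hit)]]
  out
}

#' Simulation configuration
#'
#' Assembles and validates the stated world for [simulate_dataset()]. The
#' duration model defaults to the development cohort's final-model
#' coefficients (baseline mean duration 9.78 minutes plus the retained
#' factor effects), with practice/patient/residual SDs of 0.5/1.0/3.0
#' minutes.
#'
#' @param n_practices Number of practices.
#' @param patients_per_practice Patients registered per practice.
#' @param age_sex_weights Table as in [default_age_sex_weights()].
#' @param consult_rate_per_year Expected face-to-face GP consultations per
#'   patient per year (counts are Poisson).
#' @param registry `codeset_registry` defining the factors to plant.
#' @param factor_prevalence Named probability per plantable factor; per
#'   consultation for consultation factors, per patient (carrier status)
#'   for patient factors.
#' @param duration_baseline_minutes Baseline mean duration, minutes.
#' @param factor_effects_minutes Named effect (minutes) per factor; must be
#'   a subset of `names(factor_prevalence)` or registry factors with
#'   consultation-table triggers.
#' @param sd_practice,sd_patient,sd_residual Random-intercept and residual
#'   SDs, minutes.
#' @param study_start,study_end Study window (coerced with `as.Date`).
#' @param duration_floor Lower truncation for simulated durations, minutes.
#' @param duration_cap Optional upper cap, minutes (default none).
#' @param background_event_rate Poisson mean of administrative noise codes
#'   (chapter `Z`, matching no code set) per consultation.
#' @param patient_offset Optional fixed offset (days) at which patient-
#'   factor history events are planted before the patient's first
#'   consultation; default draws uniformly inside the factor's lookback
#'   window.
#' @param seed Integer seed; identical configs give identical datasets.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_practices = 50,
                              patients_per_practice = 200,
                              age_sex_weights = default_age_sex_weights(),
                              consult_rate_per_year = 4,
                              registry = measure_codesets(),
                              factor_prevalence = default_factor_prevalence(registry),
                              duration_baseline_minutes = 9.78,
                              factor_effects_minutes = default_factor_effects(registry),
                              sd_practice = 0.5, sd_patient = 1.0,
                              sd_residual = 3.0,
                              study_start = "2013-04-01",
                              study_end = "2014-03-31",
                              duration_floor = 1.0, duration_cap = NULL,
                              background_event_rate = 0.5,
                              patient_offset = NULL, seed = 1L) {
  age_sex_weights <- data.table::as.data.table(age_sex_weights)
  assert_that(nrow(age_sex_weights) > 0, "empty age_sex_weights")
  assert_that(all(c("age_band", "age_min", "age_max", "sex", "weight") %in%
                    names(age_sex_weights)), "malformed age_sex_weights")
  assert_that(is_prob(age_sex_weights$weight), "age_sex weights must be probabilities")
  nums <- c(consult_rate_per_year, duration_baseline_minutes,
            sd_practice, sd_patient, sd_residual, duration_floor,
            background_event_rate, unlist(factor_prevalence),
            unlist(factor_effects_minutes))
  assert_that(all(is.finite(nums)), "non-finite configuration value")
  assert_that(is_count(n_practices) && n_practices >= 1, "n_practices must be a count >= 1")
  assert_that(is_count(patients_per_practice) && patients_per_practice >= 1,
              "patients_per_practice must be a count >= 1")
  assert_that(consult_rate_per_year > 0, "consult_rate_per_year must be positive")
  assert_that(sd_practice >= 0 && sd_patient >= 0, "SDs must be nonnegative")
  assert_that(sd_residual >= 0, "sd_residual must be nonnegative")
  assert_that(is_prob(unlist(factor_prevalence) %||% numeric()),
              "factor prevalences must lie in [0, 1]")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  assert_that(study_start < study_end, "study_start must precede study_end")
  ids <- registry_ids(registry)
  unknown <- setdiff(names(factor_prevalence), ids)
  assert_that(length(unknown) == 0,
              sprintf("prevalence for factor(s) not in registry: %s",
                      paste(unknown, collapse = ", ")))
  derived <- ids[vapply(registry, function(d) d$source_domain == "consultations",
                        logical(1))]
  bad <- intersect(names(factor_prevalence), derived)
  assert_that(length(bad) == 0,
              sprintf("factor(s) derived from the consultation table cannot be planted: %s",
                      paste(bad, collapse = ", ")))
  bad_eff <- setdiff(names(factor_effects_minutes),
                     union(names(factor_prevalence), derived))
  assert_that(length(bad_eff) == 0,
              sprintf("effect for factor(s) without a prevalence: %s",
                      paste(bad_eff, collapse = ", ")))
  structure(list(
    n_practices = as.integer(n_practices),
    patients_per_practice = as.integer(patients_per_practice),
    age_sex_weights = age_sex_weights,
    consult_rate_per_year = consult_rate_per_year, registry = registry,
    factor_prevalence = factor_prevalence,
    duration_baseline_minutes = duration_baseline_minutes,
    factor_effects_minutes = factor_effects_minutes,
    sd_practice = sd_practice, sd_patient = sd_patient,
    sd_residual = sd_residual, study_start = study_start,
    study_end = study_end, duration_floor = duration_floor,
    duration_cap = duration_cap,
    background_event_rate = background_event_rate,
    patient_offset = patient_offset, seed = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d practices x %d patients, ",
                     "%.1f consultations/patient/year, %d factors, seed %d\n"),
              x$n_practices, x$patients_per_practice, x$consult_rate_per_year,
              length(x$registry), x$seed))
  invisible(x)
}

# distinct codes spanning `k` distinct chapters, if possible
pick_chapter_codes <- function(codes, k) {
  ch <- chapter_of(codes)
  keep <- codes[!duplicated(ch)]
  assert_that(length(keep) >= k, "code set spans too few chapters to plant count rule")
  keep[seq_len(k)]
}

#' Simulate a synthetic primary-care dataset
#'
#' Generates patients, consultations, coded events and prescriptions under
#' the stated world in `config`, plants factor triggers at the configured
#' prevalences, derives the realized per-consultation truth flags from the
#' generated tables with the generator's own recount logic (see
#' [recount_flags()]), and draws durations from the mixed-model equation.
#' All randomness flows from a single seeded stream with a fixed draw
#' order, so identical configs give identical datasets.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_ehr`: `patients`, `consultations`,
#'   `events`, `prescriptions` (data.tables) and `truth` (the config, the
#'   realized flag table, and the per-factor planting draws).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  P <- cfg$n_practices; ppp <- cfg$patients_per_practice
  n_pat <- P * ppp
  reg <- cfg$registry
  window_days <- as.integer(cfg$study_end - cfg$study_start) + 1L
  window_years <- window_days / 365.25
  start_year <- as.integer(format(cfg$study_start, "%Y"))

  # --- draw 1: practice random intercepts
  u_practice <- rnorm(P, 0, cfg$sd_practice)

  # --- draw 2: patient panel
  w <- cfg$age_sex_weights
  stratum <- sample.int(nrow(w), n_pat, replace = TRUE, prob = w$weight)
  age <- w$age_min[stratum] +
    floor(runif(n_pat) * (w$age_max[stratum] - w$age_min[stratum] + 1L))
  patients <- data.table::data.table(
    patient_id = seq_len(n_pat),
    practice_id = rep(seq_len(P), each = ppp),
    sex = w$sex[stratum],
    birth_year = start_year - age,
    reg_start = cfg$study_start - 3650L,
    reg_end = cfg$study_end)

  # --- draw 3: patient random intercepts
  v_patient <- rnorm(n_pat, 0, cfg$sd_patient)

  # --- draw 4: consultations (Poisson counts, uniform dates)
  n_cons_pat <- rpois(n_pat, cfg$consult_rate_per_year * window_years)
  pat_idx <- rep(seq_len(n_pat), n_cons_pat)
  n_cons <- length(pat_idx)
  assert_that(n_cons > 0, "simulation produced no consultations; raise consult_rate_per_year")
  dates <- cfg$study_start + floor(runif(n_cons) * window_days)
  consultations <- data.table::data.table(
    patient_id = pat_idx, date = dates)
  data.table::setorderv(consultations, c("patient_id", "date"))
  consultations[, "consultation_id" := seq_len(n_cons)]
  data.table::setcolorder(consultations,
                          c("consultation_id", "patient_id", "date"))

  events <- list(); rxs <- list(); planted <- list()
  ev_code <- function(cid, pid, date, code)
    data.table::data.table(patient_id = pid, consultation_id = cid,
                           date = date, code = code)

  # --- draw 5: consultation-factor planting (registry order)
  for (id in registry_ids(reg)) {
    d <- reg[[id]]
    if (d$level != "consultation") next
    p <- cfg$factor_prevalence[[id]]
    if (is.null(p) || p <= 0) next
    hit <- which(rbinom(n_cons, 1L, p) == 1L)
    planted[[id]] <- consultations$consultation_id[hit]
    if (length(hit) == 0) next
    cid <- consultations$consultation_id[hit]
    pid <- consultations$patient_id[hit]
    dt <- consultations$date[hit]
    if (d$rule_kind == "code_match") {
      events[[id]] <- ev_code(cid, pid, dt, sample(d$codes, length(hit), replace = TRUE))
    } else if (d$rule_kind == "first_consult_after_dx") {
      # diagnosis coded in the consultation itself: same-day counts as first
      events[[id]] <- ev_code(cid, pid, dt, sample(d$codes, length(hit), replace = TRUE))
    } else if (d$rule_kind == "count_rule" && d$source_domain == "events") {
      k <- d$count_threshold
      codes <- if (identical(d$count_unit, "chapters"))
        pick_chapter_codes(d$codes, k) else {
          assert_that(length(d$codes) >= k,
                      sprintf("%s: fewer codes than count_threshold", id))
          d$codes[seq_len(k)]
        }
      events[[id]] <- ev_code(rep(cid, each = k), rep(pid, each = k),
                              rep(dt, each = k), rep(codes, times = length(hit)))
    } else if (d$rule_kind == "count_rule" && d$source_domain == "prescriptions") {
      k <- d$count_threshold
      subs <- paste0("SUB", sprintf("%03d", seq_len(max(k, 20L))))
      drawn <- replicate(length(hit), sample(subs, k))
      rxs[[id]] <- data.table::data.table(
        patient_id = rep(pid, each = k), consultation_id = rep(cid, each = k),
        date = rep(dt, each = k), substance_id = as.vector(drawn))
    }
  }

  # --- draw 6: patient-factor planting (history events before first consultation)
  first_cons <- consultations[, list(anchor = min(date)), by = "patient_id"]
  for (id in registry_ids(reg)) {
    d <- reg[[id]]
    if (d$level != "patient") next
    p <- cfg$factor_prevalence[[id]]
    if (is.null(p) || p <= 0) next
    carrier <- which(rbinom(n_pat, 1L, p) == 1L)
    carrier <- intersect(carrier, first_cons$patient_id)
    planted[[id]] <- carrier
    if (length(carrier) == 0) next
    anchor <- first_cons$anchor[match(carrier, first_cons$patient_id)]
    span <- if (is.infinite(d$lookback)) 3650 else d$lookback
    offset <- if (!is.null(cfg$patient_offset))
      rep(min(cfg$patient_offset, span - 1), length(carrier))
    else floor(runif(length(carrier)) * span)
    if (d$rule_kind == "code_match") {
      events[[paste0("hx_", id)]] <- ev_code(
        NA_integer_, carrier, anchor - offset,
        sample(d$codes, length(carrier), replace = TRUE))
    } else if (d$rule_kind == "count_rule" && d$source_domain == "events") {
      k <- d$count_threshold
      grp_codes <- d$codes[!duplicated(d$code_groups)]
      assert_that(length(grp_codes) >= k,
                  sprintf("%s: fewer code groups than count_threshold", id))
      events[[paste0("hx_", id)]] <- ev_code(
        NA_integer_, rep(carrier, each = k),
        rep(anchor, each = k) - rep(offset, each = k),
        rep(grp_codes[seq_len(k)], times = length(carrier)))
    } else if (d$rule_kind == "count_rule" && d$source_domain == "prescriptions") {
      k <- d$count_threshold
      off_rx <- pmin(offset, if (is.infinite(d$lookback)) offset else d$lookback - 1)
      subs <- paste0("HXS", sprintf("%03d", seq_len(k)))
      rxs[[paste0("hx_", id)]] <- data.table::data.table(
        patient_id = rep(carrier, each = k), consultation_id = NA_integer_,
        date = rep(anchor, each = k) - rep(off_rx, each = k),
        substance_id = rep(subs, times = length(carrier)))
    }
  }

  # --- draw 7: background administrative codes (chapter Z, match nothing)
  if (cfg$background_event_rate > 0) {
    nbg <- rpois(n_cons, cfg$background_event_rate)
    take <- rep(seq_len(n_cons), nbg)
    if (length(take)) {
      events[["background"]] <- ev_code(
        consultations$consultation_id[take], consultations$patient_id[take],
        consultations$date[take],
        paste0("Z", sprintf("%02d", sample.int(20L, length(take), replace = TRUE)), ".."))
    }
  }

  events <- if (length(events)) data.table::rbindlist(events) else
    data.table::data.table(patient_id = integer(), consultation_id = integer(),
                           date = as.Date(character()), code = character())
  data.table::setorderv(events, c("patient_id", "date", "code"))
  events[, "event_id" := seq_len(nrow(events))]
  data.table::setcolorder(events, c("event_id", "patient_id", "consultation_id",
                                    "date", "code"))
  prescriptions <- if (length(rxs)) data.table::rbindlist(rxs) else
    data.table::data.table(patient_id = integer(), consultation_id = integer(),
                           date = as.Date(character()), substance_id = character())
  data.table::setorderv(prescriptions, c("patient_id", "date", "substance_id"))
  prescriptions[, "rx_id" := seq_len(nrow(prescriptions))]
  data.table::setcolorder(prescriptions, c("rx_id", "patient_id", "consultation_id",
                                           "date", "substance_id"))

  dataset <- structure(list(patients = patients, consultations = consultations,
                            events = events, prescriptions = prescriptions,
                            truth = list(config = cfg, planted = planted)),
                       class = "synthetic_ehr")

  # realized truth flags, recounted from the generated tables
  flags <- recount_flags(dataset, reg)
  dataset$truth$flags <- flags

  # --- draw 8: residuals and the duration equation
  eff <- rep(0, n_cons)
  for (id in names(cfg$factor_effects_minutes)) {
    b <- cfg$factor_effects_minutes[[id]]
    if (b != 0 && id %in% names(flags)) eff <- eff + b * flags[[id]]
  }
  y <- cfg$duration_baseline_minutes + eff +
    u_practice[patients$practice_id[consultations$patient_id]] +
    v_patient[consultations$patient_id] +
    rnorm(n_cons, 0, cfg$sd_residual)
  y <- pmax(y, cfg$duration_floor)
  if (!is.null(cfg$duration_cap)) y <- pmin(y, cfg$duration_cap)
  dataset$consultations[, "duration_minutes" := y]
  dataset
}

#' @export
print.synthetic_ehr <- function(x, ...) {
  cat(sprintf(paste0("synthetic_ehr: %d patients in %d practices, ",
                     "%d consultations, %d events, %d prescriptions\n"),
              nrow(x$patients), data.table::uniqueN(x$patients$practice_id),
              nrow(x$consultations), nrow(x$events), nrow(x$prescriptions)))
  invisible(x)
}

#' Write a synthetic dataset to CSV
#'
#' Writes `patients.csv`, `consultations.csv`, `events.csv`,
#' `prescriptions.csv` (RFC-4180, ISO-8601 dates) into `dir`.
#'
#' @param dataset A `synthetic_ehr`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "consultations", "events", "prescriptions"))
    data.table::fwrite(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
                       dateTimeAs = "ISO")
  invisible(dir)
}

#' Read a dataset from CSV
#'
#' Inverse of [write_dataset()]; the `truth` element is not round-tripped.
#'
#' @param dir Directory containing the four CSV tables.
#' @return A `synthetic_ehr` (without `truth`).
#' @export
read_dataset <- function(dir) {
  rd <- function(nm) {
    dt <- data.table::fread(file.path(dir, paste0(nm, ".csv")))
    for (col in intersect(c("date", "reg_start", "reg_end"), names(dt)))
      data.table::set(dt, j = col, value = as.Date(dt[[col]]))
    dt
  }
  structure(list(patients = rd("patients"), consultations = rd("consultations"),
                 events = rd("events"), prescriptions = rd("prescriptions"),
                 truth = NULL),
            class = "synthetic_ehr")
}

#' Simulate Delphi panel vote tables
#'
#' Builds a vote table whose per-factor classification under the default
#' thresholds is controlled: `clear_endorse` factors are guaranteed
#' endorsed (at most 10% of scores are 1 and at most 10% are 2, the rest
#' drawn from 3-5), `clear_reject` factors are guaranteed rejected (at
#' least half the scores are 1, the rest 2), and `borderline` factors draw
#' each panelist's score i.i.d. from `borderline_probs` over 1..5 (default
#' endorsement probability 0.70, rejection probability 0.15, sitting on the
#' acceptance thresholds so the classification straddles them).
#'
#' @param n_panelists Panel size (>= 1).
#' @param factor_truth Named character vector factor_id -> category in
#'   `{"clear_endorse","clear_reject","borderline"}`.
#' @param seed Integer seed.
#' @param round Round number recorded in the table.
#' @param borderline_probs Probabilities of scores 1..5 for borderline
#'   factors.
#' @return data.table with columns round, panelist_id, factor_id, score.
#' @export
simulate_votes <- function(n_panelists, factor_truth, seed = 1L, round = 1L,
                           borderline_probs = c(0.15, 0.15, 0.40, 0.20, 0.10)) {
  assert_that(is_count(n_panelists) && n_panelists >= 1, "n_panelists must be >= 1")
  cats <- c("clear_endorse", "clear_reject", "borderline")
  bad <- setdiff(unique(factor_truth), cats)
  assert_that(length(bad) == 0,
              sprintf("unknown category: %s", paste(bad, collapse = ", ")))
  assert_that(length(borderline_probs) == 5 && is_prob(borderline_probs) &&
                abs(sum(borderline_probs) - 1) < 1e-8,
              "borderline_probs must be 5 probabilities summing to 1")
  n <- n_panelists
  shuf <- function(x) if (length(x) <= 1L) x else sample(x)  # length-1 safe
  with_seed(seed, {
    out <- lapply(names(factor_truth), function(id) {
      scores <- switch(
        factor_truth[[id]],
        clear_endorse = {
          n1 <- floor(0.1 * n); n2 <- floor(0.1 * n)
          shuf(c(rep(1L, n1), rep(2L, n2),
                 sample(3:5, n - n1 - n2, replace = TRUE)))
        },
        clear_reject = {
          n1 <- ceiling(0.5 * n)
          shuf(c(rep(1L, n1), rep(2L, n - n1)))
        },
        borderline = sample.int(5L, n, replace = TRUE, prob = borderline_probs))
      data.table::data.table(round = as.integer(round),
                             panelist_id = sprintf("gp%03d", seq_len(n)),
                             factor_id = id, score = as.integer(scores))
    })
    data.table::rbindlist(out)
  })
}
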