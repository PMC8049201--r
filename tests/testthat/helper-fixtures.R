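# Hand-built micro-fixtures and shared simulations for the suite.

d0 <- as.Date("2013-06-01")

mk_patients <- function(n = 1, practice = 1L) {
  data.table::data.table(
    patient_id = seq_len(n), practice_id = practice, sex = "F",
    birth_year = 1970L, reg_start = as.Date("2000-01-01"),
    reg_end = as.Date("2020-01-01"))
}

mk_dataset <- function(consultations, events = NULL, prescriptions = NULL,
                       n_patients = max(consultations$patient_id)) {
  empty_ev <- data.table::data.table(
    event_id = integer(), patient_id = integer(), consultation_id = integer(),
    date = as.Date(character()), code = character())
  empty_rx <- data.table::data.table(
    rx_id = integer(), patient_id = integer(), consultation_id = integer(),
    date = as.Date(character()), substance_id = character())
  ev <- if (is.null(events)) empty_ev else {
    events <- data.table::as.data.table(events)
    events[, event_id := .I]
    data.table::setcolorder(events, c("event_id"))
    events
  }
  rx <- if (is.null(prescriptions)) empty_rx else {
    prescriptions <- data.table::as.data.table(prescriptions)
    prescriptions[, rx_id := .I]
    data.table::setcolorder(prescriptions, c("rx_id"))
    prescriptions
  }
  structure(list(patients = mk_patients(n_patients),
                 consultations = data.table::as.data.table(consultations),
                 events = ev, prescriptions = rx, truth = NULL),
            class = "synthetic_ehr")
}

mk_cons <- function(ids, dates, patient = 1L, duration = 10) {
  data.table::data.table(consultation_id = as.integer(ids),
                         patient_id = as.integer(patient),
                         date = as.Date(dates), duration_minutes = duration)
}

mk_ev <- function(patient, consultation, dates, codes) {
  data.table::data.table(patient_id = as.integer(patient),
                         consultation_id = as.integer(consultation),
                         date = as.Date(dates), code = codes)
}

mk_rx <- function(patient, consultation, dates, substances) {
  data.table::data.table(patient_id = as.integer(patient),
                         consultation_id = as.integer(consultation),
                         date = as.Date(dates), substance_id = substances)
}

# assemble ad-hoc registries for targeted tests
registry_of <- function(...) {
  defs <- list(...)
  structure(stats::setNames(defs, vapply(defs, `[[`, "", "factor_id")),
            class = "codeset_registry")
}

mk_votes <- function(scores, factor_id = "f1", round = 1L) {
  data.table::data.table(panelist_id = sprintf("gp%03d", seq_along(scores)),
                         factor_id = factor_id, round = as.integer(round),
                         score = as.integer(scores))
}

# deterministic vote blocks forcing a given classification
votes_for_status <- function(status, factor_id, round, n = 30L) {
  score <- switch(status, endorsed = 4L, rejected = 1L, uncertain = 2L)
  mk_votes(rep(score, n), factor_id = factor_id, round = round)
}

# shared medium simulation, built once per test session
shared_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(shared_env$sim)) {
    cfg <- simulation_config(n_practices = 6, patients_per_practice = 60,
                             consult_rate_per_year = 5, seed = 2024L)
    shared_env$sim <- simulate_dataset(cfg)
  }
  shared_env$sim
}
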