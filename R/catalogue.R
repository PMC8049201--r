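# Reference bookkeeping from the development study of the measure:
# the two-round panel history for all 45 candidate factors, the initial
# multivariable duration-model coefficients (2013/14 development cohort),
# and the final-model coefficients used as simulation truth.

#' Candidate-factor panel history
#'
#' The complete two-round Delphi bookkeeping for the 45 candidate
#' complexity indicators tracked during development of the measure: 14
#' consultation and 19 patient factors put to the panel in round 1, plus 5
#' consultation and 7 patient factors suggested by panelists and introduced
#' in round 2. Per-round statuses and median panel scores are recorded;
#' final statuses follow from [resolve_final_status()].
#'
#' @return data.table with columns factor_id, label, level,
#'   introduced_round, round1_status, round2_status, median_r1, median_r2.
#' @export
delphi_history <- function() {
  E <- "endorsed"; R <- "rejected"; U <- "uncertain"; N <- NA_character_
  tab <- data.table::rbindlist(list(
    # consultation factors, round 1
    list("c_homeless",            "consultation", 1L, E, N, 3.0, NA),
    list("c_safeguarding",        "consultation", 1L, E, N, 4.0, NA),
    list("c_domestic_violence",   "consultation", 1L, E, N, 4.0, NA),
    list("c_learning_disability", "consultation", 1L, E, N, 3.0, NA),
    list("c_end_of_life",         "consultation", 1L, E, N, 3.0, NA),
    list("c_mental_health",       "consultation", 1L, E, N, 4.0, NA),
    list("c_multi_diagnoses",     "consultation", 1L, E, N, 3.0, NA),
    list("c_dementia",            "consultation", 1L, U, E, 3.0, 3.0),
    list("c_drug_alcohol",        "consultation", 1L, U, E, 3.0, 3.5),
    list("c_preventive_tasks",    "consultation", 1L, U, E, 3.0, 3.0),
    list("c_minor_surgery",       "consultation", 1L, U, U, 2.0, 2.0),
    list("c_many_drugs",          "consultation", 1L, U, E, 3.0, 3.0),
    list("c_first_cancer",        "consultation", 1L, U, E, 3.0, 4.0),
    list("c_first_diabetes",      "consultation", 1L, U, E, 3.0, 3.0),
    # consultation factors suggested by panelists, round 2
    list("c_mus",                 "consultation", 2L, N, E, NA, 4.0),
    list("c_outpatient_referral", "consultation", 2L, N, R, NA, 2.0),
    list("c_emergency_admission", "consultation", 2L, N, E, NA, 4.0),
    list("c_urgent_secondary",    "consultation", 2L, N, E, NA, 4.0),
    list("c_chronic_pain",        "consultation", 2L, N, E, NA, 3.0),
    # patient factors, round 1
    list("p_homelessness",        "patient", 1L, E, N, 3.0, NA),
    list("p_safeguarding",        "patient", 1L, E, N, 4.0, NA),
    list("p_domestic_violence",   "patient", 1L, E, N, 3.0, NA),
    list("p_no_english",          "patient", 1L, E, N, 3.0, NA),
    list("p_learning_disability", "patient", 1L, E, N, 3.0, NA),
    list("p_dementia",            "patient", 1L, E, N, 3.0, NA),
    list("p_palliative",          "patient", 1L, E, N, 3.0, NA),
    list("p_drug_alcohol",        "patient", 1L, E, N, 3.5, NA),
    list("p_severe_mental_illness","patient", 1L, E, N, 4.0, NA),
    list("p_wheelchair",          "patient", 1L, R, N, 2.0, NA),
    list("p_outpatient_referral", "patient", 1L, R, N, 2.0, NA),
    list("p_warfarin",            "patient", 1L, R, N, 2.0, NA),
    list("p_cancer_ever",         "patient", 1L, R, N, 2.0, NA),
    list("p_diabetes_ever",       "patient", 1L, R, N, 2.0, NA),
    list("p_multimorbidity",      "patient", 1L, U, E, 2.0, 3.0),
    list("p_deafness",            "patient", 1L, U, U, 2.0, 2.0),
    list("p_paraplegia",          "patient", 1L, U, E, 2.5, 3.0),
    list("p_blind",               "patient", 1L, U, U, 2.0, 2.0),
    list("p_immunosuppressant",   "patient", 1L, U, U, 2.0, 3.0),
    # patient factors suggested by panelists, round 2
    list("p_housebound",          "patient", 2L, N, E, NA, 4.0),
    list("p_personality_disorder","patient", 2L, N, E, NA, 4.0),
    list("p_mus_year",            "patient", 2L, N, E, NA, 3.0),
    list("p_morbid_obesity",      "patient", 2L, N, U, NA, 3.0),
    list("p_frequent_attender",   "patient", 2L, N, E, NA, 3.0),
    list("p_chronic_pain",        "patient", 2L, N, E, NA, 3.0),
    list("p_polypharmacy",        "patient", 2L, N, E, NA, 3.5)))
  data.table::setnames(tab, c("factor_id", "level", "introduced_round",
                              "round1_status", "round2_status",
                              "median_r1", "median_r2"))
  tab[, "final_status" := resolve_final_status(tab$round1_status, tab$round2_status)]
  tab[]
}

#' Reference duration-model coefficients from the development cohort
#'
#' Fixed-effect estimates (change in consultation duration, minutes), 95%
#' CIs and p-values from the development cohort's mixed-effects duration
#' models, as shipped reference bookkeeping. `stage = "initial"` gives the
#' initial multivariable models over all factors entering modelling;
#' `stage = "final"` gives the final models after sign- and
#' significance-based elimination. In the initial patient model, factors
#' excluded for a negative duration association carry their univariable
#' estimates (`from_univariable = TRUE`) since no multivariable estimate
#' exists for them. p-values reported only as "<0.001" are encoded as 5e-4.
#'
#' @param stage `"initial"` or `"final"`.
#' @param level `"consultation"` or `"patient"`.
#' @return data.table: factor_id, estimate, ci_low, ci_high, p_value,
#'   from_univariable; the model intercept (mean duration of consultation,
#'   minutes) is attached as attribute `"intercept"` = c(estimate, ci_low,
#'   ci_high).
#' @export
development_coefficients <- function(stage = c("initial", "final"),
                                     level = c("consultation", "patient")) {
  stage <- match.arg(stage); level <- match.arg(level)
  p_small <- 5e-4  # stands in for "<0.001"
  row <- function(id, est, lo, hi, p, univ = FALSE)
    list(factor_id = id, estimate = est, ci_low = lo, ci_high = hi,
         p_value = p, from_univariable = univ)
  if (level == "consultation") {
    init <- data.table::rbindlist(list(
      row("c_drug_alcohol",        4.19, 3.68, 4.69, p_small),
      row("c_chronic_pain",        0.98, 0.86, 1.10, p_small),
      row("c_dementia",            1.42, 0.90, 1.94, p_small),
      row("c_emergency_admission", 7.76, 7.09, 8.43, p_small),
      row("c_learning_disability", 3.84, 3.17, 4.52, p_small),
      row("c_mental_health",       3.85, 3.70, 3.99, p_small),
      row("c_multi_diagnoses",     2.54, 2.42, 2.67, p_small),
      row("c_many_drugs",          1.73, 1.67, 1.80, p_small),
      row("c_preventive_tasks",    3.73, 3.55, 3.92, p_small),
      row("c_first_cancer",        0.43, -0.11, 0.97, 0.118),
      row("c_first_diabetes",      3.05, 2.48, 3.63, p_small)))
    intercept <- c(9.78, 9.56, 10.00)
    if (stage == "initial") {
      out <- init
    } else {
      out <- init[init$factor_id != "c_first_cancer"]
      out[out$factor_id == "c_first_diabetes", "ci_high" := 3.62]
    }
  } else {
    if (stage == "initial") {
      out <- data.table::rbindlist(list(
        row("p_drug_alcohol",          1.89,  1.44,  2.33, p_small),
        row("p_chronic_pain",          0.73,  0.58,  0.89, p_small),
        row("p_dementia",             -0.78, -1.19, -0.38, p_small, TRUE),
        row("p_domestic_violence",     1.43,  0.37,  2.49, 0.008),
        row("p_frequent_attender",     0.01, -0.17,  0.19, 0.902),
        row("p_homelessness",          1.36,  0.39,  2.33, 0.006),
        row("p_housebound",           -3.72, -4.37, -3.06, p_small, TRUE),
        row("p_no_english",            0.98,  0.25,  1.72, 0.009),
        row("p_learning_disability",   0.06, -0.21,  0.33, 0.654),
        row("p_severe_mental_illness",-0.10, -0.64,  0.44, 0.727),
        row("p_multimorbidity",        0.32,  0.21,  0.43, p_small),
        row("p_palliative",           -0.58, -1.22,  0.05, 0.07, TRUE),
        row("p_personality_disorder",  0.51,  0.12,  0.89, 0.01),
        row("p_polypharmacy",         -0.07, -0.25,  0.11, 0.447),
        row("p_safeguarding",         -0.33, -0.69,  0.04, 0.079, TRUE)))
      intercept <- c(10.02, 9.79, 10.25)
    } else {
      out <- data.table::rbindlist(list(
        row("p_drug_alcohol",          1.89, 1.44, 2.33, p_small),
        row("p_chronic_pain",          0.72, 0.57, 0.87, p_small),
        row("p_domestic_violence",     1.43, 0.37, 2.49, 0.008),
        row("p_homelessness",          1.36, 0.39, 2.33, 0.006),
        row("p_no_english",            0.98, 0.25, 1.72, 0.009),
        row("p_multimorbidity",        0.30, 0.21, 0.40, p_small),
        row("p_personality_disorder",  0.51, 0.12, 0.89, 0.01)))
      intercept <- c(10.02, 9.80, 10.25)
    }
  }
  data.table::setattr(out, "intercept", intercept)
  out[]
}

#' Development-pipeline bookkeeping constants
#'
#' `development_prevalence_exclusions()` names the factors dropped in the
#' development cohort for applying to fewer than 0.05% of consultations or
#' patients. `development_reclassification()` maps the four endorsed
#' consultation factors that were too rare at consultation level onto their
#' patient-level counterparts (with lookback windows in days).
#' `development_overrides()` names the five factors force-retained in the
#' measure despite losing significance (or prevalence) in the later
#' revalidation cohort.
#'
#' @return See each description.
#' @export
development_prevalence_exclusions <- function() {
  c("c_mus", "c_urgent_secondary", "p_paraplegia", "p_mus_year")
}

#' @rdname development_prevalence_exclusions
#' @export
development_reclassification <- function() {
  list(
    c_end_of_life       = list(target = "p_palliative",        lookback = Inf),
    c_homeless          = list(target = "p_homelessness",      lookback = 365),
    c_domestic_violence = list(target = "p_domestic_violence", lookback = 365),
    c_safeguarding      = list(target = "p_safeguarding",      lookback = 1095))
}

#' @rdname development_prevalence_exclusions
#' @export
development_overrides <- function() {
  c("c_dementia", "p_drug_alcohol", "p_homelessness",
    "p_multimorbidity", "p_personality_disorder")
}
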