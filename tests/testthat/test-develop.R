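mini_flags <- function(n_cons, true_ids, factor_ids, patient_ids = seq_len(n_cons)) {
  out <- data.table::data.table(consultation_id = seq_len(n_cons))
  for (f in factor_ids)
    data.table::set(out, j = f, value = out$consultation_id %in% true_ids[[f]])
  out
}

test_that("prevalence screen applies the strict <0.05% rule per level", {
  reg <- registry_of(
    factor_definition("c_rare", "rare", "consultation", "code_match", codes = "X1..."),
    factor_definition("c_edge", "edge", "consultation", "code_match", codes = "X2..."),
    factor_definition("p_ok", "ok", "patient", "code_match", codes = "X3...",
                      lookback = 365))
  n <- 10000L
  cons <- mk_cons(seq_len(n), rep(d0, n), patient = rep(1:100, each = 100))
  ds <- mk_dataset(cons, n_patients = 100)
  flags <- mini_flags(n, list(c_rare = 1:2, c_edge = 1:5, p_ok = 1:200),
                      registry_ids(reg))
  out <- prevalence_screen(flags, ds, reg)
  expect_equal(out$prevalence[out$factor_id == "c_rare"], 2e-4)
  expect_true(out$excluded[out$factor_id == "c_rare"])      # 0.02% < 0.05%
  expect_false(out$excluded[out$factor_id == "c_edge"])     # exactly 0.05% retained
  # patient denominator: consultations 1:200 belong to patients 1:2 of 100
  expect_equal(out$numerator[out$factor_id == "p_ok"], 2)
  expect_equal(out$denominator[out$factor_id == "p_ok"], 100)
  expect_false(out$excluded[out$factor_id == "p_ok"])
})

test_that("prevalence screen is invariant to duplicating every record", {
  reg <- registry_of(
    factor_definition("c_rare", "rare", "consultation", "code_match", codes = "X1..."))
  n <- 4000L
  mk <- function(k) {
    cons <- mk_cons(seq_len(n * k), rep(d0, n * k), patient = rep(seq_len(40 * k), each = 100))
    ds <- mk_dataset(cons, n_patients = 40 * k)
    flags <- mini_flags(n * k, list(c_rare = seq_len(k)), "c_rare")
    prevalence_screen(flags, ds, reg)$excluded
  }
  expect_equal(mk(1), mk(2))
})

test_that("percentile thresholds use the inverse-ECDF convention", {
  expect_equal(specify_percentile_threshold(rep(3L, 50), 0.95), 3L)
  expect_equal(specify_percentile_threshold(1:100, 0.95), 95L)
  # brute-force sort-and-index oracle on random data
  set.seed(41)
  for (i in 1:10) {
    x <- rpois(500, 6)
    s <- sort(x)
    oracle <- s[ceiling(0.95 * length(s))]
    expect_equal(specify_percentile_threshold(x, 0.95), oracle)
  }
  # consultation counts whose empirical 95th centile is 14 -> threshold 14
  counts <- c(rep(2L, 940), rep(14L, 40), rep(20L, 20))
  expect_equal(specify_percentile_threshold(counts, 0.95), 14L)
  expect_error(specify_percentile_threshold(integer()), "empty")
})

test_that("reclassification moves consultation factors to patient level", {
  reg <- candidate_codesets()
  expect_identical(reclassify_low_prevalence(reg, list()), reg)

  kept <- setdiff(registry_ids(reg), development_prevalence_exclusions())
  reg2 <- registry_subset(reg, kept)
  reg3 <- reclassify_low_prevalence(reg2, development_reclassification())
  lv <- registry_levels(reg3)
  # 17 endorsed consultation factors - 2 low-prevalence - 4 reclassified = 11
  expect_equal(sum(lv == "consultation"), 11)
  expect_equal(sum(lv == "patient"), 15)
  expect_false("c_end_of_life" %in% registry_ids(reg3))
  # codes merged into the patient-level target
  expect_true(all(reg[["c_end_of_life"]]$codes %in% reg3[["p_palliative"]]$codes))

  expect_error(reclassify_low_prevalence(reg, list(
    nope = list(target = "p_palliative", lookback = Inf))), "unknown factor")
  expect_error(reclassify_low_prevalence(reg, list(
    c_end_of_life = list(target = "p_palliative", lookback = 365))),
    "window conflict")
})

test_that("with zero random-effect variances the mixed fit matches OLS", {
  reg <- registry_subset(measure_codesets(),
                         c("c_mental_health", "c_many_drugs"))
  prev <- c(c_mental_health = 0.3, c_many_drugs = 0.3)
  cfg <- simulation_config(n_practices = 4, patients_per_practice = 40,
                           registry = reg, factor_prevalence = as.list(prev),
                           factor_effects_minutes = list(c_mental_health = 3.85,
                                                         c_many_drugs = 1.73),
                           sd_practice = 0, sd_patient = 0, sd_residual = 2,
                           background_event_rate = 0, seed = 51L)
  ds <- simulate_dataset(cfg)
  flags <- compute_flags(ds, reg)
  fit <- fit_duration_model(ds, flags, registry_ids(reg))
  df <- merge(flags, ds$consultations, by = "consultation_id")
  ols <- lm(duration_minutes ~ c_mental_health + c_many_drugs, data = df)
  expect_equal(unname(fit$intercept["estimate"]), unname(coef(ols)[1]),
               tolerance = 1e-3)
  expect_equal(fit$terms$estimate, unname(coef(ols)[2:3]), tolerance = 1e-3)
})

test_that("null effects give ~nominal CI coverage across replicates", {
  reg <- registry_subset(measure_codesets(), c("c_mental_health", "c_chronic_pain"))
  prev <- c(c_mental_health = 0.2, c_chronic_pain = 0.2)
  n_rep <- 20
  covered <- matrix(NA, n_rep, 2)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(
      n_practices = 10, patients_per_practice = 60, consult_rate_per_year = 4,
      registry = reg, factor_prevalence = as.list(prev),
      factor_effects_minutes = list(c_mental_health = 0, c_chronic_pain = 0),
      sd_practice = 0.5, sd_patient = 1, sd_residual = 3,
      background_event_rate = 0, seed = 600L + r)
    ds <- simulate_dataset(cfg)
    fit <- fit_duration_model(ds, compute_flags(ds, reg), registry_ids(reg))
    covered[r, ] <- fit$terms$ci_low <= 0 & 0 <= fit$terms$ci_high
  }
  expect_gte(mean(covered), 0.90)
})

test_that("univariable mode fits one factor at a time", {
  ds <- shared_sim()
  reg <- registry_subset(measure_codesets(), c("c_mental_health", "c_many_drugs"))
  flags <- compute_flags(ds, reg)
  uni <- fit_duration_model(ds, flags, registry_ids(reg), mode = "univariable")
  expect_equal(uni$terms$factor_id, c("c_mental_health", "c_many_drugs"))
  solo <- fit_duration_model(ds, flags, "c_mental_health")
  expect_equal(uni$terms$estimate[1], solo$terms$estimate, tolerance = 1e-10)
})

test_that("degenerate designs error informatively", {
  ds <- shared_sim()
  reg <- registry_of(
    factor_definition("c_never", "never fires", "consultation", "code_match",
                      codes = "QQQQ."))
  flags <- compute_flags(ds, reg)
  expect_error(fit_duration_model(ds, flags, "c_never"), "singular design")
  one_prac <- mk_dataset(mk_cons(1:10, rep(d0, 10), patient = rep(1:5, 2)),
                         n_patients = 5)
  f <- mini_flags(10, list(c_x = 1:3), "c_x")
  expect_error(fit_duration_model(one_prac, f, "c_x"), "at least 2 practices")
})

test_that("prune_terms removes negatives in one pass, then worst p iteratively", {
  terms <- data.table::data.table(
    factor_id = c("a", "b", "c", "d"),
    estimate = c(2.0, -0.5, 1.0, 0.3),
    p_value = c(0.001, 0.001, 0.20, 0.06))
  out <- prune_terms(terms, alpha = 0.05)
  expect_equal(out$retained, "a")
  expect_equal(out$removal_log$factor_id, c("b", "c", "d"))
  expect_equal(out$removal_log$step, c(0L, 1L, 2L))
  expect_equal(out$removal_log$reason,
               c("negative_coefficient", "p_above_alpha", "p_above_alpha"))
  # fixed point: all positive and significant -> unchanged, empty log
  good <- terms[terms$factor_id == "a"]
  out <- prune_terms(good)
  expect_equal(out$retained, "a")
  expect_equal(nrow(out$removal_log), 0)
})

test_that("backward stepwise removes a planted null factor and terminates", {
  reg <- registry_subset(measure_codesets(),
                         c("c_mental_health", "c_emergency_admission", "c_chronic_pain"))
  prev <- c(c_mental_health = 0.15, c_emergency_admission = 0.15,
            c_chronic_pain = 0.15)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(
      n_practices = 8, patients_per_practice = 50, consult_rate_per_year = 4,
      registry = reg, factor_prevalence = as.list(prev),
      factor_effects_minutes = list(c_mental_health = 3.85,
                                    c_emergency_admission = 7.76,
                                    c_chronic_pain = 0),
      sd_practice = 0.5, sd_patient = 1, sd_residual = 3,
      background_event_rate = 0, seed = 700L + r)
    ds <- simulate_dataset(cfg)
    flags <- compute_flags(ds, reg)
    st <- backward_stepwise(ds, flags, registry_ids(reg))
    expect_lte(nrow(st$removal_log), 3)         # terminates within k steps
    expect_true(all(st$final_fit$terms$p_value < 0.05))
    if (identical(sort(st$retained),
                  c("c_emergency_admission", "c_mental_health")) &&
        "c_chronic_pain" %in% st$removal_log$factor_id) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("stepwise on all-significant factors is a fixed point", {
  ds <- shared_sim()
  reg <- registry_subset(measure_codesets(), c("c_mental_health", "c_many_drugs"))
  flags <- compute_flags(ds, reg)
  st <- backward_stepwise(ds, flags, registry_ids(reg))
  expect_setequal(st$retained, c("c_mental_health", "c_many_drugs"))
  expect_equal(nrow(st$removal_log), 0)
  expect_equal(st$final_fit$terms, st$initial_fit$terms)
})

test_that("assemble_measure unions levels, applies overrides, checks ids", {
  out <- assemble_measure(c("c_a", "c_b"), c("p_a"))
  expect_setequal(out, c("c_a", "c_b", "p_a"))
  # override-only path
  out <- assemble_measure(character(), character(), overrides = c("c_x"))
  expect_equal(as.character(out), "c_x")
  expect_equal(attr(out, "overrides"), "c_x")
  expect_error(assemble_measure(c("c_a"), c("c_a")), "both levels")
  expect_error(assemble_measure(character(), character(), overrides = "ghost",
                                registry = measure_codesets()), "unknown factor")
})
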