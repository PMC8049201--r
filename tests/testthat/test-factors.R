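# Micro-fixtures with hand-computed expected flags.

p_dv <- factor_definition("p_dv", "domestic violence, prior year", "patient",
                          "code_match", codes = "14X1.", lookback = 365)
p_dem <- factor_definition("p_dem", "dementia ever", "patient",
                           "code_match", codes = "E00..", lookback = Inf)

test_that("lookback windows are half-open (d - L, d]", {
  cons <- mk_cons(1, d0)
  reg <- registry_of(p_dv)
  flag_at <- function(offset_days) {
    ev <- mk_ev(1, NA, d0 - offset_days, "14X1.")
    flag_patient_factors(mk_dataset(cons, ev), reg)$p_dv
  }
  expect_false(flag_at(400))   # outside the 365-day window
  expect_true(flag_at(364))
  expect_false(flag_at(365))   # exactly L days before is OUTSIDE
  expect_true(flag_at(0))      # event on the consultation date is inside
  expect_false(flag_at(-1))    # no lookahead
})

test_that("'ever' factors reach arbitrarily far back but never forward", {
  cons <- mk_cons(1, d0)
  reg <- registry_of(p_dem)
  ev_old <- mk_ev(1, NA, d0 - 3650, "E00..")   # 10 years before
  expect_true(flag_patient_factors(mk_dataset(cons, ev_old), reg)$p_dem)
  ev_future <- mk_ev(1, NA, d0 + 30, "E00..")
  expect_false(flag_patient_factors(mk_dataset(cons, ev_future), reg)$p_dem)
  # consultation before all history: false, not an error
  expect_false(flag_patient_factors(mk_dataset(cons), reg)$p_dem)
})

test_that("consultation count rules match hand counts", {
  reg <- registry_subset(measure_codesets(),
                         c("c_multi_diagnoses", "c_many_drugs",
                           "c_preventive_tasks", "c_mental_health"))
  cons <- mk_cons(1, d0)
  # zero linked events and prescriptions -> all consultation flags false
  f0 <- flag_consultation_factors(mk_dataset(cons), reg)
  expect_false(any(as.matrix(f0[, -1])))

  # diagnosis codes in chapters {C, D} -> multi-diagnosis true; {C, C} -> false
  two_ch <- mk_ev(1, 1, rep(d0, 2), c("C2...", "D10.."))
  one_ch <- mk_ev(1, 1, rep(d0, 2), c("C2...", "C2..."))
  expect_true(flag_consultation_factors(mk_dataset(cons, two_ch), reg)$c_multi_diagnoses)
  expect_false(flag_consultation_factors(mk_dataset(cons, one_ch), reg)$c_multi_diagnoses)

  # 3 prescriptions of 2 unique substances -> false; a 3rd unique -> true
  rx2 <- mk_rx(1, 1, rep(d0, 3), c("S1", "S1", "S2"))
  rx3 <- mk_rx(1, 1, rep(d0, 4), c("S1", "S1", "S2", "S3"))
  expect_false(flag_consultation_factors(mk_dataset(cons, NULL, rx2), reg)$c_many_drugs)
  expect_true(flag_consultation_factors(mk_dataset(cons, NULL, rx3), reg)$c_many_drugs)

  # two distinct preventive-task codes required
  prev1 <- mk_ev(1, 1, rep(d0, 2), c("6871.", "6871."))
  prev2 <- mk_ev(1, 1, rep(d0, 2), c("6871.", "9OX1."))
  expect_false(flag_consultation_factors(mk_dataset(cons, prev1), reg)$c_preventive_tasks)
  expect_true(flag_consultation_factors(mk_dataset(cons, prev2), reg)$c_preventive_tasks)

  # exact-string code match, no hierarchy expansion
  near_miss <- mk_ev(1, 1, d0, "E20.x")
  expect_false(flag_consultation_factors(mk_dataset(cons, near_miss), reg)$c_mental_health)
})

test_that("frequent attender counts prior-year consultations excluding the index", {
  p_fa <- candidate_codesets()[["p_frequent_attender"]]
  reg <- registry_of(p_fa)
  mk_history <- function(n_prior) {
    dates <- c(d0 - seq_len(n_prior), d0)   # n_prior within the last year
    mk_dataset(mk_cons(seq_along(dates), dates))
  }
  f13 <- flag_patient_factors(mk_history(13), reg)
  expect_false(f13$p_frequent_attender[f13$consultation_id == 14])
  f14 <- flag_patient_factors(mk_history(14), reg)
  expect_true(f14$p_frequent_attender[f14$consultation_id == 15])
  # the patient's first-ever consultation (id 14, earliest date) is never
  # "frequent" by itself: the index consultation is excluded from the count
  expect_false(f14$p_frequent_attender[f14$consultation_id == 14])
})

test_that("polypharmacy counts unique substances in the prior 3 months", {
  p_poly <- candidate_codesets()[["p_polypharmacy"]]
  reg <- registry_of(p_poly)
  cons <- mk_cons(1, d0)
  in_win <- mk_rx(1, NA, d0 - (1:9 * 5), paste0("S", 1:9))
  expect_true(flag_patient_factors(mk_dataset(cons, NULL, in_win), reg)$p_polypharmacy)
  # same 9 substances but one pushed outside the 91-day window
  mixed <- data.table::copy(in_win)
  mixed$date[9] <- d0 - 91
  expect_false(flag_patient_factors(mk_dataset(cons, NULL, mixed), reg)$p_polypharmacy)
  # duplicates of one substance do not help
  dup <- mk_rx(1, NA, d0 - (1:9 * 5), c(paste0("S", 1:8), "S8"))
  expect_false(flag_patient_factors(mk_dataset(cons, NULL, dup), reg)$p_polypharmacy)
})

test_that("multimorbidity counts distinct condition groups ever coded", {
  p_mm <- candidate_codesets()[["p_multimorbidity"]]
  reg <- registry_of(p_mm)
  cons <- mk_cons(1, d0)
  # two groups only (diabetes twice, chd) -> false
  ev2 <- mk_ev(1, NA, d0 - c(10, 20, 30), c("C11..", "C11..", "G33.."))
  expect_false(flag_patient_factors(mk_dataset(cons, ev2), reg)$p_multimorbidity)
  ev3 <- mk_ev(1, NA, d0 - c(10, 20, 3000), c("C11..", "G33..", "H37.."))
  expect_true(flag_patient_factors(mk_dataset(cons, ev3), reg)$p_multimorbidity)
})

test_that("first-consultation-after-diagnosis picks the first, with ties by id", {
  c_fd <- measure_codesets()[["c_first_diabetes"]]
  reg <- registry_of(c_fd)
  cons <- mk_cons(c(1, 2, 3), d0 + c(0, 10, 20))
  # dx 5 days after the first consultation: flags consultation 2 only
  ev <- mk_ev(1, NA, d0 + 5, "C10..")
  f <- flag_consultation_factors(mk_dataset(cons, ev), reg)
  expect_equal(f$consultation_id[f$c_first_diabetes], 2L)
  # same-day diagnosis counts as the first consultation
  ev_same <- mk_ev(1, NA, d0 + 10, "C10..")
  f <- flag_consultation_factors(mk_dataset(cons, ev_same), reg)
  expect_equal(f$consultation_id[f$c_first_diabetes], 2L)
  # two consultations the same day: lowest consultation_id wins
  cons_tie <- mk_cons(c(5, 4), c(d0, d0))
  f <- flag_consultation_factors(mk_dataset(cons_tie, mk_ev(1, NA, d0, "C10..")), reg)
  expect_equal(f$consultation_id[f$c_first_diabetes], 4L)
  # diagnosis after every consultation flags nothing
  f <- flag_consultation_factors(mk_dataset(cons, mk_ev(1, NA, d0 + 100, "C10..")), reg)
  expect_false(any(f$c_first_diabetes))
})

test_that("events linked to a different patient are an error", {
  cons <- mk_cons(1, d0, patient = 1)
  ev <- mk_ev(2, 1, d0, "E20..")
  ds <- mk_dataset(cons, ev, n_patients = 2)
  expect_error(flag_consultation_factors(ds, measure_codesets()),
               "different patient")
})

test_that("adding a coded event never turns a complex consultation non-complex", {
  reg <- measure_codesets()
  ds <- shared_sim()
  flags <- compute_flags(ds, reg)
  retained <- registry_ids(reg)
  before <- classify_complexity(flags, retained, ds)
  # add a mental-health code to 50 random consultations
  set.seed(21)
  pick <- sample(ds$consultations$consultation_id, 50)
  m <- match(pick, ds$consultations$consultation_id)
  extra <- data.table::data.table(
    event_id = max(ds$events$event_id) + seq_along(pick),
    patient_id = ds$consultations$patient_id[m], consultation_id = pick,
    date = ds$consultations$date[m], code = "E20..")
  ds2 <- ds
  ds2$events <- rbind(ds$events, extra)
  after <- classify_complexity(compute_flags(ds2, reg), retained, ds2)
  expect_true(all(after$is_complex >= before$is_complex))
  expect_true(all(after$is_complex[match(pick, after$consultation_id)]))
})

test_that("vectorised flags equal the independent recount on simulated data", {
  ds <- shared_sim()
  reg <- measure_codesets()
  fast <- compute_flags(ds, reg)
  slow <- recount_flags(ds, reg)
  for (f in registry_ids(reg))
    expect_identical(fast[[f]], slow[[f]])
  # and equal the generator's stored truth
  expect_identical(fast[, registry_ids(reg), with = FALSE],
                   ds$truth$flags[, registry_ids(reg), with = FALSE])
})

test_that("classify_complexity gates on the retained set only", {
  reg <- registry_subset(measure_codesets(), c("c_mental_health", "c_chronic_pain"))
  cons <- mk_cons(1, d0)
  ev <- mk_ev(1, 1, d0, "E20..")
  flags <- compute_flags(mk_dataset(cons, ev), reg)
  full <- classify_complexity(flags, c("c_mental_health", "c_chronic_pain"),
                              mk_dataset(cons, ev))
  expect_true(full$is_complex)
  gated <- classify_complexity(flags, "c_chronic_pain", mk_dataset(cons, ev))
  expect_false(gated$is_complex)
  expect_error(classify_complexity(flags, "c_dementia", mk_dataset(cons, ev)),
               "absent from flags")
  # all flags false -> non-complex (empty OR)
  f0 <- compute_flags(mk_dataset(mk_cons(1, d0)), reg)
  expect_false(classify_complexity(f0, registry_ids(reg),
                                   mk_dataset(mk_cons(1, d0)))$is_complex)
})

test_that("age bands use age at consultation", {
  expect_equal(age_band_of(c(0, 4, 5, 84, 85, 101)),
               c("0-4", "0-4", "5-14", "75-84", "85+", "85+"))
})
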