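# Vectorised computation of per-consultation factor flags and the binary
# complexity classification. Window semantics: a patient factor applies at
# a consultation dated d when a qualifying event lies in the half-open
# window (d - L, d] — an event exactly L days before is outside, an event
# on the consultation date is inside; "ever" means any event dated <= d.
# Flags never look ahead of the consultation date.

FAR_FUTURE <- 3.6e6  # ~10 000 years in days; stands in for an unbounded window

cons_frame <- function(dataset) {
  cons <- data.table::as.data.table(dataset$consultations)
  assert_that(all(c("consultation_id", "patient_id", "date") %in% names(cons)),
              "consultations table must have consultation_id, patient_id, date")
  cons[, list(consultation_id = consultation_id, patient_id = patient_id,
              date = as.integer(as.Date(date)))]
}

check_linkage <- function(dataset) {
  cons <- dataset$consultations
  for (nm in c("events", "prescriptions")) {
    tab <- dataset[[nm]]
    if (is.null(tab) || nrow(tab) == 0) next
    linked <- tab[!is.na(tab$consultation_id)]
    if (nrow(linked) == 0) next
    m <- match(linked$consultation_id, cons$consultation_id)
    assert_that(!anyNA(m), sprintf("%s linked to unknown consultation", nm))
    assert_that(all(linked$patient_id == cons$patient_id[m]),
                sprintf("%s linked to a consultation of a different patient", nm))
  }
  invisible(TRUE)
}

#' Flag consultation-level complexity factors
#'
#' Computes, for every consultation in the dataset, the boolean vector of
#' consultation-level factors: code-match factors fire when any event coded
#' within the consultation matches the factor's code set; count rules fire
#' when the events (or prescriptions) attached to the consultation span at
#' least `count_threshold` distinct codes, code chapters, or substances;
#' first-consultation-after-diagnosis factors fire at the chronologically
#' first consultation on or after a qualifying diagnosis code with no
#' intervening consultation (same-day counts; ties broken by
#' consultation_id).
#'
#' @param dataset List with `consultations`, `events`, `prescriptions`
#'   tables (e.g. a `synthetic_ehr`).
#' @param registry A `codeset_registry`; only its consultation-level
#'   factors are used.
#' @return data.table: consultation_id plus one logical column per
#'   consultation-level factor.
#' @export
flag_consultation_factors <- function(dataset, registry) {
  check_linkage(dataset)
  cons <- cons_frame(dataset)
  ev <- data.table::as.data.table(dataset$events)
  rx <- data.table::as.data.table(dataset$prescriptions)
  linked_ev <- ev[!is.na(ev$consultation_id)]
  linked_rx <- rx[!is.na(rx$consultation_id)]
  out <- data.table::data.table(consultation_id = cons$consultation_id)
  reg <- registry_subset(registry, level = "consultation")
  for (fid in registry_ids(reg)) {
    d <- reg[[fid]]
    hit <- switch(
      d$rule_kind,
      code_match = unique(linked_ev$consultation_id[linked_ev$code %in% d$codes]),
      first_consult_after_dx = first_consult_hits(cons, ev, d$codes),
      count_rule = {
        if (d$source_domain == "events") {
          sub <- if (length(d$codes)) linked_ev[linked_ev$code %in% d$codes] else linked_ev
          unit <- if (identical(d$count_unit, "chapters")) chapter_of(sub$code) else sub$code
          cnt <- data.table::data.table(consultation_id = sub$consultation_id,
                                        unit = unit)[
            , list(n = data.table::uniqueN(unit)), by = "consultation_id"]
          cnt$consultation_id[cnt$n >= d$count_threshold]
        } else if (d$source_domain == "prescriptions") {
          cnt <- linked_rx[, list(n = data.table::uniqueN(substance_id)),
                           by = "consultation_id"]
          cnt$consultation_id[cnt$n >= d$count_threshold]
        } else stop(sprintf("%s: consultation-level count over %s not supported",
                            fid, d$source_domain), call. = FALSE)
      })
    data.table::set(out, j = fid, value = out$consultation_id %in% hit)
  }
  out[]
}

# first consultation at/after each diagnosis date, no intervening
# consultation; ties on date broken by consultation_id
first_consult_hits <- function(cons, ev, codes) {
  dx <- ev[ev$code %in% codes, list(patient_id = patient_id,
                                    date = as.integer(as.Date(date)))]
  if (nrow(dx) == 0) return(integer())
  cc <- data.table::copy(cons)
  data.table::setorderv(cc, c("patient_id", "date", "consultation_id"))
  data.table::setkeyv(cc, c("patient_id", "date"))  # stable: id order kept in ties
  hits <- cc[dx, on = c("patient_id", "date"), roll = -Inf, mult = "first",
             nomatch = NULL]
  unique(hits$consultation_id)
}

#' Flag patient-level complexity factors at each consultation date
#'
#' Computes patient-level factor flags anchored at every consultation:
#' code-match factors fire when a qualifying event lies in the half-open
#' lookback window `(date - L, date]` (or ever, for unbounded factors);
#' the multimorbidity rule counts distinct condition groups coded at or
#' before the consultation; the polypharmacy rule counts distinct
#' substances prescribed in its window; the frequent-attender rule counts
#' the patient's other consultations in the prior window, excluding the
#' index consultation itself.
#'
#' @inheritParams flag_consultation_factors
#' @return data.table: consultation_id plus one logical column per
#'   patient-level factor.
#' @export
flag_patient_factors <- function(dataset, registry) {
  check_linkage(dataset)
  cons <- cons_frame(dataset)
  ev <- data.table::as.data.table(dataset$events)
  rx <- data.table::as.data.table(dataset$prescriptions)
  out <- data.table::data.table(consultation_id = cons$consultation_id)
  reg <- registry_subset(registry, level = "patient")
  for (fid in registry_ids(reg)) {
    d <- reg[[fid]]
    L <- if (is.infinite(d$lookback)) FAR_FUTURE else d$lookback
    hit <- if (d$rule_kind == "code_match") {
      sub <- ev[ev$code %in% d$codes,
                list(patient_id = patient_id, lo = as.integer(as.Date(date)))]
      window_hits(cons, sub, L)
    } else if (d$source_domain == "events") {
      sel <- ev$code %in% d$codes
      sub <- data.table::data.table(
        patient_id = ev$patient_id[sel],
        lo = as.integer(as.Date(ev$date[sel])),
        grp_key = d$code_groups[match(ev$code[sel], d$codes)])
      window_count_hits(cons, sub, L, "grp_key", d$count_threshold)
    } else if (d$source_domain == "prescriptions") {
      sub <- rx[, list(patient_id = patient_id, lo = as.integer(as.Date(date)),
                       grp_key = substance_id)]
      window_count_hits(cons, sub, L, "grp_key", d$count_threshold)
    } else {  # consultation counts, index excluded
      sub <- cons[, list(patient_id = patient_id, lo = date,
                         grp_key = as.character(consultation_id))]
      cnt <- window_pair_counts(cons, sub, L)
      cnt$consultation_id[cnt$n - 1L >= d$count_threshold]
    }
    data.table::set(out, j = fid, value = out$consultation_id %in% hit)
  }
  out[]
}

# consultations with >=1 source row in (date - L, date]
window_hits <- function(cons, sub, L) {
  if (nrow(sub) == 0) return(integer())
  sub <- data.table::copy(sub)[, "hi" := lo + L]
  hits <- cons[sub, on = c("patient_id", "date>=lo", "date<hi"),
               nomatch = NULL, allow.cartesian = TRUE,
               list(consultation_id = x.consultation_id)]
  unique(hits$consultation_id)
}

window_pair_counts <- function(cons, sub, L) {
  sub <- data.table::copy(sub)[, "hi" := lo + L]
  pairs <- cons[sub, on = c("patient_id", "date>=lo", "date<hi"),
                nomatch = NULL, allow.cartesian = TRUE,
                list(consultation_id = x.consultation_id, grp_key = i.grp_key)]
  pairs[, list(n = data.table::uniqueN(grp_key)), by = "consultation_id"]
}

window_count_hits <- function(cons, sub, L, key, threshold) {
  if (nrow(sub) == 0) return(integer())
  cnt <- window_pair_counts(cons, sub, L)
  cnt$consultation_id[cnt$n >= threshold]
}

#' Compute the full factor-flag table
#'
#' Joins [flag_consultation_factors()] and [flag_patient_factors()] and
#' appends `n_factors_present`.
#'
#' @inheritParams flag_consultation_factors
#' @return data.table: consultation_id, one logical column per registry
#'   factor, and n_factors_present.
#' @export
compute_flags <- function(dataset, registry) {
  lv <- registry_levels(registry)
  parts <- list()
  if (any(lv == "consultation"))
    parts <- c(parts, list(flag_consultation_factors(dataset, registry)))
  if (any(lv == "patient"))
    parts <- c(parts, list(flag_patient_factors(dataset, registry)))
  assert_that(length(parts) > 0, "registry has no factors")
  out <- Reduce(function(a, b) merge(a, b, by = "consultation_id"), parts)
  cols <- setdiff(names(out), "consultation_id")
  out[, "n_factors_present" := rowSums(as.matrix(out[, cols, with = FALSE]))]
  out[]
}

#' Classify consultations as complex or non-complex
#'
#' A consultation is complex when at least one of the retained factors is
#' present; complexity is binary by design — the factors are not combined
#' into a cumulative score.
#'
#' @param flags Flag table from [compute_flags()].
#' @param retained_factors Character vector of factor ids forming the
#'   measure; must all be columns of `flags`.
#' @param dataset Dataset supplying durations and patient age/sex.
#' @param age_breaks Left endpoints of the age bands used for reporting.
#' @return data.table: consultation_id, is_complex, n_factors_present (over
#'   the retained set), duration_minutes, age, age_band, sex.
#' @export
classify_complexity <- function(flags, retained_factors, dataset,
                                age_breaks = c(0, 5, 15, 25, 35, 45, 55, 65, 75, 85)) {
  missing <- setdiff(retained_factors, names(flags))
  assert_that(length(missing) == 0,
              sprintf("retained factor(s) absent from flags: %s",
                      paste(missing, collapse = ", ")))
  m <- as.matrix(flags[, retained_factors, with = FALSE])
  out <- data.table::data.table(consultation_id = flags$consultation_id,
                                n_factors_present = rowSums(m),
                                is_complex = rowSums(m) >= 1)
  cons <- data.table::as.data.table(dataset$consultations)
  pat <- data.table::as.data.table(dataset$patients)
  out <- merge(out, cons[, c("consultation_id", "patient_id", "date",
                             "duration_minutes"), with = FALSE],
               by = "consultation_id")
  out <- merge(out, pat[, c("patient_id", "birth_year", "sex"), with = FALSE],
               by = "patient_id")
  # age at consultation = consultation year - birth year (configurable
  # convention; records carry no birth date finer than the year)
  out[, "age" := as.integer(format(as.Date(out$date), "%Y")) - out$birth_year]
  out[, "age_band" := age_band_of(out$age, age_breaks)]
  data.table::setorderv(out, "consultation_id")
  out[]
}

#' Age-band labelling
#'
#' @param age Integer ages.
#' @param breaks Left endpoints of the bands; the last band is unbounded.
#' @return Character band labels such as `"15-24"`, `"85+"`.
#' @export
age_band_of <- function(age, breaks = c(0, 5, 15, 25, 35, 45, 55, 65, 75, 85)) {
  breaks <- sort(unique(breaks))
  labs <- c(paste0(utils::head(breaks, -1), "-", breaks[-1] - 1),
            paste0(breaks[length(breaks)], "+"))
  labs[findInterval(pmax(age, breaks[1]), breaks)]
}
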