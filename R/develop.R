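# Measure-development pipeline: prevalence screening, percentile-based
# threshold respecification, consultation->patient reclassification,
# mixed-effects duration regression, sign- and significance-based backward
# elimination, and assembly of the retained factor set.

#' Pipeline configuration
#'
#' @param exclusion_threshold Factors applying to strictly less than this
#'   proportion of consultations (or patients) are screened out
#'   (default 0.05%).
#' @param stepwise_alpha Significance threshold for backward elimination.
#' @param frequent_attender_percentile,polypharmacy_percentile Centiles at
#'   which the corresponding count thresholds are respecified.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(exclusion_threshold = 0.0005,
                            stepwise_alpha = 0.05,
                            frequent_attender_percentile = 0.95,
                            polypharmacy_percentile = 0.95) {
  vals <- c(exclusion_threshold, stepwise_alpha,
            frequent_attender_percentile, polypharmacy_percentile)
  assert_that(all(vals > 0 & vals < 1), "pipeline_config values must lie in (0, 1)")
  structure(list(exclusion_threshold = exclusion_threshold,
                 stepwise_alpha = stepwise_alpha,
                 frequent_attender_percentile = frequent_attender_percentile,
                 polypharmacy_percentile = polypharmacy_percentile),
            class = "pipeline_config")
}

#' Prevalence screen
#'
#' Computes each factor's prevalence — over consultations for
#' consultation-level factors, over patients for patient-level factors (a
#' patient counts once if the factor holds at any of their consultations in
#' the study window) — and marks for exclusion factors applying to strictly
#' less than the exclusion threshold.
#'
#' @param flags Flag table from [compute_flags()].
#' @param dataset The dataset the flags were computed on.
#' @param registry The registry the flags cover.
#' @param config A [pipeline_config()].
#' @return data.table: factor_id, level, numerator, denominator,
#'   prevalence, excluded.
#' @export
prevalence_screen <- function(flags, dataset, registry,
                              config = pipeline_config()) {
  cons <- data.table::as.data.table(dataset$consultations)
  n_cons <- nrow(flags)
  n_pat <- nrow(dataset$patients)
  assert_that(n_cons > 0 && n_pat > 0, "zero denominator in prevalence screen")
  fl <- merge(flags, cons[, c("consultation_id", "patient_id"), with = FALSE],
              by = "consultation_id")
  rows <- lapply(registry_ids(registry), function(fid) {
    level <- registry[[fid]]$level
    if (level == "consultation") {
      num <- sum(fl[[fid]]); den <- n_cons
    } else {
      num <- data.table::uniqueN(fl$patient_id[fl[[fid]]]); den <- n_pat
    }
    data.table::data.table(factor_id = fid, level = level, numerator = num,
                           denominator = den, prevalence = num / den)
  })
  out <- data.table::rbindlist(rows)
  out[, "excluded" := out$prevalence < config$exclusion_threshold]
  out[]
}

#' Respecify a count threshold at an empirical centile
#'
#' Turns a qualitative factor ("frequent attender", "polypharmacy") into a
#' count rule by taking the smallest observed value at or above the given
#' empirical centile (inverse-ECDF quantile, rounded up to an integer).
#' With prior-year consultation counts whose 95th centile is 14 this
#' returns 14, i.e. the rule "at least 14 consultations in the last year".
#'
#' @param counts Nonnegative integer statistic per patient.
#' @param percentile Centile in (0, 1), default 0.95.
#' @return Integer threshold.
#' @export
specify_percentile_threshold <- function(counts, percentile = 0.95) {
  assert_that(length(counts) > 0, "empty statistic table")
  assert_that(all(is.finite(counts)) && all(counts >= 0),
              "counts must be nonnegative and finite")
  assert_that(percentile > 0 && percentile < 1, "percentile must be in (0, 1)")
  as.integer(ceiling(stats::quantile(counts, percentile, type = 1, names = FALSE)))
}

#' Reclassify consultation factors to patient level
#'
#' Moves the named consultation-level factors to patient level: each is
#' removed from the consultation-level set and its codes are merged into
#' the named patient-level target (created if absent) with the supplied
#' lookback window. Reclassifying onto an existing patient factor whose
#' window differs is an error.
#'
#' @param registry A `codeset_registry`.
#' @param map Named list: consultation factor_id -> `list(target =
#'   patient factor_id, lookback = days or Inf)`.
#' @return Updated `codeset_registry`.
#' @export
reclassify_low_prevalence <- function(registry, map) {
  if (length(map) == 0) return(registry)
  defs <- unclass(registry)
  for (src in names(map)) {
    spec <- map[[src]]
    assert_that(src %in% names(defs), sprintf("unknown factor: %s", src))
    d <- defs[[src]]
    assert_that(d$level == "consultation",
                sprintf("%s is not a consultation-level factor", src))
    tgt <- spec$target
    if (tgt %in% names(defs)) {
      t <- defs[[tgt]]
      assert_that(t$level == "patient", sprintf("%s is not patient-level", tgt))
      assert_that(identical(as.numeric(t$lookback), as.numeric(spec$lookback)),
                  sprintf("window conflict reclassifying %s onto %s", src, tgt))
      new_codes <- union(t$codes, d$codes)
      new_groups <- c(t$code_groups, d$code_groups[match(setdiff(d$codes, t$codes), d$codes)])
      defs[[tgt]] <- factor_definition(tgt, t$label, "patient", t$rule_kind,
                                       codes = new_codes, code_groups = new_groups,
                                       lookback = t$lookback,
                                       count_threshold = t$count_threshold,
                                       count_unit = t$count_unit,
                                       source_domain = t$source_domain)
    } else {
      defs[[tgt]] <- factor_definition(tgt, d$label, "patient", d$rule_kind,
                                       codes = d$codes, code_groups = d$code_groups,
                                       lookback = spec$lookback,
                                       count_threshold = d$count_threshold,
                                       count_unit = d$count_unit,
                                       source_domain = d$source_domain)
    }
    defs[[src]] <- NULL
  }
  new_registry(unname(defs))
}

model_frame <- function(dataset, flags, factor_ids) {
  cons <- data.table::as.data.table(dataset$consultations)
  pat <- data.table::as.data.table(dataset$patients)
  df <- merge(flags[, c("consultation_id", factor_ids), with = FALSE],
              cons[, c("consultation_id", "patient_id", "duration_minutes"),
                   with = FALSE], by = "consultation_id")
  df <- merge(df, pat[, c("patient_id", "practice_id"), with = FALSE],
              by = "patient_id")
  for (f in factor_ids) data.table::set(df, j = f, value = as.numeric(df[[f]]))
  df
}

#' Fit a mixed-effects duration model
#'
#' Regresses consultation duration (minutes) on binary factor indicators
#' with random intercepts for practice and for patient (patients are
#' nested within practices; patient ids are unique across practices so the
#' crossed specification is equivalent), fitted by REML via
#' \pkg{lme4}. Consultation and patient factors are modelled separately by
#' design — pass one level's factors at a time. `mode = "univariable"`
#' fits one factor at a time and assembles the per-factor estimates;
#' `"multivariable"` fits them jointly. Inference is Wald-style: normal
#' 95% CIs and two-sided p-values from the estimate and its standard
#' error.
#'
#' @param dataset Dataset supplying durations, patients, practices.
#' @param flags Flag table covering `factor_ids`.
#' @param factor_ids Factors to model (may be empty for an intercept-only
#'   model in multivariable mode).
#' @param mode `"multivariable"` or `"univariable"`.
#' @param reml Use REML (default) or ML.
#' @param conf_level Confidence level for Wald intervals.
#' @return Object of class `duration_model_fit`: `terms` (data.table:
#'   factor_id, estimate, se, ci_low, ci_high, p_value), `intercept`,
#'   `variance_components` (practice, patient, residual), sizes, `mode`,
#'   `converged`, `messages`, and `model` (the lme4 fit; multivariable
#'   only).
#' @export
fit_duration_model <- function(dataset, flags, factor_ids,
                               mode = c("multivariable", "univariable"),
                               reml = TRUE, conf_level = 0.95) {
  mode <- match.arg(mode)
  df <- model_frame(dataset, flags, factor_ids)
  assert_that(data.table::uniqueN(df$practice_id) >= 2,
              "need at least 2 practices to fit practice random effects")
  constant <- factor_ids[vapply(factor_ids, function(f)
    length(unique(df[[f]])) < 2, logical(1))]
  assert_that(length(constant) == 0,
              sprintf("singular design: factor(s) constant across consultations: %s",
                      paste(constant, collapse = ", ")))
  if (mode == "univariable") {
    fits <- lapply(factor_ids, function(f)
      fit_duration_model(dataset, flags, f, mode = "multivariable",
                         reml = reml, conf_level = conf_level))
    terms <- data.table::rbindlist(lapply(fits, `[[`, "terms"))
    out <- fits[[1]]
    out$terms <- terms; out$mode <- "univariable"; out$model <- NULL
    out$intercept <- NULL; out$variance_components <- NULL
    out$converged <- all(vapply(fits, `[[`, logical(1), "converged"))
    out$messages <- unlist(lapply(fits, `[[`, "messages"))
    return(out)
  }
  rhs <- if (length(factor_ids)) paste(factor_ids, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("duration_minutes ~", rhs,
                                 "+ (1 | practice_id) + (1 | patient_id)"))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = df, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(b / se))
  keep <- names(b) != "(Intercept)"
  terms <- data.table::data.table(
    factor_id = names(b)[keep], estimate = unname(b[keep]),
    se = unname(se[keep]), ci_low = unname(b[keep] - z * se[keep]),
    ci_high = unname(b[keep] + z * se[keep]), p_value = unname(p[keep]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vget <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  structure(list(
    terms = terms,
    intercept = c(estimate = unname(b["(Intercept)"]),
                  ci_low = unname(b["(Intercept)"] - z * se[1]),
                  ci_high = unname(b["(Intercept)"] + z * se[1]),
                  se = unname(se[1])),
    variance_components = c(practice = vget("practice_id"),
                            patient = vget("patient_id"),
                            residual = vget("Residual")),
    n_consultations = nrow(df),
    n_patients = data.table::uniqueN(df$patient_id),
    n_practices = data.table::uniqueN(df$practice_id),
    mode = mode, reml = reml,
    converged = !any(grepl("failed to converge|unable to evaluate", msgs)),
    singular = lme4::isSingular(fit),
    messages = msgs, model = fit),
    class = "duration_model_fit")
}

#' @export
print.duration_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("mixed-effects duration model (%s, %s): %d consultations, %d patients, %d practices\n",
              x$mode, if (isTRUE(x$reml)) "REML" else "ML",
              x$n_consultations %||% NA, x$n_patients %||% NA, x$n_practices %||% NA))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept (mean duration): %.2f [%.2f, %.2f] minutes\n",
                x$intercept["estimate"], x$intercept["ci_low"], x$intercept["ci_high"]))
  print(x$terms, digits = digits)
  if (!is.null(x$variance_components)) {
    v <- x$variance_components
    cat(sprintf("  random-intercept SDs: practice %.3f, patient %.3f, residual %.3f\n",
                sqrt(v[["practice"]]), sqrt(v[["patient"]]), sqrt(v[["residual"]])))
  }
  if (length(x$messages)) cat("  fitter messages:", unique(x$messages), sep = "\n    ")
  invisible(x)
}

#' Backward stepwise elimination on a fitted coefficient table
#'
#' Pure bookkeeping form of the elimination used on data by
#' [backward_stepwise()]: first removes, in a single pass, every factor
#' with a negative coefficient; then repeatedly removes the single factor
#' with the largest p-value at or above `alpha` until all remaining
#' factors are significant. Because no refitting occurs, this is suitable
#' for replaying a published coefficient table.
#'
#' @param terms data.table with columns factor_id, estimate, p_value.
#' @param alpha Significance threshold.
#' @return list: `retained` (factor ids), `removal_log` (data.table:
#'   step, factor_id, reason, estimate, p_value); step 0 rows are the
#'   sign-based pass.
#' @export
prune_terms <- function(terms, alpha = 0.05) {
  terms <- data.table::as.data.table(terms)
  log <- list()
  neg <- terms[terms$estimate < 0]
  if (nrow(neg))
    log[[length(log) + 1]] <- data.table::data.table(
      step = 0L, factor_id = neg$factor_id, reason = "negative_coefficient",
      estimate = neg$estimate, p_value = neg$p_value)
  cur <- terms[terms$estimate >= 0]
  step <- 0L
  repeat {
    if (nrow(cur) == 0) break
    worst <- which.max(cur$p_value)
    if (cur$p_value[worst] < alpha) break
    step <- step + 1L
    log[[length(log) + 1]] <- data.table::data.table(
      step = step, factor_id = cur$factor_id[worst], reason = "p_above_alpha",
      estimate = cur$estimate[worst], p_value = cur$p_value[worst])
    cur <- cur[-worst]
  }
  list(retained = cur$factor_id,
       removal_log = if (length(log)) data.table::rbindlist(log) else
         data.table::data.table(step = integer(), factor_id = character(),
                                reason = character(), estimate = numeric(),
                                p_value = numeric()))
}

#' Backward stepwise elimination with refitting
#'
#' Starting from the multivariable fit of `factor_ids`, removes in one
#' pass all factors whose initial coefficient is negative, then
#' iteratively refits and removes the single factor with the largest
#' p-value at or above `alpha`, until every remaining factor is
#' significant. One factor is removed per refit. If everything is removed
#' the intercept-only model is returned with a warning.
#'
#' @inheritParams fit_duration_model
#' @param alpha Significance threshold for removal.
#' @param drop_negative Apply the initial sign-based pass (default TRUE).
#' @return list: `initial_fit`, `final_fit`, `retained`, `removal_log`
#'   (as in [prune_terms()]).
#' @export
backward_stepwise <- function(dataset, flags, factor_ids, alpha = 0.05,
                              drop_negative = TRUE, reml = TRUE) {
  initial <- fit_duration_model(dataset, flags, factor_ids, "multivariable",
                                reml = reml)
  log <- list()
  cur <- factor_ids
  if (drop_negative) {
    neg <- initial$terms[initial$terms$estimate < 0]
    if (nrow(neg)) {
      log[[length(log) + 1]] <- data.table::data.table(
        step = 0L, factor_id = neg$factor_id, reason = "negative_coefficient",
        estimate = neg$estimate, p_value = neg$p_value)
      cur <- setdiff(cur, neg$factor_id)
    }
  }
  fit <- if (length(cur) == length(factor_ids)) initial else
    fit_duration_model(dataset, flags, cur, "multivariable", reml = reml)
  step <- 0L
  repeat {
    if (length(cur) == 0) break
    worst <- which.max(fit$terms$p_value)
    if (fit$terms$p_value[worst] < alpha) break
    step <- step + 1L
    log[[length(log) + 1]] <- data.table::data.table(
      step = step, factor_id = fit$terms$factor_id[worst],
      reason = "p_above_alpha", estimate = fit$terms$estimate[worst],
      p_value = fit$terms$p_value[worst])
    cur <- setdiff(cur, fit$terms$factor_id[worst])
    fit <- fit_duration_model(dataset, flags, cur, "multivariable", reml = reml)
  }
  if (length(cur) == 0)
    warning("backward stepwise removed every factor; returning intercept-only model")
  list(initial_fit = initial, final_fit = fit, retained = cur,
       removal_log = if (length(log)) data.table::rbindlist(log) else
         data.table::data.table(step = integer(), factor_id = character(),
                                reason = character(), estimate = numeric(),
                                p_value = numeric()))
}

#' Assemble the final retained factor set
#'
#' Takes the union of the factors surviving the separate consultation- and
#' patient-level eliminations, plus any explicit overrides (factors
#' force-retained on grounds outside the elimination, as was done for
#' factors losing significance only in the revalidation cohort). The two
#' surviving sets must be disjoint.
#'
#' @param consultation_fit,patient_fit `duration_model_fit` objects or
#'   plain character vectors of surviving factor ids.
#' @param overrides Factor ids to force-retain.
#' @param registry Optional registry used to validate override ids.
#' @return Character vector of retained factor ids, with attribute
#'   `"overrides"` recording the forced ones.
#' @export
assemble_measure <- function(consultation_fit, patient_fit,
                             overrides = character(), registry = NULL) {
  ids_of <- function(x) if (inherits(x, "duration_model_fit")) x$terms$factor_id
    else as.character(x)
  a <- ids_of(consultation_fit); b <- ids_of(patient_fit)
  dup <- intersect(a, b)
  assert_that(length(dup) == 0,
              sprintf("factor(s) retained at both levels: %s", paste(dup, collapse = ", ")))
  if (!is.null(registry)) {
    bad <- setdiff(overrides, registry_ids(registry))
    assert_that(length(bad) == 0,
                sprintf("override names unknown factor(s): %s", paste(bad, collapse = ", ")))
  }
  out <- union(union(a, b), overrides)
  attr(out, "overrides") <- setdiff(overrides, union(a, b))
  out
}
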