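# Application of the final binary measure: proportion complex, mean
# durations of complex vs non-complex consultations with a CI on the
# difference, and age-sex stratified complexity proportions.

#' Summarise complexity results
#'
#' Computes the headline summary of a scored dataset: the number and
#' proportion of complex consultations, arithmetic mean durations of
#' complex and non-complex consultations, their difference with a
#' two-sample large-n normal (Welch) confidence interval, and
#' age-band-by-sex strata. With all-complex or all-non-complex input the
#' summary is still produced, with the difference and its CI undefined
#' (`NA`).
#'
#' @param results Output of [classify_complexity()].
#' @param conf_level Confidence level for the difference CI.
#' @return List of class `complexity_summary`: n_consultations, n_complex,
#'   prop_complex, mean_duration_complex, mean_duration_noncomplex,
#'   difference, difference_ci, missing_duration, strata (data.table:
#'   age_band, sex, n, n_complex, prop_complex).
#' @export
summarise_complexity <- function(results, conf_level = 0.95) {
  results <- data.table::as.data.table(results)
  n <- nrow(results)
  assert_that(n > 0, "no consultations to summarise")
  missing_dur <- sum(is.na(results$duration_minutes))
  cx <- results$is_complex
  n_cx <- sum(cx)
  d1 <- results$duration_minutes[cx]
  d0 <- results$duration_minutes[!cx]
  mean1 <- if (length(d1)) mean(d1, na.rm = TRUE) else NA_real_
  mean0 <- if (length(d0)) mean(d0, na.rm = TRUE) else NA_real_
  if (n_cx > 0 && n_cx < n) {
    diff <- mean1 - mean0
    se <- sqrt(stats::var(d1, na.rm = TRUE) / sum(!is.na(d1)) +
                 stats::var(d0, na.rm = TRUE) / sum(!is.na(d0)))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(diff - z * se, diff + z * se)
  } else {
    diff <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  strata <- results[, list(n = .N, n_complex = sum(is_complex),
                           prop_complex = mean(is_complex)),
                    by = c("age_band", "sex")]
  data.table::setorderv(strata, c("age_band", "sex"))
  structure(list(n_consultations = n, n_complex = n_cx,
                 prop_complex = n_cx / n,
                 mean_duration_complex = mean1,
                 mean_duration_noncomplex = mean0,
                 difference = diff, difference_ci = ci,
                 missing_duration = missing_dur, strata = strata[]),
            class = "complexity_summary")
}

#' @export
print.complexity_summary <- function(x, ...) {
  cat(sprintf("%d of %d consultations complex (%.1f%%)\n",
              x$n_complex, x$n_consultations, 100 * x$prop_complex))
  if (!is.na(x$difference))
    cat(sprintf("mean duration %.2f (complex) vs %.2f (non-complex) minutes; difference %.2f [%.2f, %.2f]\n",
                x$mean_duration_complex, x$mean_duration_noncomplex,
                x$difference, x$difference_ci[1], x$difference_ci[2]))
  else
    cat("duration difference undefined (all consultations on one side)\n")
  if (x$missing_duration > 0)
    cat(sprintf("%d consultations with missing duration included in counts\n",
                x$missing_duration))
  print(x$strata)
  invisible(x)
}

#' Write a complexity summary to disk
#'
#' Writes `summary.json` (scalar summary) and `strata.csv` into `dir`.
#'
#' @param summary A `complexity_summary`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- summary[setdiff(names(summary), "strata")]
  jsonlite::write_json(scalars, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  data.table::fwrite(summary$strata, file.path(dir, "strata.csv"))
  invisible(dir)
}
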