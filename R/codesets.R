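#' @import data.table
#' @importFrom stats median quantile rbinom rnorm rpois runif qnorm pnorm sd var
#' @importFrom utils head tail
NULL

RULE_KINDS <- c("code_match", "count_rule", "first_consult_after_dx")
COUNT_UNITS <- c("codes", "chapters", "groups", "substances", "consultations")
SOURCE_DOMAINS <- c("events", "prescriptions", "consultations")
CODE_SENTINELS <- c("-", "—", "")

#' Construct a complexity-factor definition
#'
#' A factor definition describes how one candidate complexity factor is
#' detected in coded primary-care records: at which level it operates
#' (within a single consultation, or as a patient characteristic with a
#' lookback window), which clinical codes trigger it, and — for count
#' rules — what is counted and against which threshold.
#'
#' @param factor_id Unique identifier (e.g. `"c_mental_health"`).
#' @param label Human-readable wording.
#' @param level `"consultation"` or `"patient"`.
#' @param rule_kind One of `"code_match"`, `"count_rule"`,
#'   `"first_consult_after_dx"`.
#' @param codes Character vector of clinical codes (may be empty for pure
#'   count rules such as the frequent-attender rule).
#' @param code_groups Optional character vector parallel to `codes` grouping
#'   codes into conditions (used by the multimorbidity count rule); defaults
#'   to each code being its own group.
#' @param lookback Lookback window in days for patient-level factors;
#'   `Inf` means "ever recorded"; `NA` for consultation-level factors
#'   (the window is the consultation itself).
#' @param count_threshold Integer threshold for count rules (`NA` otherwise).
#' @param count_unit What a count rule counts: `"codes"`, `"chapters"`,
#'   `"groups"`, `"substances"` or `"consultations"`.
#' @param source_domain Record table the rule reads: `"events"`,
#'   `"prescriptions"` or `"consultations"`.
#' @return A list of class `factor_definition`.
#' @export
factor_definition <- function(factor_id, label, level, rule_kind,
                              codes = character(), code_groups = NULL,
                              lookback = NA_real_, count_threshold = NA_integer_,
                              count_unit = NA_character_,
                              source_domain = "events") {
  assert_that(length(level) == 1 && level %in% c("consultation", "patient"),
              sprintf("%s: unknown level '%s'", factor_id, paste(level, collapse = "/")))
  assert_that(length(rule_kind) == 1 && rule_kind %in% RULE_KINDS,
              sprintf("%s: unknown rule_kind '%s'", factor_id, paste(rule_kind, collapse = "/")))
  assert_that(length(source_domain) == 1 && source_domain %in% SOURCE_DOMAINS,
              sprintf("%s: unknown source_domain '%s'", factor_id,
                      paste(source_domain, collapse = "/")))
  codes <- unique(as.character(codes))
  codes <- codes[!codes %in% CODE_SENTINELS]
  if (is.null(code_groups)) {
    code_groups <- codes
  } else {
    code_groups <- as.character(code_groups)
    assert_that(length(code_groups) == length(codes),
                sprintf("%s: code_groups must parallel codes", factor_id))
  }
  if (rule_kind %in% c("code_match", "first_consult_after_dx"))
    assert_that(length(codes) > 0,
                sprintf("%s: %s rules need a non-empty code set", factor_id, rule_kind))
  if (rule_kind == "count_rule") {
    assert_that(is_count(count_threshold) && count_threshold >= 1,
                sprintf("%s: count_rule needs count_threshold >= 1", factor_id))
    count_unit <- match.arg(count_unit, COUNT_UNITS)
  }
  if (level == "consultation" && rule_kind == "code_match")
    assert_that(is.na(lookback),
                sprintf("%s: consultation-level code_match has no lookback", factor_id))
  if (level == "patient")
    assert_that(is.numeric(lookback) && !is.na(lookback) && lookback > 0,
                sprintf("%s: patient-level factors need a positive lookback (Inf = ever)", factor_id))
  structure(list(factor_id = factor_id, label = label, level = level,
                 rule_kind = rule_kind, codes = codes, code_groups = code_groups,
                 lookback = as.numeric(lookback),
                 count_threshold = as.integer(count_threshold),
                 count_unit = count_unit, source_domain = source_domain),
            class = "factor_definition")
}

#' @export
print.factor_definition <- function(x, ...) {
  win <- if (is.na(x$lookback)) "within consultation"
         else if (is.infinite(x$lookback)) "ever" else sprintf("%d days", x$lookback)
  cat(sprintf("<%s> %s [%s, %s, %s; %d codes]\n", x$factor_id, x$label,
              x$level, x$rule_kind, win, length(x$codes)))
  invisible(x)
}

new_registry <- function(defs) {
  ids <- vapply(defs, `[[`, "", "factor_id")
  assert_that(!anyDuplicated(ids), "duplicate factor_id in registry")
  names(defs) <- ids
  structure(defs, class = "codeset_registry")
}

#' @export
print.codeset_registry <- function(x, ...) {
  cat(sprintf("codeset registry: %d factors (%d consultation, %d patient)\n",
              length(x), sum(registry_levels(x) == "consultation"),
              sum(registry_levels(x) == "patient")))
  invisible(x)
}

#' Factor ids and levels of a registry
#'
#' @param registry A `codeset_registry`.
#' @return `registry_ids()`: character vector of factor ids;
#'   `registry_levels()`: named character vector of levels.
#' @export
registry_ids <- function(registry) names(registry)

#' @rdname registry_ids
#' @export
registry_levels <- function(registry)
  vapply(registry, `[[`, "", "level")

#' Subset a code-set registry
#'
#' @param registry A `codeset_registry`.
#' @param ids Factor ids to keep (order preserved), or `NULL` with `level`
#'   to keep one level.
#' @param level Optional `"consultation"` or `"patient"` filter.
#' @return A `codeset_registry`.
#' @export
registry_subset <- function(registry, ids = NULL, level = NULL) {
  keep <- registry_ids(registry)
  if (!is.null(level)) keep <- keep[registry_levels(registry)[keep] == level]
  if (!is.null(ids)) {
    missing <- setdiff(ids, keep)
    assert_that(length(missing) == 0,
                sprintf("unknown factor id(s): %s", paste(missing, collapse = ", ")))
    keep <- ids
  }
  new_registry(unname(registry[keep]))
}

parse_lookback <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  out[tolower(x) == "ever"] <- Inf
  num <- suppressWarnings(as.numeric(x))
  out[!is.na(num)] <- num[!is.na(num)]
  out
}

format_lookback <- function(x) {
  ifelse(is.na(x), "", ifelse(is.infinite(x), "ever", format(x, scientific = FALSE)))
}

#' Load a code-set registry from CSV
#'
#' The file has one row per (factor, code) pair with columns `factor_id`,
#' `label`, `level`, `rule_kind`, `lookback`, `count_threshold`,
#' `source_domain`, `code` and optionally `count_unit` and `code_group`.
#' Pure count rules (no code list) use a sentinel code `-`/`—`.
#' `lookback` is `"ever"`, a number of days, or blank for consultation-level
#' factors. Rows sharing a `factor_id` are merged (codes deduplicated); the
#' factor's metadata must agree across its rows.
#'
#' @param path CSV file path.
#' @return A `codeset_registry`.
#' @export
load_codesets <- function(path) {
  assert_that(file.exists(path), sprintf("code-set file not found: %s", path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  assert_that(nrow(dt) > 0, "empty code-set file")
  req <- c("factor_id", "label", "level", "rule_kind", "lookback",
           "count_threshold", "source_domain", "code")
  missing <- setdiff(req, names(dt))
  assert_that(length(missing) == 0,
              sprintf("code-set file missing column(s): %s", paste(missing, collapse = ", ")))
  if (!"count_unit" %in% names(dt)) dt[, "count_unit" := NA_character_]
  if (!"code_group" %in% names(dt)) dt[, "code_group" := dt$code]
  dt[, "row" := .I]
  defs <- lapply(split(dt, by = "factor_id", sorted = FALSE), function(g) {
    first <- function(col) {
      u <- unique(g[[col]])
      if (length(u) > 1)
        stop(sprintf("factor %s: inconsistent %s near row %d", g$factor_id[1], col, g$row[1]),
             call. = FALSE)
      u
    }
    keep <- !g$code %in% CODE_SENTINELS
    tryCatch(
      factor_definition(
        factor_id = g$factor_id[1], label = first("label"),
        level = first("level"), rule_kind = first("rule_kind"),
        codes = g$code[keep],
        code_groups = if (any(keep)) g$code_group[keep] else NULL,
        lookback = parse_lookback(first("lookback")),
        count_threshold = {
          th <- first("count_threshold")
          if (th %in% c("", "NA")) NA_integer_ else as.integer(th)
        },
        count_unit = {
          cu <- first("count_unit")
          if (is.na(cu) || cu == "") NA_character_ else cu
        },
        source_domain = first("source_domain")),
      error = function(e) stop(sprintf("row %d: %s", g$row[1], conditionMessage(e)),
                               call. = FALSE))
  })
  new_registry(unname(defs))
}

#' Write a code-set registry to CSV
#'
#' Inverse of [load_codesets()]: `load_codesets(write_codesets(r, f))` equals
#' `r` for any valid registry.
#'
#' @param registry A `codeset_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codesets <- function(registry, path) {
  rows <- lapply(registry, function(d) {
    codes <- if (length(d$codes)) d$codes else "-"
    groups <- if (length(d$codes)) d$code_groups else "-"
    data.table::data.table(
      factor_id = d$factor_id, label = d$label, level = d$level,
      rule_kind = d$rule_kind, lookback = format_lookback(d$lookback),
      count_threshold = ifelse(is.na(d$count_threshold), "", as.character(d$count_threshold)),
      source_domain = d$source_domain, code = codes,
      count_unit = ifelse(is.na(d$count_unit), "", d$count_unit),
      code_group = groups)
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Clinical-code chapter
#'
#' Returns the chapter of a clinical code under the Read-v2 convention that
#' the chapter is the code's first character (case preserved: `"h33.."` and
#' `"H33.."` are distinct chapters). Supply `chapter_map` (named character
#' vector code -> chapter) to override for other terminologies.
#'
#' @param code Character vector of non-empty codes.
#' @param chapter_map Optional named character vector overriding chapters for
#'   specific codes.
#' @return Character vector of chapters.
#' @export
chapter_of <- function(code, chapter_map = NULL) {
  code <- as.character(code)
  assert_that(all(nzchar(code)), "empty code string")
  ch <- substr(code, 1L, 1L)
  if (!is.null(chapter_map)) {
    hit <- match(code, names(chapter_map))
    ch[!is.na(hit)] <- unname(chapter_map[hit[!is.na(hit)]])
  }
  ch
}

#' Bundled toy code sets
#'
#' `measure_codesets()` returns the registry of the 17 factors in the final
#' complexity measure (10 consultation-level, 7 patient-level);
#' `candidate_codesets()` returns the wider registry of all 34
#' panel-endorsed candidate factors, including those later dropped for low
#' prevalence or a negative duration association. Codes are toy Read-style
#' codes shipped with the package — they are synthetic stand-ins, not the
#' study's deposited code sets.
#'
#' @return A `codeset_registry`.
#' @export
measure_codesets <- function() {
  load_codesets(system.file("extdata", "codesets_final.csv",
                            package = "gpcomplexity", mustWork = TRUE))
}

#' @rdname measure_codesets
#' @export
candidate_codesets <- function() {
  load_codesets(system.file("extdata", "codesets_candidate.csv",
                            package = "gpcomplexity", mustWork = TRUE))
}
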