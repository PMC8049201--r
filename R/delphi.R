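#' Delphi decision thresholds
#'
#' Thresholds for classifying a factor from one round of panel votes.
#' Scores 3-5 count as endorsement and a score of 1 as rejection (score 2
#' counts towards neither, but stays in the denominator). A factor is
#' accepted when strictly more than 70% of voters endorse it and strictly
#' fewer than 20% reject it; it is not accepted when fewer than 40% endorse
#' and more than 20% reject; every other combination is uncertain. All four
#' comparisons are strict, so a factor endorsed by exactly 70% of voters is
#' uncertain, not endorsed.
#'
#' @param endorse_min_prop Accept requires prop_endorse strictly above this.
#' @param reject_max_prop_for_accept Accept requires prop_reject strictly
#'   below this.
#' @param endorse_max_prop_for_reject Reject requires prop_endorse strictly
#'   below this.
#' @param reject_min_prop_for_reject Reject requires prop_reject strictly
#'   above this.
#' @param endorse_scores Scores counted as endorsement.
#' @param reject_scores Scores counted as rejection.
#' @return A list of class `delphi_thresholds`.
#' @export
delphi_thresholds <- function(endorse_min_prop = 0.70,
                              reject_max_prop_for_accept = 0.20,
                              endorse_max_prop_for_reject = 0.40,
                              reject_min_prop_for_reject = 0.20,
                              endorse_scores = c(3L, 4L, 5L),
                              reject_scores = 1L) {
  props <- c(endorse_min_prop, reject_max_prop_for_accept,
             endorse_max_prop_for_reject, reject_min_prop_for_reject)
  assert_that(is_prob(props), "all Delphi thresholds must lie in [0, 1]")
  assert_that(length(intersect(endorse_scores, reject_scores)) == 0,
              "endorse_scores and reject_scores must be disjoint")
  structure(list(endorse_min_prop = endorse_min_prop,
                 reject_max_prop_for_accept = reject_max_prop_for_accept,
                 endorse_max_prop_for_reject = endorse_max_prop_for_reject,
                 reject_min_prop_for_reject = reject_min_prop_for_reject,
                 endorse_scores = as.integer(endorse_scores),
                 reject_scores = as.integer(reject_scores)),
            class = "delphi_thresholds")
}

validate_votes <- function(votes, require_single_factor = FALSE,
                           require_single_round = FALSE) {
  votes <- data.table::as.data.table(votes)
  req <- c("panelist_id", "factor_id", "round", "score")
  missing <- setdiff(req, names(votes))
  assert_that(length(missing) == 0,
              sprintf("vote table missing column(s): %s", paste(missing, collapse = ", ")))
  # abstentions (missing scores) are dropped: they leave the denominator
  votes <- votes[!is.na(votes$score)]
  assert_that(nrow(votes) > 0, "empty vote set")
  assert_that(all(votes$score %in% 1:5), "scores must be integers in 1..5")
  assert_that(all(votes$round %in% 1:2), "round must be 1 or 2")
  if (require_single_factor)
    assert_that(data.table::uniqueN(votes$factor_id) == 1,
                "votes span multiple factors")
  if (require_single_round)
    assert_that(data.table::uniqueN(votes$round) == 1, "votes span multiple rounds")
  assert_that(!anyDuplicated(votes[, c("panelist_id", "factor_id", "round")]),
              "duplicate (panelist, factor, round) vote")
  votes
}

# inclusive-quartile IQR; median of an even panel = mean of the two
# central scores (so medians like 3.5 are possible)
score_summary <- function(scores) {
  list(median = stats::median(scores),
       iqr = unname(stats::quantile(scores, c(0.25, 0.75), type = 7)))
}

classify_props <- function(prop_endorse, prop_reject, thresholds) {
  endorsed <- prop_endorse > thresholds$endorse_min_prop &
    prop_reject < thresholds$reject_max_prop_for_accept
  rejected <- prop_endorse < thresholds$endorse_max_prop_for_reject &
    prop_reject > thresholds$reject_min_prop_for_reject
  status <- rep("uncertain", length(prop_endorse))
  status[rejected] <- "rejected"
  status[endorsed] <- "endorsed"  # the two regions cannot overlap (0.70 > 0.40)
  status
}

#' Classify one factor from one round of votes
#'
#' @param votes Data frame of votes (`panelist_id`, `factor_id`, `round`,
#'   `score`) for a single factor and round.
#' @param thresholds A [delphi_thresholds()] object.
#' @return A one-row data.table: factor_id, round, n_votes, prop_endorse,
#'   prop_reject, median_score, iqr_low, iqr_high, status.
#' @export
classify_factor <- function(votes, thresholds = delphi_thresholds()) {
  votes <- validate_votes(votes, require_single_factor = TRUE,
                          require_single_round = TRUE)
  n <- nrow(votes)
  pe <- sum(votes$score %in% thresholds$endorse_scores) / n
  pr <- sum(votes$score %in% thresholds$reject_scores) / n
  ss <- score_summary(votes$score)
  data.table::data.table(
    factor_id = votes$factor_id[1], round = votes$round[1], n_votes = n,
    prop_endorse = pe, prop_reject = pr, median_score = ss$median,
    iqr_low = ss$iqr[1], iqr_high = ss$iqr[2],
    status = classify_props(pe, pr, thresholds))
}

classify_all <- function(votes, thresholds) {
  votes <- validate_votes(votes)
  data.table::rbindlist(lapply(
    split(votes, by = "factor_id", sorted = TRUE),
    classify_factor, thresholds = thresholds))
}

#' Resolve final status from per-round statuses
#'
#' Applies the two-round carry-forward rule to already-classified rounds:
#' a factor endorsed or rejected in round 1 keeps that status; a factor
#' uncertain in round 1 (or introduced in round 2) takes its round-2
#' status; anything still uncertain after round 2 — including an uncertain
#' factor never revoted — is rejected.
#'
#' @param round1_status Character vector in
#'   `{"endorsed","rejected","uncertain"}` or `NA` for factors introduced in
#'   round 2.
#' @param round2_status Character vector (same length) or `NA` where no
#'   round-2 vote took place.
#' @return Character vector of final statuses (`"endorsed"`/`"rejected"`).
#' @export
resolve_final_status <- function(round1_status, round2_status) {
  assert_that(length(round1_status) == length(round2_status),
              "status vectors must have equal length")
  ok <- c("endorsed", "rejected", "uncertain", NA)
  assert_that(all(round1_status %in% ok) && all(round2_status %in% ok),
              "unknown status value")
  final <- round1_status
  open <- is.na(round1_status) | round1_status == "uncertain"
  final[open] <- round2_status[open]
  final[is.na(final) | final == "uncertain"] <- "rejected"
  final
}

#' Run the two-round Delphi workflow on vote tables
#'
#' Round-1 votes are classified per factor; endorsed/rejected statuses are
#' final. Factors uncertain after round 1, plus any factors introduced in
#' round 2, are classified from the round-2 votes; factors still uncertain
#' are rejected. Round-2 votes for a factor already finalised in round 1 are
#' an error.
#'
#' @param round1_votes Vote table for round 1.
#' @param round2_votes Vote table for round 2 (may be `NULL`/empty).
#' @param round2_new_factors Character vector of factor ids first put to the
#'   panel in round 2.
#' @param thresholds A [delphi_thresholds()] object.
#' @return data.table with one row per factor: factor_id, round1_status,
#'   round2_status, final_status, medians and vote counts per round.
#' @export
run_two_rounds <- function(round1_votes, round2_votes = NULL,
                           round2_new_factors = character(),
                           thresholds = delphi_thresholds()) {
  r1 <- classify_all(round1_votes, thresholds)
  uncertain <- r1$factor_id[r1$status == "uncertain"]
  eligible_r2 <- union(uncertain, round2_new_factors)
  r2 <- NULL
  if (!is.null(round2_votes) && nrow(data.table::as.data.table(round2_votes)) > 0) {
    r2 <- classify_all(round2_votes, thresholds)
    finalised <- setdiff(r2$factor_id, eligible_r2)
    assert_that(length(finalised) == 0,
                sprintf("round-2 votes for factor(s) already finalised in round 1: %s",
                        paste(finalised, collapse = ", ")))
  }
  all_ids <- sort(union(r1$factor_id, union(round2_new_factors,
                                            if (is.null(r2)) character() else r2$factor_id)))
  out <- data.table::data.table(factor_id = all_ids)
  out <- merge(out, r1[, c("factor_id", "status", "median_score", "n_votes")],
               by = "factor_id", all.x = TRUE)
  data.table::setnames(out, c("status", "median_score", "n_votes"),
                       c("round1_status", "median_r1", "n_votes_r1"))
  if (!is.null(r2)) {
    out <- merge(out, r2[, c("factor_id", "status", "median_score", "n_votes")],
                 by = "factor_id", all.x = TRUE)
    data.table::setnames(out, c("status", "median_score", "n_votes"),
                         c("round2_status", "median_r2", "n_votes_r2"))
  } else {
    out[, c("round2_status", "median_r2", "n_votes_r2") :=
          list(NA_character_, NA_real_, NA_integer_)]
  }
  out[, "final_status" := resolve_final_status(out$round1_status, out$round2_status)]
  out[]
}

#' Individualised round-1 feedback report
#'
#' Reproduces the controlled-feedback step between rounds: for one panelist,
#' each factor's own score is set against the whole panel's median and
#' interquartile range, with the deviation from the median, ordered by
#' factor id; an overall summary row gives the mean absolute deviation.
#'
#' @param panelist_id The panelist to report on.
#' @param round1_votes Full round-1 vote table.
#' @return List with `rows` (per-factor data.table: factor_id, own_score,
#'   panel_median, iqr_low, iqr_high, deviation) and `summary` (n_factors,
#'   mean_abs_deviation).
#' @export
feedback_report <- function(panelist_id, round1_votes) {
  votes <- validate_votes(round1_votes, require_single_round = TRUE)
  pid <- panelist_id  # avoid capture by the data.table column of the same name
  own <- votes[votes$panelist_id == pid]
  assert_that(nrow(own) > 0, sprintf("unknown panelist: %s", pid))
  panel <- votes[, {
    ss <- score_summary(score)
    list(panel_median = ss$median, iqr_low = ss$iqr[1], iqr_high = ss$iqr[2])
  }, by = "factor_id"]
  rows <- merge(own[, c("factor_id", "score")], panel, by = "factor_id")
  data.table::setnames(rows, "score", "own_score")
  rows[, "deviation" := rows$own_score - rows$panel_median]
  data.table::setorderv(rows, "factor_id")
  list(rows = rows[],
       summary = list(panelist_id = panelist_id, n_factors = nrow(rows),
                      mean_abs_deviation = mean(abs(rows$deviation))))
}
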