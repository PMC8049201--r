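# Reference recount of factor flags. This is a deliberately plain
# implementation (base R, per-patient loops for the windowed rules) kept
# independent of the vectorised factors module, so the two can be checked
# against each other; the generator also uses it to derive the realized
# truth flags from the tables it has just written.

#' Reference recount of per-consultation factor flags
#'
#' Recomputes the boolean factor matrix for every consultation directly
#' from the record tables, one factor at a time, using straightforward
#' subset-and-count logic. Semantics are identical to [compute_flags()]
#' (half-open lookback windows `(date - L, date]`, "ever" = any time at or
#' before the consultation, index consultation excluded from the
#' frequent-attender count) but the implementation is independent. Slower;
#' intended as an oracle and for generating simulation truth.
#'
#' @param dataset A `synthetic_ehr` (or any list with the four tables).
#' @param registry A `codeset_registry`.
#' @return data.table: consultation_id plus one logical column per factor.
#' @export
recount_flags <- function(dataset, registry) {
  cons <- dataset$consultations
  ev <- dataset$events
  rx <- dataset$prescriptions
  ord <- order(cons$patient_id, as.integer(cons$date), cons$consultation_id)
  c_pat <- cons$patient_id[ord]
  c_date <- as.integer(cons$date)[ord]
  c_id <- cons$consultation_id[ord]
  out <- data.table::data.table(consultation_id = c_id)

  linked_ev <- ev[!is.na(ev$consultation_id)]
  linked_rx <- rx[!is.na(rx$consultation_id)]

  for (fid in registry_ids(registry)) {
    d <- registry[[fid]]
    flag <- logical(length(c_id))
    if (d$level == "consultation") {
      if (d$rule_kind == "code_match") {
        hit <- unique(linked_ev$consultation_id[linked_ev$code %in% d$codes])
        flag <- c_id %in% hit
      } else if (d$rule_kind == "first_consult_after_dx") {
        dx <- ev[ev$code %in% d$codes]
        hit <- integer()
        for (p in unique(dx$patient_id)) {
          sel <- which(c_pat == p)
          if (!length(sel)) next
          for (dd in as.integer(dx$date[dx$patient_id == p])) {
            k <- which(c_date[sel] >= dd)
            if (length(k)) hit <- c(hit, c_id[sel[k[1]]])
          }
        }
        flag <- c_id %in% hit
      } else if (d$source_domain == "events") {
        sub <- if (length(d$codes)) linked_ev[linked_ev$code %in% d$codes] else linked_ev
        key <- if (identical(d$count_unit, "chapters"))
          chapter_of(sub$code) else sub$code
        n_per <- tapply(key, sub$consultation_id, function(x) length(unique(x)))
        hit <- as.integer(names(n_per)[n_per >= d$count_threshold])
        flag <- c_id %in% hit
      } else if (d$source_domain == "prescriptions") {
        n_per <- tapply(linked_rx$substance_id, linked_rx$consultation_id,
                        function(x) length(unique(x)))
        hit <- as.integer(names(n_per)[n_per >= d$count_threshold])
        flag <- c_id %in% hit
      }
    } else {  # patient-level, anchored at the consultation date
      L <- d$lookback
      in_window <- function(e, dd) if (is.infinite(L)) e <= dd else (e > dd - L) & (e <= dd)
      if (d$rule_kind == "code_match") {
        sub <- ev[ev$code %in% d$codes]
        for (p in unique(sub$patient_id)) {
          e <- as.integer(sub$date[sub$patient_id == p])
          sel <- which(c_pat == p)
          flag[sel] <- vapply(c_date[sel], function(dd) any(in_window(e, dd)), logical(1))
        }
      } else if (d$source_domain == "events") {  # count distinct groups
        sub <- ev[ev$code %in% d$codes]
        grp <- d$code_groups[match(sub$code, d$codes)]
        for (p in unique(sub$patient_id)) {
          i <- sub$patient_id == p
          e <- as.integer(sub$date[i]); g <- grp[i]
          sel <- which(c_pat == p)
          flag[sel] <- vapply(c_date[sel], function(dd)
            length(unique(g[in_window(e, dd)])) >= d$count_threshold, logical(1))
        }
      } else if (d$source_domain == "prescriptions") {
        for (p in unique(rx$patient_id)) {
          i <- rx$patient_id == p
          e <- as.integer(rx$date[i]); s <- rx$substance_id[i]
          sel <- which(c_pat == p)
          flag[sel] <- vapply(c_date[sel], function(dd)
            length(unique(s[in_window(e, dd)])) >= d$count_threshold, logical(1))
        }
      } else {  # consultation counts: index consultation excluded
        for (p in unique(c_pat)) {
          sel <- which(c_pat == p)
          dts <- c_date[sel]
          flag[sel] <- vapply(dts, function(dd)
            sum(in_window(dts, dd)) - 1L >= d$count_threshold, logical(1))
        }
      }
    }
    data.table::set(out, j = fid, value = flag)
  }
  data.table::setorderv(out, "consultation_id")
  out[]
}
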