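# Cycle-level fertility-behavior metrics, the intention-by-behavior
# cross-tabulation, and condom/withdrawal cycle flagging.

#' Did a cycle include intercourse on a fertile day?
#'
#' @param cycle a `crms_cycle` with chart data
#' @param statuses day statuses from [classify_days()]
#' @param include_unknown also count intercourse on days of undetermined
#'   fertility (the wider column of the behavior table)
#' @return logical
#' @export
cycle_has_fertile_intercourse <- function(cycle, statuses, include_unknown = FALSE) {
  if (!has_chart(cycle)) stop_crms("cycle has no chart data", "crms_no_chart")
  hit <- statuses$status == "FERTILE"
  if (include_unknown) hit <- hit | statuses$status == "UNKNOWN"
  any(cycle$days$intercourse & hit)
}

#' Summarise one cycle's fertility behavior
#'
#' @param cycle a `crms_cycle` with chart data
#' @param statuses day statuses from [classify_days()]
#' @return one-row data.frame: `any_intercourse`, `intercourse_on_fertile`,
#'   `intercourse_on_fertile_or_unknown`
#' @export
cycle_behavior <- function(cycle, statuses) {
  data.frame(couple_id = cycle$couple_id,
             cycle_index = cycle$cycle_index,
             any_intercourse = any(cycle$days$intercourse),
             intercourse_on_fertile =
               cycle_has_fertile_intercourse(cycle, statuses, FALSE),
             intercourse_on_fertile_or_unknown =
               cycle_has_fertile_intercourse(cycle, statuses, TRUE),
             stringsAsFactors = FALSE)
}

intention_row_order <- c("TRYING_HARD_CONCEIVE", "CONCEIVE", "NEUTRAL",
                         "AVOID", "TRYING_HARD_AVOID", "ABSTAIN")

#' Intention-by-behavior cross-tabulation
#'
#' One row per 6-level couple-cycle intention (most achieving first), with
#' the count and percentage of cycles with intercourse on at least one
#' known fertile day, the same including days of undetermined fertility,
#' and the cycle total; a Total row closes the table.  Cycles missing a
#' reconciled intention or behavior data are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param intents data.frame with `couple_id`, `cycle_index`, `reconciled`
#' @param behaviors data.frame from [cycle_behavior()] rows
#' @param n_total_cycles optional total cycle count in the cohort, used to
#'   report exclusions beyond the merge (defaults to the union of inputs)
#' @return data.frame (class `crms_behavior_table`)
#' @export
intention_behavior_table <- function(intents, behaviors, n_total_cycles = NULL) {
  m <- merge(intents[!is.na(intents$reconciled),
                     c("couple_id", "cycle_index", "reconciled")],
             behaviors, by = c("couple_id", "cycle_index"))
  if (is.null(n_total_cycles)) {
    all_keys <- unique(rbind(intents[c("couple_id", "cycle_index")],
                             behaviors[c("couple_id", "cycle_index")]))
    n_total_cycles <- nrow(all_keys)
  }
  rows <- lapply(intention_row_order, function(lv) {
    b <- m[m$reconciled == lv, , drop = FALSE]
    data.frame(intention = lv,
               n_fertile = sum(b$intercourse_on_fertile),
               n_fertile_or_unknown = sum(b$intercourse_on_fertile_or_unknown),
               total = nrow(b), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(intention = "Total",
                               n_fertile = sum(tab$n_fertile),
                               n_fertile_or_unknown = sum(tab$n_fertile_or_unknown),
                               total = sum(tab$total)))
  tab$pct_fertile <- fmt_pct(tab$n_fertile, tab$total)
  tab$pct_fertile_or_unknown <- fmt_pct(tab$n_fertile_or_unknown, tab$total)
  structure(tab, class = c("crms_behavior_table", "data.frame"),
            n_excluded = n_total_cycles - nrow(m))
}

#' Flag cycles with any identified condom or withdrawal use
#'
#' Unions every available source: either partner's SOC report of barrier
#' or withdrawal use (the SOC question refers to the cycle immediately
#' prior to the questionnaire, so responses are shifted back one cycle)
#' and any chart annotation.
#'
#' @param soc data.frame of SOC responses; `prior_cycle_methods` is a
#'   semicolon-joined set
#' @param chart_annotations optional data.frame (`couple_id`,
#'   `cycle_index`, `barrier_withdrawal` logical)
#' @return data.frame `couple_id`, `cycle_index`, `barrier_withdrawal`
#'   covering every cycle named by either source
#' @export
flag_barrier_withdrawal <- function(soc, chart_annotations = NULL) {
  methods <- strsplit(ifelse(is.na(soc$prior_cycle_methods), "",
                             soc$prior_cycle_methods), ";", fixed = TRUE)
  soc_hit <- vapply(methods, function(m) any(m %in% c("condom", "withdrawal")),
                    logical(1))
  # report at cycle k describes methods used in cycle k-1
  flagged <- data.frame(couple_id = soc$couple_id,
                        cycle_index = soc$cycle_index - 1L,
                        hit = soc_hit, stringsAsFactors = FALSE)
  flagged <- flagged[flagged$cycle_index >= 1L, , drop = FALSE]
  if (!is.null(chart_annotations) && nrow(chart_annotations) > 0) {
    flagged <- rbind(flagged,
                     data.frame(couple_id = chart_annotations$couple_id,
                                cycle_index = chart_annotations$cycle_index,
                                hit = chart_annotations$barrier_withdrawal))
  }
  if (nrow(flagged) == 0L) {
    return(data.frame(couple_id = character(), cycle_index = integer(),
                      barrier_withdrawal = logical()))
  }
  agg <- stats::aggregate(hit ~ couple_id + cycle_index, data = flagged, FUN = any)
  names(agg)[names(agg) == "hit"] <- "barrier_withdrawal"
  agg[order(agg$couple_id, agg$cycle_index), , drop = FALSE]
}
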