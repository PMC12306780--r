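# The three-level correct-use eligibility cascade and the five correct-use
# cycle definitions (two to conceive, three to avoid pregnancy).

#' Correct-use category names
#'
#' The five correct-use definitions: two to conceive (any fertile day;
#' at least one peak-type mucus day) and three to avoid pregnancy (no
#' intercourse on fertile or unknown days; intercourse only on Peak+4 or
#' later; intercourse on the last non-fertile day before the fertile
#' window with none on fertile days).
#'
#' @format character vector of length 5
#' @export
CORRECT_USE_CATEGORIES <- c("CONCEIVE_ANY_FERTILE", "CONCEIVE_PEAK_TYPE",
                            "AVOID_STRICT", "AVOID_POSTPEAK_ONLY",
                            "AVOID_LAST_DRY_PREPEAK")

FIDELITY_OK <- c("ALL_WITHOUT_EXCEPTION", "NEARLY_ALL_RARE_EXCEPTION")

#' Is a couple eligible for correct-use analyses?
#'
#' Eligibility requires that at least one partner reported on the exit
#' questionnaire that they recorded every act of intercourse all of the
#' time without exception, or nearly all of the time with maybe a rare
#' exception.
#'
#' @param fidelity data.frame with `couple_id` and `exit_answer` (one row
#'   per partner; answers `ALL_WITHOUT_EXCEPTION`,
#'   `NEARLY_ALL_RARE_EXCEPTION`, `NOT_ALL`, `MISSING`)
#' @return data.frame `couple_id`, `eligible`
#' @export
couple_eligible <- function(fidelity) {
  fidelity$ok <- fidelity$exit_answer %in% FIDELITY_OK
  agg <- stats::aggregate(ok ~ couple_id, data = fidelity, FUN = any)
  names(agg)[names(agg) == "ok"] <- "eligible"
  agg
}

#' Assign teacher follow-up assessments to cycles
#'
#' Each cycle receives the follow-up record closest in date to the cycle's
#' end; ties break toward the earlier visit.
#'
#' @param followups data.frame `couple_id`, `visit_date`,
#'   `consistent_observations`, `peak_id_ok`, `accurate_charting`
#' @param cycle_ends data.frame `couple_id`, `cycle_index`, `end_date`
#' @return `cycle_ends` with the three assessment booleans appended (NA
#'   when the couple has no follow-up records)
#' @export
assign_assessments <- function(followups, cycle_ends) {
  pick <- function(cid, end) {
    f <- followups[followups$couple_id == cid, , drop = FALSE]
    if (nrow(f) == 0L) {
      return(data.frame(consistent_observations = NA, peak_id_ok = NA,
                        accurate_charting = NA))
    }
    d <- abs(as.numeric(f$visit_date) - as.numeric(end))
    # ties toward the earlier visit
    f <- f[order(d, as.numeric(f$visit_date)), , drop = FALSE]
    f[1, c("consistent_observations", "peak_id_ok", "accurate_charting")]
  }
  picked <- do.call(rbind, Map(pick, cycle_ends$couple_id, cycle_ends$end_date))
  cbind(cycle_ends, picked, row.names = NULL)
}

#' Classify one cycle against the five correct-use definitions
#'
#' The cycle must belong to an eligible couple and be completely charted
#' (daily observations for the entire cycle, no day of unknown fertility
#' caused by missing observations) with at least one recorded act of
#' intercourse; otherwise no category applies (`eligible = FALSE`).
#' Category membership is determined from the day statuses and intercourse
#' placement; levels 2 and 3 apply progressively stricter evidence
#' filters on top of the same category.
#'
#' @param cycle a `crms_cycle` with chart data
#' @param statuses day statuses from [classify_days()]
#' @param assessment list/row with `consistent_observations`, `peak_id_ok`,
#'   `accurate_charting` (teacher follow-up assigned to this cycle)
#' @param barrier_withdrawal any identified condom/withdrawal use this cycle
#' @param nonstandard_chart nonstandard chart format flag
#' @param strict_end_of_day treat intercourse with unrecorded end-of-day
#'   timing on an end-of-day-only non-fertile day as potentially fertile,
#'   excluding the cycle from the avoid categories (default TRUE)
#' @return list: `eligible`, `categories` (character vector), `l2`, `l3`
#'   (does the cycle pass the level-2 / level-3 filters)
#' @export
classify_cycle_correct_use <- function(cycle, statuses, assessment,
                                       barrier_withdrawal = FALSE,
                                       nonstandard_chart = FALSE,
                                       strict_end_of_day = TRUE) {
  if (!has_chart(cycle)) stop_crms("incomplete chart: no chart data",
                                   "crms_incomplete_chart")
  days <- cycle$days
  complete <- !any(statuses$status == "UNKNOWN")
  has_ic <- any(days$intercourse)
  if (!complete || !has_ic) {
    return(list(eligible = FALSE, categories = character(0),
                l2 = FALSE, l3 = FALSE))
  }
  ic_days <- days$day_of_cycle[days$intercourse]
  st <- statuses$status[match(ic_days, statuses$day_of_cycle)]
  eod_only <- statuses$end_of_day_only[match(ic_days, statuses$day_of_cycle)]
  eod_recorded <- days$intercourse_end_of_day[days$intercourse]
  peak_type_ic <- vapply(ic_days, function(d) {
    disc <- days$discharge[days$day_of_cycle == d]
    identical(disc, "peak-type-mucus")
  }, logical(1))

  any_fertile <- any(st == "FERTILE")
  any_unknown <- any(st == "UNKNOWN")
  # timing-ambiguous: act on an end-of-day-only non-fertile day without a
  # recorded end-of-day timing
  amb_day <- st == "NON_FERTILE" & eod_only & !(eod_recorded %in% TRUE)
  ambiguous <- any(amb_day)

  cats <- character(0)
  if (any_fertile) {
    cats <- c(cats, "CONCEIVE_ANY_FERTILE")
    if (any(peak_type_ic)) cats <- c(cats, "CONCEIVE_PEAK_TYPE")
  } else {
    avoid_blocked <- any_unknown || (strict_end_of_day && ambiguous)
    if (!avoid_blocked) cats <- c(cats, "AVOID_STRICT")
    if (!is.na(cycle$peak_day) && !(strict_end_of_day && ambiguous) &&
        all(ic_days >= cycle$peak_day + 4L)) {
      cats <- c(cats, "AVOID_POSTPEAK_ONLY")
    }
    # the defining day of this exploratory category is itself end-of-day
    # only, so its own timing ambiguity cannot be exclusionary; ambiguity
    # on any other day still blocks under the strict flag
    last_dry <- last_dry_prepeak_day(statuses)
    if (!is.na(last_dry) && last_dry %in% ic_days) {
      amb_elsewhere <- any(amb_day & ic_days != last_dry)
      if (!(strict_end_of_day && amb_elsewhere)) {
        cats <- c(cats, "AVOID_LAST_DRY_PREPEAK")
      }
    }
  }
  l2 <- isTRUE(assessment$consistent_observations) &&
    isTRUE(assessment$peak_id_ok) && isTRUE(assessment$accurate_charting)
  l3 <- l2 && !isTRUE(barrier_withdrawal) && !isTRUE(nonstandard_chart)
  list(eligible = TRUE, categories = cats, l2 = l2, l3 = l3)
}

# the single non-fertile day immediately preceding the first fertile day of
# the mucus-based fertile window (i.e., the first fertile day after the last
# leading menses/fertile block ends and a non-fertile gap has occurred)
last_dry_prepeak_day <- function(statuses) {
  s <- statuses$status
  nf <- which(s == "NON_FERTILE")
  if (length(nf) == 0L) return(NA_integer_)
  first_nf <- nf[1]
  window_start <- which(s == "FERTILE" & statuses$day_of_cycle > first_nf)
  if (length(window_start) == 0L) return(NA_integer_)
  cand <- window_start[1] - 1L
  if (s[cand] == "NON_FERTILE") statuses$day_of_cycle[cand] else NA_integer_
}

#' Correct-use cascade table
#'
#' Aggregates per-cycle correct-use classifications into the category x
#' level table: couples, cycles and pregnancies per cell, mirroring the
#' progressive restriction cascade (level 1: eligible couple, complete
#' chart, intercourse present; level 2: satisfactory teacher assessment;
#' level 3: no condoms/withdrawal or nonstandard chart).
#'
#' @param cycle_info data.frame with one row per eligible classified cycle:
#'   `couple_id`, `cycle_index`, `pregnancy`, `l2`, `l3`, and one logical
#'   column per category name in `CORRECT_USE_CATEGORIES`
#' @return data.frame (class `crms_correct_use_table`): `category`,
#'   `level`, `couples`, `cycles`, `pregnancies`
#' @export
correct_use_table <- function(cycle_info) {
  rows <- list()
  for (cat in CORRECT_USE_CATEGORIES) {
    in_cat <- if (cat %in% names(cycle_info)) cycle_info[[cat]] else
      rep(FALSE, nrow(cycle_info))
    for (lev in 1:3) {
      keep <- in_cat &
        (lev < 2 | cycle_info$l2) &
        (lev < 3 | cycle_info$l3)
      sub <- cycle_info[keep, , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(category = cat, level = lev,
                   couples = length(unique(sub$couple_id)),
                   cycles = nrow(sub),
                   pregnancies = sum(sub$pregnancy),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("crms_correct_use_table", "data.frame")
  out
}
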