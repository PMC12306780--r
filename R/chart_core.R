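# Day-level data model for standardized CrMS fertility charts, the
# day-fertility classifier, peak-day identification, cycle-length
# imputation and pregnancy-surveillance flags.

BLEEDING_CODES  <- c("H", "M", "L", "VL", "B", "none")
DISCHARGE_CODES <- c("dry", "non-peak-mucus", "peak-type-mucus", "unobserved")
OBSFREQ_CODES   <- c("x1", "x2", "x3", "AD", "none")
STATUS_LEVELS   <- c("FERTILE", "NON_FERTILE", "UNKNOWN")

#' Default day-classification rule table
#'
#' The rule table is data, not code: it parameterises how charted
#' observations map to day fertility status so that alternative published
#' rule sets can be swapped in without touching the classifier.  Defaults
#' follow standard CrMS instruction: menses-bleeding days are fertile;
#' pre-peak dry days are non-fertile with intercourse restricted to the end
#' of the day; any mucus day is fertile, and the `count_of_three` days
#' following a pre-peak non-peak-mucus patch are fertile; the peak day and
#' the three days after it are fertile; Peak+4 is non-fertile end-of-day
#' only; Peak+5 onward dry days are non-fertile; days lacking a usable
#' observation are of unknown fertility.
#'
#' @param version rule-set version string, logged with every run
#' @param menses_codes bleeding codes treated as menses (fertile)
#' @param count_of_three days of fertility following a pre-peak
#'   non-peak-mucus patch
#' @param peak_plus_fertile days after the peak day still counted fertile
#' @param peak_plus_end_of_day the post-peak day on which intercourse is
#'   restricted to the end of the day (Peak+4 under CrMS instruction)
#' @return a `crms_rules` list
#' @export
default_rule_table <- function(version = "crms-default-1.0",
                               menses_codes = c("H", "M", "L"),
                               count_of_three = 3L,
                               peak_plus_fertile = 3L,
                               peak_plus_end_of_day = 4L) {
  structure(list(version = version,
                 menses_codes = menses_codes,
                 count_of_three = as.integer(count_of_three),
                 peak_plus_fertile = as.integer(peak_plus_fertile),
                 peak_plus_end_of_day = as.integer(peak_plus_end_of_day)),
            class = "crms_rules")
}

#' Write / read a rule table as a versioned key-value config file
#'
#' Plain `key = value` text; vector values are comma-joined.
#'
#' @param rules a `crms_rules` object
#' @param path file path
#' @return `read_rule_table` returns a `crms_rules` object
#' @export
write_rule_table <- function(rules, path) {
  stopifnot(inherits(rules, "crms_rules"))
  lines <- vapply(names(rules), function(k) {
    sprintf("%s = %s", k, paste(rules[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rule_table
#' @export
read_rule_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[[1]])
    val <- strsplit(trimws(paste(p[-1], collapse = "=")), ",", fixed = TRUE)[[1]]
    val <- trimws(val)
    num <- suppressWarnings(as.integer(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  structure(out, class = "crms_rules")
}

validate_day_codes <- function(days) {
  bad <- !(days$bleeding %in% BLEEDING_CODES) |
    !(days$discharge %in% DISCHARGE_CODES) |
    !(days$observation_frequency %in% OBSFREQ_CODES)
  if (any(bad)) {
    stop_crms(sprintf("invalid observation code on day(s) %s",
                      paste(days$day_of_cycle[bad], collapse = ", ")),
              "crms_invalid_code")
  }
  eod_bad <- !is.na(days$intercourse_end_of_day) & !days$intercourse
  if (any(eod_bad)) {
    stop_crms("intercourse_end_of_day set on a day without intercourse",
              "crms_invalid_code")
  }
  invisible(TRUE)
}

#' Construct a couple-cycle
#'
#' One menstrual cycle for one couple: an ordered block of charted day
#' records (possibly empty for questionnaire-only or imputed cycles),
#' provenance of the information, and the identified peak day.
#'
#' @param couple_id couple identifier
#' @param cycle_index 1-based ordinal of the cycle within the couple
#' @param days data.frame of day records (columns `day_of_cycle`,
#'   `bleeding`, `discharge`, `observation_frequency`, `intercourse`,
#'   `intercourse_end_of_day`), or NULL for chart-less cycles
#' @param length_days cycle length; defaults to `nrow(days)` when charted
#' @param start_date cycle start (integer day offset or Date)
#' @param source one of `"CHART_AND_SOC"`, `"CHART_ONLY"`, `"SOC_ONLY"`,
#'   `"IMPUTED"`
#' @param peak_day identified peak day, or NA to identify from the chart
#' @param pregnancy_in_cycle did a conception occur in this cycle
#' @return a `crms_cycle` object
#' @export
crms_cycle <- function(couple_id, cycle_index, days = NULL,
                       length_days = if (!is.null(days)) nrow(days) else NA_integer_,
                       start_date = NA_integer_,
                       source = c("CHART_AND_SOC", "CHART_ONLY", "SOC_ONLY", "IMPUTED"),
                       peak_day = NA_integer_,
                       pregnancy_in_cycle = FALSE) {
  source <- match.arg(source)
  has_chart <- source %in% c("CHART_AND_SOC", "CHART_ONLY")
  if (has_chart) {
    stopifnot(is.data.frame(days), nrow(days) >= 1)
    days <- days[order(days$day_of_cycle), , drop = FALSE]
    if (!all(days$day_of_cycle == seq_len(nrow(days)))) {
      stop_crms("charted days must cover 1..length_days exactly", "crms_bad_cycle")
    }
    if (is.na(length_days)) length_days <- nrow(days)
    if (length_days != nrow(days)) {
      stop_crms("length_days must equal the charted day count", "crms_bad_cycle")
    }
    validate_day_codes(days)
  } else if (!is.null(days) && nrow(days) > 0 && source == "IMPUTED") {
    stop_crms("imputed cycles carry no day records", "crms_bad_cycle")
  }
  if (!is.na(peak_day) && (peak_day < 1 || peak_day > length_days)) {
    stop_crms("peak_day outside 1..length_days", "crms_bad_cycle")
  }
  structure(list(couple_id = couple_id,
                 cycle_index = as.integer(cycle_index),
                 start_date = start_date,
                 length_days = as.integer(length_days),
                 days = days,
                 peak_day = as.integer(peak_day),
                 source = source,
                 pregnancy_in_cycle = isTRUE(pregnancy_in_cycle)),
            class = "crms_cycle")
}

has_chart <- function(cycle) cycle$source %in% c("CHART_AND_SOC", "CHART_ONLY")

#' Is a charted day a peak-type (estrogenic) mucus day?
#'
#' @param day one day record (list or single data.frame row) with a
#'   `discharge` field
#' @return logical
#' @export
is_peak_type_mucus <- function(day) {
  d <- if (is.data.frame(day)) day$discharge[[1]] else day$discharge
  if (is.na(d) || identical(d, "unobserved")) {
    stop_crms("discharge unobserved on this day", "crms_unobserved")
  }
  identical(d, "peak-type-mucus")
}

#' Identify the peak day of a cycle
#'
#' The peak day is the last day of peak-type mucus in the cycle.  When the
#' peak-type days form more than one separated run, the latest day is still
#' returned but the result carries a `possible_double_peak` attribute so
#' stress-cycle double peaks can be surfaced downstream.
#'
#' @param cycle a `crms_cycle` with chart data
#' @return integer day of cycle (NA if no peak-type mucus observed), with
#'   attribute `possible_double_peak`
#' @export
identify_peak_day <- function(cycle) {
  if (!has_chart(cycle)) stop_crms("cycle has no chart data", "crms_no_chart")
  pk <- which(cycle$days$discharge == "peak-type-mucus")
  if (length(pk) == 0L) {
    return(structure(NA_integer_, possible_double_peak = FALSE))
  }
  runs <- sum(diff(pk) > 1L) + 1L
  structure(as.integer(max(pk)), possible_double_peak = runs > 1L)
}

# a day has a usable observation if discharge was observed, or bleeding is
# a menses-grade code (menses days are classified from bleeding alone)
day_observed <- function(days, rules) {
  days$discharge != "unobserved" | days$bleeding %in% rules$menses_codes
}

#' Classify each charted day as fertile, non-fertile, or unknown
#'
#' Applies the rule table to a charted cycle and returns one status per
#' day.  Days lacking a usable observation are UNKNOWN (missing
#' information).  Pre-peak dry days and Peak+4 are non-fertile only from
#' the end of the day; the returned `end_of_day_only` column marks them so
#' that intercourse timing ambiguity can be handled downstream.
#'
#' @param cycle a `crms_cycle` with chart data
#' @param rules a `crms_rules` rule table
#' @param peak_day override the peak day; defaults to the cycle's recorded
#'   peak or, failing that, [identify_peak_day()]
#' @return data.frame with columns `day_of_cycle`, `status` (one of
#'   FERTILE / NON_FERTILE / UNKNOWN) and `end_of_day_only` (logical)
#' @export
classify_days <- function(cycle, rules = default_rule_table(), peak_day = NULL) {
  if (!has_chart(cycle)) stop_crms("cycle has no chart data", "crms_no_chart")
  days <- cycle$days
  validate_day_codes(days)
  n <- nrow(days)
  if (is.null(peak_day)) {
    peak_day <- if (!is.na(cycle$peak_day)) cycle$peak_day
                else as.integer(identify_peak_day(cycle))
  }
  observed <- day_observed(days, rules)
  status <- rep("NON_FERTILE", n)
  eod <- rep(FALSE, n)

  menses <- days$bleeding %in% rules$menses_codes
  mucus_peak <- observed & days$discharge == "peak-type-mucus"
  mucus_nonpeak <- observed & days$discharge == "non-peak-mucus"
  d <- days$day_of_cycle
  pre_peak <- if (is.na(peak_day)) rep(TRUE, n) else d < peak_day

  # count-of-three: days following a pre-peak non-peak-mucus patch
  count3 <- rep(FALSE, n)
  if (rules$count_of_three > 0L) {
    src <- which(mucus_nonpeak & pre_peak)
    for (s in src[src < n]) {
      idx <- (s + 1L):min(n, s + rules$count_of_three)
      count3[idx[pre_peak[idx]]] <- TRUE
    }
  }

  fertile <- menses | mucus_peak | mucus_nonpeak | (count3 & observed)
  if (!is.na(peak_day)) {
    fertile <- fertile | (observed & d >= peak_day &
                            d <= peak_day + rules$peak_plus_fertile)
  }
  status[fertile] <- "FERTILE"
  status[!observed] <- "UNKNOWN"

  nf <- status == "NON_FERTILE"
  if (is.na(peak_day)) {
    eod[nf] <- TRUE   # all non-fertile days are pre-peak-style without a peak
  } else {
    eod[nf & d < peak_day] <- TRUE
    eod[nf & d == peak_day + rules$peak_plus_end_of_day] <- TRUE
  }
  data.frame(day_of_cycle = d, status = status, end_of_day_only = eod,
             stringsAsFactors = FALSE)
}

#' Impute a cycle length from a woman's observed lengths
#'
#' Median of the available observed lengths, rounded half-up to an integer
#' day count.
#'
#' @param history numeric vector of observed cycle lengths for the woman
#' @return integer length in days
#' @export
impute_cycle_length <- function(history) {
  history <- history[!is.na(history)]
  if (length(history) == 0L) {
    stop_crms("no cycle lengths available for imputation", "crms_no_lengths")
  }
  as.integer(floor(stats::median(history) + 0.5))
}

#' Flag a cycle for pregnancy surveillance
#'
#' A cycle is flagged when the charted post-peak phase reaches the
#' threshold (a lengthened luteal phase), or when the start of the next
#' cycle is delayed past the expected start by at least the delay
#' threshold.  With no identified peak the surveillance falls back to the
#' menses-delay criterion alone, and signals if that is unavailable too.
#'
#' @param cycle a `crms_cycle`
#' @param postpeak_threshold_days charted post-peak days triggering the
#'   flag (default 17)
#' @param next_start_delay_days observed delay of next menses vs expected,
#'   in days; NA when unknown
#' @param delay_threshold_days menses delay triggering the flag (default 7)
#' @return logical
#' @export
flag_possible_pregnancy <- function(cycle, postpeak_threshold_days = 17L,
                                    next_start_delay_days = NA_real_,
                                    delay_threshold_days = 7L) {
  delay_hit <- !is.na(next_start_delay_days) &&
    next_start_delay_days >= delay_threshold_days
  if (is.na(cycle$peak_day)) {
    if (is.na(next_start_delay_days)) {
      stop_crms("peak day unknown and no menses-delay information",
                "crms_peak_unknown")
    }
    return(delay_hit)
  }
  postpeak <- cycle$length_days - cycle$peak_day
  postpeak >= postpeak_threshold_days || delay_hit
}

# ---- chart file round-trip ------------------------------------------------

CHART_COLS <- c("couple_id", "cycle_index", "day_of_cycle", "bleeding",
                "discharge", "observation_frequency", "intercourse",
                "intercourse_end_of_day")

#' Read / write chart files
#'
#' Tab-delimited, one day record per row, header required; missing codes
#' written as ".".  Reader and writer round-trip exactly.
#'
#' @param path file path
#' @param chart data.frame of day records with the chart columns
#' @return `read_chart_file` returns a data.frame of day records
#' @export
read_chart_file <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  missing_cols <- setdiff(CHART_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop_crms(sprintf("chart file %s lacks column(s): %s", path,
                      paste(missing_cols, collapse = ", ")), "crms_bad_file")
  }
  df$cycle_index <- as.integer(df$cycle_index)
  df$day_of_cycle <- as.integer(df$day_of_cycle)
  df$intercourse <- df$intercourse == "1"
  df$intercourse_end_of_day <- ifelse(df$intercourse_end_of_day == ".",
                                      NA, df$intercourse_end_of_day == "1")
  df[, CHART_COLS]
}

#' @rdname read_chart_file
#' @export
write_chart_file <- function(chart, path) {
  out <- chart[, CHART_COLS]
  out$intercourse <- ifelse(out$intercourse, "1", "0")
  out$intercourse_end_of_day <- ifelse(is.na(out$intercourse_end_of_day), ".",
                                       ifelse(out$intercourse_end_of_day, "1", "0"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble couple-cycles from a long chart data.frame
#'
#' @param chart data.frame of day records (chart columns)
#' @param pregnancies optional data.frame (`couple_id`, `cycle_index`) of
#'   conception cycles
#' @param source provenance label applied to every produced cycle
#' @return list of `crms_cycle` objects, peak days identified
#' @export
chart_to_cycles <- function(chart, pregnancies = NULL, source = "CHART_AND_SOC") {
  preg_key <- if (!is.null(pregnancies)) {
    paste(pregnancies$couple_id, pregnancies$cycle_index)
  } else character(0)
  key <- interaction(chart$couple_id, chart$cycle_index, drop = TRUE)
  lapply(split(chart, key), function(block) {
    cyc <- crms_cycle(couple_id = block$couple_id[[1]],
                      cycle_index = block$cycle_index[[1]],
                      days = block[, setdiff(CHART_COLS, c("couple_id", "cycle_index"))],
                      source = source,
                      pregnancy_in_cycle =
                        paste(block$couple_id[[1]], block$cycle_index[[1]]) %in% preg_key)
    cyc$peak_day <- as.integer(identify_peak_day(cyc))
    cyc
  })
}
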