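# Deterministic rule engine assigning CrMS pregnancy classifications from
# structured pregnancy-evaluation findings, with reason codes.

#' CrMS pregnancy classification categories
#'
#' @format character vector of length 7
#' @export
CRMS_CATEGORIES <- c("ACHIEVING", "METHOD", "USING", "TEACHING",
                     "USING_TEACHING", "UNRESOLVED", "NON_CRMS")

#' Teaching-deficiency reason codes
#'
#' @format character vector
#' @export
TEACHING_DEFICIENCY_CODES <- c("followup_schedule", "uncorrected_charting",
                               "advanced_too_fast", "unclear_instructions",
                               "yellow_stamp_protocol",
                               "incomplete_documentation")

#' Achieving-behavior reason codes
#'
#' Evaluation flags marking conception-oriented behaviors (negotiated-down
#' observations, special occasions, knowingly taking a chance, and so on).
#'
#' @format character vector
#' @export
ACHIEVING_FLAG_CODES <- c("negotiated_down", "special_occasion",
                          "taking_a_chance", "followup_indicated_trying",
                          "incomplete_charting_knowing",
                          "missed_observations_knowing")

#' Construct a structured pregnancy evaluation
#'
#' Fields mirror the vocabulary of the standardized CrMS pregnancy review:
#' whether and where intercourse fell relative to identified fertility,
#' end-of-day timing ambiguity, charting and interpretation errors,
#' teaching deficiencies, barrier/withdrawal involvement, and whether the
#' available information suffices for classification.
#'
#' @param couple_id,cycle_index identifiers
#' @param evaluation_done was a pregnancy evaluation completed
#' @param intercourse_on_known_fertile TRUE / FALSE / NA (unknown)
#' @param fertile_day_type `"peak_type_or_count3"`, `"other_fertile"`,
#'   `"none"`, or `"unknown"`
#' @param end_of_day_ambiguous intercourse on an end-of-day-only
#'   non-fertile day (pre-peak or Peak+4) with unknown time of day
#' @param charting_errors `"none"`, `"user_error"`, or
#'   `"multiple_significant"`
#' @param misinterpretation fertile day misread as non-fertile
#' @param double_peak_missed unrecognized double peak (stress cycle)
#' @param teaching_deficiencies character subset of the teaching
#'   deficiency codes
#' @param achieving_flags character subset of the achieving-behavior codes
#'   (negotiated-down observations, special occasion, taking a chance, ...)
#' @param barrier_or_withdrawal_on_fertile TRUE / FALSE / NA (barrier used
#'   but fertile-day involvement unclear)
#' @param barrier_or_withdrawal_used any condom/withdrawal use in the
#'   conception cycle
#' @param info_sufficient is the information sufficient to classify
#' @param external_documentation documentation available despite no formal
#'   evaluation
#' @return a `crms_pregnancy_evaluation` list
#' @export
pregnancy_evaluation <- function(couple_id, cycle_index,
                                 evaluation_done = TRUE,
                                 intercourse_on_known_fertile = NA,
                                 fertile_day_type = c("none", "peak_type_or_count3",
                                                      "other_fertile", "unknown"),
                                 end_of_day_ambiguous = FALSE,
                                 charting_errors = c("none", "user_error",
                                                     "multiple_significant"),
                                 misinterpretation = FALSE,
                                 double_peak_missed = FALSE,
                                 teaching_deficiencies = character(0),
                                 achieving_flags = character(0),
                                 barrier_or_withdrawal_on_fertile = FALSE,
                                 barrier_or_withdrawal_used = FALSE,
                                 info_sufficient = TRUE,
                                 external_documentation = FALSE) {
  fertile_day_type <- match.arg(fertile_day_type)
  charting_errors <- match.arg(charting_errors)
  stopifnot(all(teaching_deficiencies %in% TEACHING_DEFICIENCY_CODES),
            all(achieving_flags %in% ACHIEVING_FLAG_CODES))
  if (!evaluation_done && !external_documentation) info_sufficient <- FALSE
  if (identical(intercourse_on_known_fertile, FALSE) &&
      fertile_day_type %in% c("peak_type_or_count3", "other_fertile")) {
    stop_crms("inconsistent evaluation: fertile_day_type set with no fertile intercourse",
              "crms_inconsistent_evaluation")
  }
  structure(list(couple_id = couple_id, cycle_index = as.integer(cycle_index),
                 evaluation_done = evaluation_done,
                 intercourse_on_known_fertile = intercourse_on_known_fertile,
                 fertile_day_type = fertile_day_type,
                 end_of_day_ambiguous = end_of_day_ambiguous,
                 charting_errors = charting_errors,
                 misinterpretation = misinterpretation,
                 double_peak_missed = double_peak_missed,
                 teaching_deficiencies = teaching_deficiencies,
                 achieving_flags = achieving_flags,
                 barrier_or_withdrawal_on_fertile = barrier_or_withdrawal_on_fertile,
                 barrier_or_withdrawal_used = barrier_or_withdrawal_used,
                 info_sufficient = info_sufficient,
                 external_documentation = external_documentation),
            class = "crms_pregnancy_evaluation")
}

#' Classify a pregnancy into its CrMS category
#'
#' Fixed precedence: (1) any condom/withdrawal use on fertile days — or
#' barrier use whose fertile-day involvement cannot be excluded — makes
#' the pregnancy not CrMS-related; (2) insufficient information is
#' unresolved; (3) intercourse on known fertile days, or achieving
#' behaviors (including end-of-day-ambiguous acts accompanied by achieving
#' behaviors), is achieving-related; (4) end-of-day ambiguity without
#' achieving behaviors is unresolved (could be method-, achieving- or
#' using-related depending on the unknown timing); (5) misinterpretation,
#' missed double peak, or multiple significant charting errors are
#' using-related; (6) contributory teaching deficiencies are
#' teaching-related (co-assigned with using as using/teaching); (7) with
#' all instructions followed, conception from outside the identified
#' fertile window is method-related.
#'
#' @param e a `crms_pregnancy_evaluation`
#' @return list with `category` (one primary CrMS category) and `reasons`
#'   (character reason codes)
#' @export
classify_pregnancy <- function(e) {
  stopifnot(inherits(e, "crms_pregnancy_evaluation"))
  reasons <- character(0)

  bw <- e$barrier_or_withdrawal_on_fertile
  if (isTRUE(bw)) {
    return(list(category = "NON_CRMS",
                reasons = "condoms or withdrawal used on fertile day(s)"))
  }
  if (is.na(bw) && isTRUE(e$barrier_or_withdrawal_used)) {
    return(list(category = "NON_CRMS",
                reasons = "condom/withdrawal used in cycle, unclear whether on fertile days"))
  }
  if (!isTRUE(e$info_sufficient)) {
    r <- if (!e$evaluation_done)
      "no pregnancy evaluation done, and insufficient other information"
    else "insufficient information for classification"
    return(list(category = "UNRESOLVED", reasons = r))
  }
  achieving <- isTRUE(e$intercourse_on_known_fertile) ||
    length(e$achieving_flags) > 0
  if (achieving) {
    if (isTRUE(e$intercourse_on_known_fertile)) {
      reasons <- c(reasons, switch(e$fertile_day_type,
        peak_type_or_count3 = "intercourse on known fertile days (peak-type mucus or within count of 3)",
        other_fertile = "intercourse on known fertile days of other type",
        unknown = "intercourse on known fertile day(s), details unavailable",
        none = "intercourse on known fertile day(s)"))
    }
    if (isTRUE(e$end_of_day_ambiguous)) {
      reasons <- c(reasons, "intercourse before end of day on an end-of-day-only day")
    }
    reasons <- c(reasons, e$achieving_flags)
    return(list(category = "ACHIEVING", reasons = reasons))
  }
  if (isTRUE(e$end_of_day_ambiguous)) {
    return(list(category = "UNRESOLVED",
                reasons = "unknown whether intercourse on end-of-day-only day occurred earlier or at end of day"))
  }
  using <- isTRUE(e$misinterpretation) || isTRUE(e$double_peak_missed) ||
    identical(e$charting_errors, "multiple_significant")
  if (using) {
    if (isTRUE(e$misinterpretation))
      reasons <- c(reasons, "misinterpreted a fertile day as non-fertile")
    if (isTRUE(e$double_peak_missed))
      reasons <- c(reasons, "did not recognize double peak (stress cycle)")
    if (identical(e$charting_errors, "multiple_significant"))
      reasons <- c(reasons, "multiple significant errors in charting")
  }
  teaching <- length(e$teaching_deficiencies) > 0
  if (teaching) reasons <- c(reasons, e$teaching_deficiencies)
  if (using && teaching) return(list(category = "USING_TEACHING", reasons = reasons))
  if (using) return(list(category = "USING", reasons = reasons))
  if (teaching) return(list(category = "TEACHING", reasons = reasons))
  list(category = "METHOD",
       reasons = "all instructions followed; conception from outside the identified fertile window")
}

#' Summarise classified pregnancies
#'
#' @param evaluations list of `crms_pregnancy_evaluation` objects
#' @return list: `counts` named integer vector over the CrMS categories
#'   (all categories present, zero-filled), `reasons` data.frame of
#'   category/reason frequencies (one pregnancy may carry several reasons),
#'   `assignments` data.frame of per-pregnancy categories
#' @export
classification_summary <- function(evaluations) {
  counts <- stats::setNames(integer(length(CRMS_CATEGORIES)), CRMS_CATEGORIES)
  if (length(evaluations) == 0L) {
    return(list(counts = counts,
                reasons = data.frame(category = character(), reason = character(),
                                     n = integer()),
                assignments = data.frame(couple_id = character(),
                                         cycle_index = integer(),
                                         category = character())))
  }
  cls <- lapply(evaluations, classify_pregnancy)
  cats <- vapply(cls, `[[`, character(1), "category")
  tab <- table(factor(cats, levels = CRMS_CATEGORIES))
  counts[names(tab)] <- as.integer(tab)
  reason_rows <- do.call(rbind, Map(function(c1, e) {
    # a using/teaching pregnancy is echoed once in each reason family
    fam <- if (c1$category == "USING_TEACHING") c("USING", "TEACHING")
           else c1$category
    do.call(rbind, lapply(fam, function(f) {
      rs <- c1$reasons
      if (c1$category == "USING_TEACHING") {
        rs <- if (f == "TEACHING") rs[rs %in% TEACHING_DEFICIENCY_CODES]
              else rs[!(rs %in% TEACHING_DEFICIENCY_CODES)]
      }
      if (length(rs) == 0L) return(NULL)
      data.frame(category = f, reason = rs, stringsAsFactors = FALSE)
    }))
  }, cls, evaluations))
  reasons <- stats::aggregate(n ~ category + reason,
                              data = transform(reason_rows, n = 1L), FUN = sum)
  assignments <- data.frame(
    couple_id = vapply(evaluations, function(e) as.character(e$couple_id), character(1)),
    cycle_index = vapply(evaluations, function(e) e$cycle_index, integer(1)),
    category = cats, stringsAsFactors = FALSE)
  list(counts = counts, reasons = reasons, assignments = assignments)
}

# ---- evaluation file round-trip -------------------------------------------

EVAL_COLS <- c("couple_id", "cycle_index", "evaluation_done",
               "intercourse_on_known_fertile", "fertile_day_type",
               "end_of_day_ambiguous", "charting_errors", "misinterpretation",
               "double_peak_missed", "teaching_deficiencies", "achieving_flags",
               "barrier_or_withdrawal_on_fertile", "barrier_or_withdrawal_used",
               "info_sufficient", "external_documentation")

eval_to_row <- function(e) {
  tri <- function(x) if (is.na(x)) "." else if (x) "1" else "0"
  data.frame(couple_id = as.character(e$couple_id),
             cycle_index = e$cycle_index,
             evaluation_done = tri(e$evaluation_done),
             intercourse_on_known_fertile = tri(e$intercourse_on_known_fertile),
             fertile_day_type = e$fertile_day_type,
             end_of_day_ambiguous = tri(e$end_of_day_ambiguous),
             charting_errors = e$charting_errors,
             misinterpretation = tri(e$misinterpretation),
             double_peak_missed = tri(e$double_peak_missed),
             teaching_deficiencies = if (length(e$teaching_deficiencies))
               paste(e$teaching_deficiencies, collapse = ";") else ".",
             achieving_flags = if (length(e$achieving_flags))
               paste(e$achieving_flags, collapse = ";") else ".",
             barrier_or_withdrawal_on_fertile = tri(e$barrier_or_withdrawal_on_fertile),
             barrier_or_withdrawal_used = tri(e$barrier_or_withdrawal_used),
             info_sufficient = tri(e$info_sufficient),
             external_documentation = tri(e$external_documentation),
             stringsAsFactors = FALSE)
}

#' Write / read pregnancy evaluation files
#'
#' Tab-delimited; tri-state logicals as 1/0/"."; code sets
#' semicolon-joined.  Round-trips to identical classifications.
#'
#' @param evaluations list of `crms_pregnancy_evaluation` objects
#' @param path file path
#' @return `read_evaluation_file` returns a list of evaluations
#' @export
write_evaluation_file <- function(evaluations, path) {
  rows <- do.call(rbind, lapply(evaluations, eval_to_row))
  if (is.null(rows)) {
    rows <- stats::setNames(data.frame(matrix(ncol = length(EVAL_COLS), nrow = 0)),
                            EVAL_COLS)
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evaluation_file
#' @export
read_evaluation_file <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  untri <- function(x) if (x == ".") NA else x == "1"
  unset <- function(x) if (x == ".") character(0) else
    strsplit(x, ";", fixed = TRUE)[[1]]
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pregnancy_evaluation(
      couple_id = r$couple_id, cycle_index = as.integer(r$cycle_index),
      evaluation_done = isTRUE(untri(r$evaluation_done)),
      intercourse_on_known_fertile = untri(r$intercourse_on_known_fertile),
      fertile_day_type = r$fertile_day_type,
      end_of_day_ambiguous = isTRUE(untri(r$end_of_day_ambiguous)),
      charting_errors = r$charting_errors,
      misinterpretation = isTRUE(untri(r$misinterpretation)),
      double_peak_missed = isTRUE(untri(r$double_peak_missed)),
      teaching_deficiencies = unset(r$teaching_deficiencies),
      achieving_flags = unset(r$achieving_flags),
      barrier_or_withdrawal_on_fertile = untri(r$barrier_or_withdrawal_on_fertile),
      barrier_or_withdrawal_used = isTRUE(untri(r$barrier_or_withdrawal_used)),
      info_sufficient = isTRUE(untri(r$info_sufficient)),
      external_documentation = isTRUE(untri(r$external_documentation)))
  })
}
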