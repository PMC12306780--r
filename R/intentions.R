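# Start-of-cycle (SOC) questionnaire model: the 6-level pregnancy-intention
# scale, couple "most achieving" reconciliation, prospective-window
# filtering, collapsing schemes, and the partner concordance table.

#' The ordered 6-level pregnancy-intention scale
#'
#' Levels in ascending "achieving" order: planning to abstain ranks least
#' achieving, trying as hard as possible to conceive ranks most achieving.
#' Couple reconciliation takes the maximum of the two partners under this
#' order.
#'
#' @return character vector of level names, least to most achieving
#' @export
intention_levels <- function() {
  c("ABSTAIN", "TRYING_HARD_AVOID", "AVOID", "NEUTRAL",
    "CONCEIVE", "TRYING_HARD_CONCEIVE")
}

intention_rank <- function(x) match(x, intention_levels())

#' Reconcile the couple-cycle intention from the two partners
#'
#' When partners disagree, the "most achieving" response is used; when only
#' one partner responded, that response is used.  Both missing signals an
#' error unless `require_any = FALSE`, in which case NA is returned (used
#' by the pipeline, which reports such cycles as excluded).
#'
#' @param female,male intention level names (vectors recycle)
#' @param require_any error on pairs with both values missing
#' @return character vector of reconciled levels
#' @export
reconcile_couple_intention <- function(female, male, require_any = TRUE) {
  rf <- intention_rank(female)
  rm_ <- intention_rank(male)
  both_na <- is.na(rf) & is.na(rm_)
  if (require_any && any(both_na)) {
    stop_crms("no intention available from either partner", "crms_no_intention")
  }
  r <- pmax(rf, rm_, na.rm = TRUE)
  out <- intention_levels()[r]
  out[both_na] <- NA_character_
  out
}

#' Keep only prospectively completed SOC responses
#'
#' Retains responses completed within the first `window_days` days of the
#' cycle.  `window_days = Inf` reproduces the "all questionnaires"
#' sensitivity arm (identity).
#'
#' @param responses data.frame with a `completion_day` column
#' @param window_days window in days from cycle start (default 11)
#' @return filtered data.frame
#' @export
filter_prospective <- function(responses, window_days = 11) {
  responses[responses$completion_day <= window_days, , drop = FALSE]
}

#' Drop duplicate SOC responses, keeping the earliest per partner-cycle
#'
#' @param responses data.frame with `couple_id`, `cycle_index`, `partner`,
#'   `completion_day`
#' @return data.frame with one row per couple-cycle-partner
#' @export
dedupe_soc <- function(responses) {
  o <- order(responses$couple_id, responses$cycle_index, responses$partner,
             responses$completion_day)
  responses <- responses[o, , drop = FALSE]
  key <- paste(responses$couple_id, responses$cycle_index, responses$partner)
  responses[!duplicated(key), , drop = FALSE]
}

#' Collapse 6-level intentions into reporting groups
#'
#' `four_group` combines the two conceive levels into Achieving and the
#' two avoid levels into Avoiding (partner-concordance reporting).
#' `lifetable` additionally classifies the undecided with trying to
#' conceive (life-table stratification).
#'
#' @param level intention level names
#' @param scheme `"four_group"` or `"lifetable"`
#' @return character vector of group labels
#' @export
collapse_intentions <- function(level, scheme = c("four_group", "lifetable")) {
  scheme <- match.arg(scheme)
  if (anyNA(intention_rank(level))) {
    stop_crms("missing intention cannot be collapsed", "crms_missing_intention")
  }
  maps <- list(
    four_group = c(TRYING_HARD_CONCEIVE = "Achieving", CONCEIVE = "Achieving",
                   NEUTRAL = "Neutral", AVOID = "Avoiding",
                   TRYING_HARD_AVOID = "Avoiding", ABSTAIN = "Abstaining"),
    lifetable = c(TRYING_HARD_CONCEIVE = "Conceive", CONCEIVE = "Conceive",
                  NEUTRAL = "Conceive", AVOID = "Avoiding",
                  TRYING_HARD_AVOID = "Avoiding", ABSTAIN = "Abstain"))
  unname(maps[[scheme]][level])
}

four_group_levels <- c("Achieving", "Neutral", "Avoiding", "Abstaining")

#' Build couple-cycle intentions from SOC responses
#'
#' Deduplicates (earliest response per partner-cycle), optionally restricts
#' to the prospective window, and reconciles the two partners.
#'
#' @param soc data.frame of SOC responses (`couple_id`, `cycle_index`,
#'   `partner` in F/M, `completion_day`, `intention`)
#' @param window_days prospective window; `Inf` keeps all responses
#' @return data.frame with `couple_id`, `cycle_index`, `female`, `male`,
#'   `reconciled`, `prospective`
#' @export
build_couple_cycle_intentions <- function(soc, window_days = 11) {
  soc <- dedupe_soc(soc)
  soc <- filter_prospective(soc, window_days)
  key <- interaction(soc$couple_id, soc$cycle_index, drop = TRUE)
  rows <- lapply(split(soc, key), function(block) {
    f <- block$intention[block$partner == "F"]
    m <- block$intention[block$partner == "M"]
    data.frame(couple_id = block$couple_id[[1]],
               cycle_index = block$cycle_index[[1]],
               female = if (length(f)) f[[1]] else NA_character_,
               male = if (length(m)) m[[1]] else NA_character_,
               latest_completion = max(block$completion_day),
               stringsAsFactors = FALSE)
  })
  out <- rbind_all(rows)
  if (is.null(out)) {
    out <- data.frame(couple_id = character(), cycle_index = integer(),
                      female = character(), male = character(),
                      latest_completion = integer())
  }
  out$reconciled <- reconcile_couple_intention(out$female, out$male,
                                               require_any = FALSE)
  # prospective = every used response completed within the primary 11-day
  # window, regardless of the filtering arm in force
  out$prospective <- out$latest_completion <= 11
  out$latest_completion <- NULL
  out[order(out$couple_id, out$cycle_index), , drop = FALSE]
}

#' Partner concordance of cycle pregnancy intentions
#'
#' Collapses each partner's intention to the four reporting groups and
#' cross-tabulates female (rows) against male (columns); cycles missing
#' either partner are excluded and counted.  Concordance is the diagonal
#' share of included cycles.
#'
#' @param cycles data.frame with `female` and `male` 6-level intentions
#' @return object of class `crms_concordance`: list with `matrix` (4x4
#'   counts), `concordance`, `n_included`, `n_excluded`
#' @export
concordance_table <- function(cycles) {
  if (nrow(cycles) == 0L) stop_crms("no intention data", "crms_no_data")
  ok <- !is.na(intention_rank(cycles$female)) & !is.na(intention_rank(cycles$male))
  inc <- cycles[ok, , drop = FALSE]
  if (nrow(inc) == 0L) stop_crms("no cycles with both partners responding",
                                 "crms_no_data")
  f <- factor(collapse_intentions(inc$female), levels = four_group_levels)
  m <- factor(collapse_intentions(inc$male), levels = four_group_levels)
  mat <- table(Female = f, Male = m)
  concordance_from_matrix(unclass(mat), n_excluded = sum(!ok))
}

#' Concordance summary from a 4x4 count matrix
#'
#' @param mat square count matrix, female rows by male columns
#' @param n_excluded count of cycles excluded for missing responses
#' @return a `crms_concordance` object
#' @export
concordance_from_matrix <- function(mat, n_excluded = 0L) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  total <- sum(mat)
  structure(list(matrix = mat,
                 agree = sum(diag(mat)),
                 n_included = total,
                 n_excluded = n_excluded,
                 concordance = sum(diag(mat)) / total),
            class = "crms_concordance")
}

#' @export
print.crms_concordance <- function(x, ...) {
  cat(sprintf("Couple-cycle intention concordance: %s%% (%d/%d agree; %d cycles excluded)\n",
              fmt_pct(x$agree, x$n_included), x$agree, x$n_included, x$n_excluded))
  print(x$matrix)
  invisible(x)
}

# ---- SOC file round-trip --------------------------------------------------

SOC_COLS <- c("couple_id", "cycle_index", "partner", "completion_day",
              "intention", "prior_cycle_methods")

#' Read / write SOC questionnaire files
#'
#' Tab-delimited, one response per row; intention as canonical token,
#' prior-cycle method flags semicolon-joined, missing written as ".".
#'
#' @param path file path
#' @param soc data.frame of SOC responses
#' @return `read_soc_file` returns a data.frame
#' @export
read_soc_file <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  missing_cols <- setdiff(SOC_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop_crms(sprintf("SOC file %s lacks column(s): %s", path,
                      paste(missing_cols, collapse = ", ")), "crms_bad_file")
  }
  df$cycle_index <- as.integer(df$cycle_index)
  df$completion_day <- as.integer(df$completion_day)
  df$intention[df$intention == "."] <- NA_character_
  df$prior_cycle_methods[df$prior_cycle_methods == "."] <- ""
  df[, SOC_COLS]
}

#' @rdname read_soc_file
#' @export
write_soc_file <- function(soc, path) {
  out <- soc[, SOC_COLS]
  out$intention[is.na(out$intention)] <- "."
  out$prior_cycle_methods[is.na(out$prior_cycle_methods) |
                            out$prior_cycle_methods == ""] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
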