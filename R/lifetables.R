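# Single-decrement cycle-based cumulative pregnancy probabilities and the
# CrMS multiple-decrement ordinal-month net-rate life table.

#' Build a couple's analytic timeline
#'
#' The analytic start is the later of the start of the cycle during which
#' consent occurred and the start of the cycle with the first recorded
#' intercourse.  Cycles are numbered ordinally from the analytic start;
#' ordinal months are consecutive fixed-length bins from the same start.
#'
#' @param cycle_starts integer/Date vector of cycle start dates, in cycle
#'   order
#' @param consent_date consent date
#' @param first_intercourse_date date of first recorded intercourse (NA if
#'   none)
#' @param exit_date study exit date
#' @param month_length_days ordinal month length (default 30.44)
#' @return list: `entry_date`, `ordinals` (data.frame `cycle_index`,
#'   `ordinal`; NA before entry), `n_months` (ordinal months of follow-up),
#'   `month_of` (function mapping a date to its ordinal month)
#' @export
build_timeline <- function(cycle_starts, consent_date,
                           first_intercourse_date = NA,
                           exit_date = NULL,
                           month_length_days = 30.44) {
  cs <- as.numeric(cycle_starts)
  consent <- as.numeric(consent_date)
  fic <- as.numeric(first_intercourse_date)
  start_of_cycle_containing <- function(x) {
    idx <- findInterval(x, cs)
    if (idx < 1L) cs[1] else cs[idx]
  }
  entry <- start_of_cycle_containing(consent)
  if (!is.na(fic)) entry <- max(entry, start_of_cycle_containing(fic))
  if (!is.null(exit_date) && as.numeric(exit_date) < entry) {
    stop_crms("exit precedes analytic entry: invalid timeline",
              "crms_invalid_timeline")
  }
  ordinal <- rep(NA_integer_, length(cs))
  post <- which(cs >= entry)
  ordinal[post] <- seq_along(post)
  month_of <- function(date) {
    as.integer(floor((as.numeric(date) - entry) / month_length_days)) + 1L
  }
  n_months <- if (is.null(exit_date)) NA_integer_ else
    max(0L, month_of(as.numeric(exit_date) - 1e-9))
  list(entry_date = entry,
       ordinals = data.frame(cycle_index = seq_along(cs), ordinal = ordinal),
       n_months = n_months,
       month_of = month_of)
}

#' Single-decrement cycle-based life table
#'
#' Product-limit estimator of the cumulative probability of pregnancy over
#' ordinal cycles, stratified.  Each contributed cycle carries the stratum
#' of its own reconciled intention, its ordinal (the couple's study cycle
#' number by default), and whether a pregnancy occurred in it.  For each
#' stratum and ordinal i, the conditional probability is
#' `q_i = events_i / n_at_risk_i`, and the cumulative probability through
#' k is `CP(k) = 1 - prod_{i<=k} (1 - q_i)`.  Withdrawals are reported as
#' `n_i - events_i - n_{i+1}` (net; can be negative in intention-stratified
#' tables where couples move between strata).
#'
#' @param cycles data.frame with `stratum`, `ordinal`, `event` (logical),
#'   and `couple_id` (used for the couples count)
#' @param max_ordinal horizon (default 13 cycles)
#' @return object of class `crms_lifetable`: list with `risk` (per-stratum
#'   per-ordinal rows), `summary` (couples, cycles, pregnancies, CP at 6
#'   and at the horizon, per stratum), `skipped` (ordinals with empty risk
#'   sets)
#' @export
single_decrement <- function(cycles, max_ordinal = 13L) {
  cycles <- cycles[!is.na(cycles$stratum) & cycles$ordinal <= max_ordinal, ,
                   drop = FALSE]
  strata <- unique(cycles$stratum)
  risk_rows <- list(); summ_rows <- list(); skipped <- list()
  for (s in strata) {
    cs <- cycles[cycles$stratum == s, , drop = FALSE]
    n_i <- tabulate(cs$ordinal, nbins = max_ordinal)
    e_i <- tabulate(cs$ordinal[cs$event], nbins = max_ordinal)
    w_i <- n_i - e_i - c(n_i[-1], 0L)
    q <- ifelse(n_i > 0, e_i / n_i, NA_real_)
    if (any(n_i == 0)) {
      skipped[[s]] <- which(n_i == 0)
    }
    cp <- 1 - cumprod(ifelse(is.na(q), 1, 1 - q))
    risk_rows[[s]] <- data.frame(stratum = s, ordinal = seq_len(max_ordinal),
                                 n_at_risk = n_i, events = e_i,
                                 withdrawals = w_i, q = q, cp = cp,
                                 stringsAsFactors = FALSE)
    summ_rows[[s]] <- data.frame(stratum = s,
                                 couples = length(unique(cs$couple_id)),
                                 couples_at_first = length(unique(
                                   cs$couple_id[cs$ordinal == 1L])),
                                 cycles = nrow(cs),
                                 pregnancies = sum(cs$event),
                                 cp6 = cp[min(6L, max_ordinal)],
                                 cp_final = cp[max_ordinal],
                                 stringsAsFactors = FALSE)
  }
  structure(list(risk = rbind_all(risk_rows),
                 summary = rbind_all(summ_rows),
                 skipped = skipped,
                 max_ordinal = max_ordinal,
                 type = "single-decrement"),
            class = "crms_lifetable")
}

#' @export
print.crms_lifetable <- function(x, ...) {
  cat(sprintf("%s life table (horizon %d)\n", x$type, x$max_ordinal))
  if (!is.null(x$summary)) {
    s <- x$summary
    if (!is.null(s$cp_final)) {
      s$cp_final_pct <- fmt_pct(s$cp_final * 100, 100)
    }
    print(s, row.names = FALSE)
  }
  if (!is.null(x$net_rates)) print(x$net_rates, row.names = FALSE)
  invisible(x)
}

#' Multiple-decrement ordinal-month life table with net rates
#'
#' Competing-risk life table over ordinal months: all causes share the
#' single all-use denominator (no separation of months into
#' avoiding-related or achieving-related use).  Each couple contributes
#' months `1..months_observed`; if the couple exited with a
#' cause-classified pregnancy, the event falls in the final month.  For
#' cause c and month m, `q_{c,m} = events_{c,m} / n_m`; the net cumulative
#' rate per 100 couples is `NR_c = 100 * sum_m q_{c,m} prod_{j<m} p_j`
#' with `p_j = 1 - sum_c q_{c,j}` the all-cause continuation probability.
#' The accounting identity `sum_c NR_c/100 + prod_m p_m = 1` holds exactly.
#'
#' Couples whose pregnancy was not CrMS-related are removed entirely
#' before calling (or via `drop_causes`), as they are excluded from the
#' CrMS life table.
#'
#' @param couples data.frame, one row per couple: `couple_id`,
#'   `months_observed` (last ordinal month contributed, >= 1), `cause`
#'   (CrMS pregnancy category, NA when exit was not a pregnancy)
#' @param max_ordinal horizon in ordinal months (default 12)
#' @param drop_causes causes whose couples are removed entirely (default
#'   `"NON_CRMS"`)
#' @return `crms_lifetable` with `risk` (per cause-month), `net_rates`
#'   (per-cause NR over the horizon), `continuation` (all-cause
#'   continuation probability at the horizon)
#' @export
multiple_decrement <- function(couples, max_ordinal = 12L,
                               drop_causes = "NON_CRMS") {
  couples <- couples[!(couples$cause %in% drop_causes), , drop = FALSE]
  no_cause <- !is.na(couples$cause) & couples$cause == ""
  if (any(no_cause)) {
    warning("pregnancy without CrMS cause routed to UNRESOLVED")
    couples$cause[no_cause] <- "UNRESOLVED"
  }
  m_obs <- pmin(couples$months_observed, max_ordinal)
  # events past the horizon do not count as events within it
  cause <- ifelse(couples$months_observed <= max_ordinal, couples$cause, NA)
  causes <- sort(unique(cause[!is.na(cause)]))
  n_m <- vapply(seq_len(max_ordinal), function(m) sum(m_obs >= m), integer(1))
  q <- matrix(0, nrow = max_ordinal, ncol = length(causes),
              dimnames = list(NULL, causes))
  for (ci in seq_along(causes)) {
    e <- vapply(seq_len(max_ordinal), function(m) {
      sum(m_obs == m & !is.na(cause) & cause == causes[ci])
    }, integer(1))
    q[, ci] <- ifelse(n_m > 0, e / n_m, 0)
  }
  p_m <- 1 - rowSums(q)
  surv_before <- cumprod(c(1, p_m[-max_ordinal]))
  nr <- 100 * colSums(q * surv_before)
  risk <- do.call(rbind, lapply(seq_along(causes), function(ci) {
    data.frame(cause = causes[ci], ordinal = seq_len(max_ordinal),
               n_at_risk = n_m, events = as.integer(round(q[, ci] * n_m)),
               q = q[, ci], stringsAsFactors = FALSE)
  }))
  if (is.null(risk)) {
    risk <- data.frame(cause = character(), ordinal = integer(),
                       n_at_risk = integer(), events = integer(),
                       q = numeric())
  }
  structure(list(risk = risk,
                 net_rates = data.frame(cause = causes, net_rate_per_100 = nr,
                                        stringsAsFactors = FALSE),
                 continuation = prod(p_m),
                 n_couples = nrow(couples),
                 summary = NULL,
                 max_ordinal = max_ordinal,
                 type = "multiple-decrement"),
            class = "crms_lifetable")
}

LIFETABLE_STRATA <- c("Conceive", "All Avoiding", "Trying-hard Avoid", "Abstain")

# map a reconciled 6-level intention to the life-table strata it feeds
lifetable_strata_of <- function(intention) {
  grp <- collapse_intentions(intention, "lifetable")
  out <- lapply(seq_along(intention), function(i) {
    s <- switch(grp[i], Conceive = "Conceive", Avoiding = "All Avoiding",
                Abstain = "Abstain")
    if (intention[i] == "TRYING_HARD_AVOID") c(s, "Trying-hard Avoid") else s
  })
  out
}

#' Sensitivity grid of intention-stratified life tables
#'
#' Crosses the two sensitivity axes (SOC completion window: within 11 days
#' vs all; condom/withdrawal cycles: excluded vs included) and, within
#' each scenario, estimates the single-decrement cumulative pregnancy
#' probability for the strata Conceive (including undecided), All
#' Avoiding, Trying-hard Avoid, and Abstain.
#'
#' @param soc SOC response data.frame
#' @param cycle_events data.frame `couple_id`, `cycle_index`, `ordinal`,
#'   `event` for every analyzable cycle
#' @param barrier_flags data.frame from [flag_barrier_withdrawal()]
#' @param window_days primary prospective window (default 11)
#' @param max_ordinal life-table horizon (default 13)
#' @return data.frame (class `crms_sensitivity_grid`): one row per
#'   scenario x stratum with couples, cycles, pregnancies, CP6 and CP13
#' @export
sensitivity_grid <- function(soc, cycle_events, barrier_flags,
                             window_days = 11, max_ordinal = 13L) {
  arms <- expand.grid(window = c("within_window", "all"),
                      barrier = c("excluded", "included"),
                      stringsAsFactors = FALSE)
  out <- list()
  for (a in seq_len(nrow(arms))) {
    w <- if (arms$window[a] == "within_window") window_days else Inf
    intents <- build_couple_cycle_intentions(soc, window_days = w)
    d <- merge(cycle_events, intents[, c("couple_id", "cycle_index", "reconciled")],
               by = c("couple_id", "cycle_index"))
    d <- d[!is.na(d$reconciled), , drop = FALSE]
    if (arms$barrier[a] == "excluded" && nrow(barrier_flags) > 0) {
      d <- merge(d, barrier_flags, by = c("couple_id", "cycle_index"),
                 all.x = TRUE)
      d <- d[!(d$barrier_withdrawal %in% TRUE), , drop = FALSE]
    }
    strata <- lifetable_strata_of(d$reconciled)
    expanded <- data.frame(
      couple_id = rep(d$couple_id, lengths(strata)),
      ordinal = rep(d$ordinal, lengths(strata)),
      event = rep(d$event, lengths(strata)),
      stratum = unlist(strata), stringsAsFactors = FALSE)
    lt <- single_decrement(expanded, max_ordinal = max_ordinal)
    s <- lt$summary
    if (!is.null(s) && nrow(s) > 0) {
      s$window <- arms$window[a]
      s$barrier <- arms$barrier[a]
      out[[a]] <- s
    }
  }
  grid <- rbind_all(out)
  grid$stratum <- factor(grid$stratum, levels = LIFETABLE_STRATA)
  grid <- grid[order(grid$stratum, grid$window, grid$barrier), , drop = FALSE]
  class(grid) <- c("crms_sensitivity_grid", "data.frame")
  grid
}
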