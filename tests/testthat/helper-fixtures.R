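# Fixture builders and the independent day-classification oracle.

# a clean standard cycle: menses days 1..5, mucus build-up ending at the
# peak, dry elsewhere, fully observed
std_days <- function(len = 28L, peak = 14L, buildup = 5L) {
  bleeding <- rep("none", len)
  bleeding[1:5] <- c("H", "M", "M", "L", "VL")
  discharge <- rep("dry", len)
  build <- (peak - buildup + 1L):peak
  discharge[build[seq_len(max(0, length(build) - 3L))]] <- "non-peak-mucus"
  discharge[build[build > peak - 3L]] <- "peak-type-mucus"
  data.frame(day_of_cycle = seq_len(len), bleeding = bleeding,
             discharge = discharge, observation_frequency = "AD",
             intercourse = FALSE, intercourse_end_of_day = NA,
             stringsAsFactors = FALSE)
}

std_cycle <- function(len = 28L, peak = 14L, intercourse_days = integer(0),
                      eod = NULL, source = "CHART_AND_SOC", ...) {
  days <- std_days(len, peak, ...)
  days$intercourse[intercourse_days] <- TRUE
  if (!is.null(eod)) days$intercourse_end_of_day[intercourse_days] <- eod
  cyc <- crms_cycle("C1", 1L, days = days, source = source)
  cyc$peak_day <- as.integer(identify_peak_day(cyc))
  cyc
}

# random charted cycle exercising all code combinations
random_cycle <- function(len = sample(21:35, 1)) {
  days <- data.frame(
    day_of_cycle = seq_len(len),
    bleeding = sample(c("H", "M", "L", "VL", "B", "none"), len, replace = TRUE,
                      prob = c(.05, .05, .05, .03, .02, .8)),
    discharge = sample(c("dry", "non-peak-mucus", "peak-type-mucus", "unobserved"),
                       len, replace = TRUE, prob = c(.5, .15, .2, .15)),
    observation_frequency = sample(c("x1", "x2", "x3", "AD", "none"), len,
                                   replace = TRUE),
    intercourse = runif(len) < 0.15,
    intercourse_end_of_day = NA, stringsAsFactors = FALSE)
  cyc <- crms_cycle("R1", 1L, days = days, source = "CHART_ONLY")
  cyc$peak_day <- as.integer(identify_peak_day(cyc))
  cyc
}

# independent straight-line re-implementation of the default rule table,
# deliberately structured as a per-day scan (oracle for classify_days)
oracle_classify <- function(cycle, peak_day = cycle$peak_day) {
  days <- cycle$days
  menses <- c("H", "M", "L")
  out <- character(nrow(days))
  for (d in days$day_of_cycle) {
    bl <- days$bleeding[d]; disc <- days$discharge[d]
    observed <- disc != "unobserved" || bl %in% menses
    if (!observed) { out[d] <- "UNKNOWN"; next }
    if (bl %in% menses) { out[d] <- "FERTILE"; next }
    if (!is.na(peak_day) && d >= peak_day && d <= peak_day + 3L) {
      out[d] <- "FERTILE"; next
    }
    if (disc %in% c("peak-type-mucus", "non-peak-mucus")) {
      out[d] <- "FERTILE"; next
    }
    # count of three after a pre-peak non-peak-mucus patch, pre-peak only
    in_count3 <- FALSE
    if (is.na(peak_day) || d < peak_day) {
      for (j in max(1L, d - 3L):(d - 1L)) {
        if (j < 1L || j >= d) next
        if (days$discharge[j] == "non-peak-mucus" &&
            (is.na(peak_day) || j < peak_day)) in_count3 <- TRUE
      }
    }
    out[d] <- if (in_count3) "FERTILE" else "NON_FERTILE"
  }
  out
}

# tiny single-stratum cohort for life-table oracle checks: per-couple
# geometric conception times with random censoring
random_lt_cohort <- function(n = 25, p = 0.15, cens_p = 0.2, max_ord = 13L) {
  t_event <- rgeom(n, p) + 1L
  t_cens <- ifelse(runif(n) < cens_p, sample(1:max_ord, n, replace = TRUE),
                   max_ord)
  time <- pmin(t_event, t_cens, max_ord)
  event <- t_event <= pmin(t_cens, max_ord)
  list(time = time, event = event,
       cycles = do.call(rbind, lapply(seq_len(n), function(i) {
         data.frame(couple_id = i, stratum = "all",
                    ordinal = seq_len(time[i]),
                    event = c(rep(FALSE, time[i] - 1L), event[i]))
       })))
}

small_cohort <- function(n = 40, seed = 11, ...) {
  generate_cohort(sim_config(n_couples = n, seed = seed, ...))
}
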