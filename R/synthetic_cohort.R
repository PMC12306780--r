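# Seeded synthetic cohort generator: couples, cycles, charts, SOC
# questionnaires, barrier use, conceptions and censoring, with full ground
# truth for validating every pipeline stage.

#' Simulation configuration
#'
#' Defaults state the "paper-like" world the generator emulates: ~300
#' couples followed up to one year, cycle lengths 29 +/- 3 days (truncated
#' 21..42), a 13 +/- 1.5 day luteal phase, a 5-day pre-peak mucus
#' build-up, about 10% unobserved days, an intention mix dominated by
#' avoiders with occasional switching, day-specific conception
#' probabilities peaking near ovulation, rare condom/withdrawal cycles
#' with attenuated (not zeroed) conception risk, partner-specific SOC
#' nonresponse, and a small monthly dropout hazard.
#'
#' @param n_couples number of couples
#' @param seed RNG seed; fully determines the cohort
#' @param cycle_length_mean,cycle_length_sd,cycle_length_range follicular
#'   cycle length model (days)
#' @param luteal_length_mean,luteal_length_sd luteal (post-peak) length
#' @param mucus_buildup_days pre-peak mucus build-up days
#' @param missing_observation_rate marginal per-day probability the
#'   discharge observation is missing; realised as a cycle-level mixture
#'   (see `missing_cycle_fraction`) because missingness clusters within
#'   cycles rather than striking days independently
#' @param missing_cycle_fraction fraction of cycles carrying any missing
#'   observations; within those cycles the per-day missing rate is
#'   `missing_observation_rate / missing_cycle_fraction`
#' @param intention_mix named probabilities over the 6 intention levels
#' @param intention_persistence probability a couple keeps the previous
#'   cycle's intention
#' @param intercourse_rates per-intention named list of per-day intercourse
#'   probabilities by charted day status (FERTILE / NON_FERTILE / UNKNOWN);
#'   the FERTILE entries of the avoid intentions are the fertile-day
#'   "leakage" probabilities
#' @param fecundability length-7 day-specific conception probabilities for
#'   days ovulation-5 .. ovulation+1
#' @param barrier_prob per-cycle probability of condom/withdrawal use
#' @param barrier_attenuation multiplier on day-specific conception
#'   probability in barrier cycles
#' @param barrier_soc_report_prob probability a responding partner reports
#'   the prior cycle's barrier use on the SOC questionnaire
#' @param barrier_chart_note_prob probability barrier use is annotated on
#'   the chart
#' @param soc_nonresponse named (F, M) per-cycle nonresponse probabilities
#' @param soc_completion_geom_p geometric parameter of the SOC completion
#'   day (day = 1 + geometric, capped at 28)
#' @param disagreement_prob probability a partner reports one level away
#'   from the couple's true intention
#' @param fidelity_mix couple-level exit-questionnaire recording-fidelity
#'   mix (ALL, NEARLY, NOT_ALL, MISSING)
#' @param teacher_ok_prob per-assessment probability each teacher criterion
#'   is satisfactory
#' @param monthly_dropout_hazard per-ordinal-month probability of leaving
#'   the study without pregnancy
#' @param chart_missing_rate per-cycle probability the chart is never
#'   returned (the cycle appears in the SOC stream only)
#' @param max_followup_days censoring horizon (one year)
#' @param max_cycles cycle-count cap
#' @param pregnant_postpeak_mean,pregnant_postpeak_sd charted post-peak
#'   days in a conception cycle (lengthened luteal phase)
#' @param end_of_day_recorded_prob probability the end-of-day timing field
#'   is filled for an act of intercourse (the study-era chart rarely
#'   recorded it)
#' @return a validated `crms_sim_config`
#' @export
sim_config <- function(n_couples = 296L, seed = 20260911L,
                       cycle_length_mean = 29, cycle_length_sd = 3,
                       cycle_length_range = c(21L, 42L),
                       luteal_length_mean = 13, luteal_length_sd = 1.5,
                       mucus_buildup_days = 5L,
                       missing_observation_rate = 0.10,
                       missing_cycle_fraction = 0.30,
                       intention_mix = c(TRYING_HARD_CONCEIVE = 0.015,
                                         CONCEIVE = 0.02, NEUTRAL = 0.05,
                                         AVOID = 0.46, TRYING_HARD_AVOID = 0.335,
                                         ABSTAIN = 0.12),
                       intention_persistence = 0.85,
                       intercourse_rates = list(
                         TRYING_HARD_CONCEIVE = c(FERTILE = 0.40, NON_FERTILE = 0.25, UNKNOWN = 0.30),
                         CONCEIVE = c(FERTILE = 0.35, NON_FERTILE = 0.20, UNKNOWN = 0.25),
                         NEUTRAL = c(FERTILE = 0.15, NON_FERTILE = 0.15, UNKNOWN = 0.15),
                         AVOID = c(FERTILE = 0.035, NON_FERTILE = 0.22, UNKNOWN = 0.07),
                         TRYING_HARD_AVOID = c(FERTILE = 0.03, NON_FERTILE = 0.20, UNKNOWN = 0.05),
                         ABSTAIN = c(FERTILE = 0.004, NON_FERTILE = 0.010, UNKNOWN = 0.005)),
                       fecundability = c(0.03, 0.07, 0.12, 0.20, 0.26, 0.30, 0.10),
                       barrier_prob = 0.05, barrier_attenuation = 0.2,
                       barrier_soc_report_prob = 0.7,
                       barrier_chart_note_prob = 0.5,
                       soc_nonresponse = c(F = 0.12, M = 0.18),
                       soc_completion_geom_p = 0.30,
                       disagreement_prob = 0.08,
                       fidelity_mix = c(ALL = 0.40, NEARLY = 0.22,
                                        NOT_ALL = 0.12, MISSING = 0.26),
                       teacher_ok_prob = 0.85,
                       monthly_dropout_hazard = 0.02,
                       chart_missing_rate = 0.05,
                       max_followup_days = 365L, max_cycles = 13L,
                       pregnant_postpeak_mean = 25, pregnant_postpeak_sd = 4,
                       end_of_day_recorded_prob = 0.10) {
  cfg <- as.list(environment())
  if (missing_cycle_fraction > 0 &&
      missing_observation_rate / missing_cycle_fraction > 1) {
    stop_crms("config out of range: missing_observation_rate exceeds missing_cycle_fraction",
              "crms_bad_config")
  }
  probs <- c(missing_observation_rate, missing_cycle_fraction,
             intention_mix, intention_persistence,
             unlist(intercourse_rates), fecundability, barrier_prob,
             barrier_attenuation, barrier_soc_report_prob,
             barrier_chart_note_prob, soc_nonresponse, soc_completion_geom_p,
             disagreement_prob, fidelity_mix, teacher_ok_prob,
             monthly_dropout_hazard, chart_missing_rate,
             end_of_day_recorded_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_crms("config out of range: probabilities must lie in [0, 1]",
              "crms_bad_config")
  }
  if (length(fecundability) != 7L) {
    stop_crms("config out of range: fecundability must have length 7",
              "crms_bad_config")
  }
  stopifnot(setequal(names(intention_mix), intention_levels()),
            setequal(names(intercourse_rates), intention_levels()))
  structure(cfg, class = "crms_sim_config")
}

rtrunc_int <- function(n, mean, sd, lo, hi) {
  pmin(pmax(as.integer(round(stats::rnorm(n, mean, sd))), lo), hi)
}

sample_level <- function(mix) sample(names(mix), 1L, prob = mix)

# shift an intention one level toward a neighbour on the achieving order
jitter_intention <- function(level) {
  r <- intention_rank(level)
  shift <- if (r == 1L) 1L else if (r == 6L) -1L else sample(c(-1L, 1L), 1L)
  intention_levels()[r + shift]
}

make_cycle_chart <- function(couple_id, cycle_index, len, peak, cfg) {
  bleeding <- rep("none", len)
  bl <- c("H", "M", "M", "L", "VL")
  bleeding[seq_len(min(5L, len))] <- bl[seq_len(min(5L, len))]
  discharge <- rep("dry", len)
  build <- max(1L, peak - cfg$mucus_buildup_days + 1L):peak
  nonpeak_n <- max(0L, length(build) - 3L)
  if (nonpeak_n > 0) discharge[build[seq_len(nonpeak_n)]] <- "non-peak-mucus"
  discharge[build[(nonpeak_n + 1L):length(build)]] <- "peak-type-mucus"
  obsfreq <- rep("AD", len)
  rate <- if (cfg$missing_cycle_fraction > 0 &&
              stats::runif(1) < cfg$missing_cycle_fraction) {
    cfg$missing_observation_rate / cfg$missing_cycle_fraction
  } else 0
  miss <- stats::runif(len) < rate
  # never blank the peak day itself: the charted peak must be identifiable
  miss[peak] <- FALSE
  discharge[miss] <- "unobserved"
  obsfreq[miss] <- "none"
  data.frame(couple_id = couple_id, cycle_index = cycle_index,
             day_of_cycle = seq_len(len), bleeding = bleeding,
             discharge = discharge, observation_frequency = obsfreq,
             intercourse = FALSE, intercourse_end_of_day = NA,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Emits the four input streams consumed by the analysis modules (daily
#' charts, SOC questionnaires, couple baselines, pregnancy evaluations)
#' plus teacher follow-up assessments, chart barrier annotations, and
#' ground-truth tables (true intention, ovulation and conception day per
#' cycle).  Identical configurations produce identical cohorts.
#'
#' @param config a `crms_sim_config`
#' @return object of class `crms_cohort`: list with `charts`, `soc`,
#'   `baselines`, `evaluations`, `followups`, `chart_annotations`,
#'   `truth_cycles`, `truth_couples`, `day_status_counts`, `config`
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "crms_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  rules <- default_rule_table()
  fid_answers <- c(ALL = "ALL_WITHOUT_EXCEPTION",
                   NEARLY = "NEARLY_ALL_RARE_EXCEPTION",
                   NOT_ALL = "NOT_ALL", MISSING = "MISSING")

  charts <- list(); socs <- list(); truth <- list(); evals <- list()
  followups <- list(); annotations <- list(); baselines <- list()
  status_counts <- c(FERTILE = 0L, NON_FERTILE = 0L, UNKNOWN = 0L)

  for (i in seq_len(cfg$n_couples)) {
    cid <- sprintf("C%04d", i)
    fid_cat <- sample_level(cfg$fidelity_mix)
    f_ans <- fid_answers[[fid_cat]]
    m_ans <- if (fid_cat %in% c("ALL", "NEARLY")) {
      sample(fid_answers, 1L)
    } else sample(fid_answers[c("NOT_ALL", "MISSING")], 1L)
    visit_days <- sort(unique(pmax(7L, as.integer(
      c(14, 28, 45, 70, 100, 140, 200, 280) + round(stats::rnorm(8, 0, 5))))))
    n_v <- length(visit_days)
    followups[[i]] <- data.frame(
      couple_id = cid, visit_date = visit_days,
      consistent_observations = stats::runif(n_v) < cfg$teacher_ok_prob,
      peak_id_ok = stats::runif(n_v) < cfg$teacher_ok_prob,
      accurate_charting = stats::runif(n_v) < cfg$teacher_ok_prob,
      stringsAsFactors = FALSE)

    # enrolled with intention to avoid; fall back to the full mix when the
    # configured world has no avoiders at all
    avoid_mix <- cfg$intention_mix[c("AVOID", "TRYING_HARD_AVOID", "ABSTAIN")]
    intent <- if (sum(avoid_mix) > 0) sample_level(avoid_mix / sum(avoid_mix))
              else sample_level(cfg$intention_mix)
    t0 <- 0; k <- 0L
    exit_reason <- "completed_year"
    c_charts <- list(); c_truth <- list(); c_soc <- list(); c_ann <- list()
    prev_barrier <- FALSE

    while (t0 < cfg$max_followup_days && k < cfg$max_cycles) {
      k <- k + 1L
      if (k > 1L && stats::runif(1) > cfg$intention_persistence) {
        intent <- sample_level(cfg$intention_mix)
      }
      len <- rtrunc_int(1, cfg$cycle_length_mean, cfg$cycle_length_sd,
                        cfg$cycle_length_range[1], cfg$cycle_length_range[2])
      luteal <- pmin(pmax(as.integer(round(
        stats::rnorm(1, cfg$luteal_length_mean, cfg$luteal_length_sd))),
        9L), len - 8L)
      peak <- len - luteal
      ovulation <- peak + sample(c(-1L, 0L, 1L), 1L)

      chart <- make_cycle_chart(cid, k, len, peak, cfg)
      cyc <- crms_cycle(cid, k, days = chart[, -(1:2)], source = "CHART_AND_SOC")
      cyc$peak_day <- as.integer(identify_peak_day(cyc))
      st <- classify_days(cyc, rules)

      rates <- cfg$intercourse_rates[[intent]]
      p_day <- rates[st$status]
      ic <- stats::runif(len) < p_day
      eod <- rep(NA, len)
      rec <- ic & stats::runif(len) < cfg$end_of_day_recorded_prob
      eod[rec] <- stats::runif(sum(rec)) < 0.8
      chart$intercourse <- ic
      chart$intercourse_end_of_day <- eod

      barrier <- stats::runif(1) < cfg$barrier_prob && any(ic)
      if (barrier && stats::runif(1) < cfg$barrier_chart_note_prob) {
        c_ann[[length(c_ann) + 1L]] <- data.frame(
          couple_id = cid, cycle_index = k, barrier_withdrawal = TRUE)
      }

      window <- (ovulation - 5L):(ovulation + 1L)
      window <- window[window >= 1L & window <= len]
      fec <- cfg$fecundability[window - ovulation + 6L]
      if (barrier) fec <- fec * cfg$barrier_attenuation
      hit <- ic[window] & stats::runif(length(window)) < fec
      conceived <- any(hit)
      conception_day <- if (conceived) window[which(hit)[1]] else NA_integer_

      if (conceived) {
        postpeak <- max(18L, as.integer(round(stats::rnorm(
          1, cfg$pregnant_postpeak_mean, cfg$pregnant_postpeak_sd))))
        ext_len <- peak + postpeak
        if (ext_len > len) {
          extra <- make_cycle_chart(cid, k, ext_len, peak, cfg)
          keep <- seq_len(len)
          extra$intercourse[keep] <- chart$intercourse
          extra$intercourse_end_of_day[keep] <- chart$intercourse_end_of_day
          extra$bleeding[keep] <- chart$bleeding
          extra$discharge[keep] <- chart$discharge
          extra$observation_frequency[keep] <- chart$observation_frequency
          ex_idx <- (len + 1L):ext_len
          p_ex <- cfg$intercourse_rates[[intent]][["NON_FERTILE"]]
          extra$intercourse[ex_idx] <- stats::runif(length(ex_idx)) < p_ex
          chart <- extra
          len <- ext_len
        }
        exit_reason <- "pregnant"
      }

      # SOC responses for this cycle (intention stated at cycle start)
      for (p in c("F", "M")) {
        if (stats::runif(1) < cfg$soc_nonresponse[[p]]) next
        stated <- intent
        if (stats::runif(1) < cfg$disagreement_prob) stated <- jitter_intention(intent)
        meths <- character(0)
        if (prev_barrier && stats::runif(1) < cfg$barrier_soc_report_prob) {
          meths <- sample(c("condom", "withdrawal"), 1L)
        }
        if (stats::runif(1) < 0.05) meths <- c(meths, "BBT")
        c_soc[[length(c_soc) + 1L]] <- data.frame(
          couple_id = cid, cycle_index = k, partner = p,
          completion_day = min(1L + stats::rgeom(1, cfg$soc_completion_geom_p), 28L),
          intention = stated,
          prior_cycle_methods = paste(meths, collapse = ";"),
          stringsAsFactors = FALSE)
      }

      if (conceived && len > nrow(st)) {
        # recount statuses over the lengthened (pregnant) chart
        cyc_f <- crms_cycle(cid, k, days = chart[, -(1:2)],
                            source = "CHART_AND_SOC")
        cyc_f$peak_day <- as.integer(identify_peak_day(cyc_f))
        st <- classify_days(cyc_f, rules)
      }
      chart_emitted <- stats::runif(1) >= cfg$chart_missing_rate
      if (chart_emitted) c_charts[[length(c_charts) + 1L]] <- chart
      c_truth[[k]] <- data.frame(
        couple_id = cid, cycle_index = k, start_day = t0, length_days = len,
        peak_day = peak, ovulation_day = ovulation, intention = intent,
        barrier = barrier, conceived = conceived,
        conception_day = conception_day, chart_emitted = chart_emitted,
        stringsAsFactors = FALSE)
      cs <- table(factor(st$status, levels = names(status_counts)))
      status_counts <- status_counts + as.integer(cs)
      prev_barrier <- barrier
      t0 <- t0 + len
      if (conceived) break
      p_drop <- 1 - (1 - cfg$monthly_dropout_hazard)^(len / 30.44)
      if (stats::runif(1) < p_drop) { exit_reason <- "dropout"; break }
    }
    followup_days <- min(t0, cfg$max_followup_days)
    months_observed <- max(1L, min(12L, as.integer(ceiling(followup_days / 30.44))))

    charts[[i]] <- do.call(rbind, c_charts)
    truth[[i]] <- do.call(rbind, c_truth)
    if (length(c_soc)) socs[[i]] <- do.call(rbind, c_soc)
    if (length(c_ann)) annotations[[i]] <- do.call(rbind, c_ann)
    baselines[[i]] <- data.frame(
      couple_id = cid, consent_day = 0L,
      female_fidelity = f_ans, male_fidelity = unname(m_ans),
      exit_reason = exit_reason, followup_days = followup_days,
      months_observed = months_observed, n_cycles = k,
      stringsAsFactors = FALSE)

    last <- truth[[i]][nrow(truth[[i]]), ]
    if (last$conceived) {
      # classify from the internally generated chart even when it was
      # withheld from the emitted stream (the review panel had more
      # information than the analytic chart file)
      evals[[length(evals) + 1L]] <-
        make_truth_evaluation(cid, last, chart, rules, cfg)
    }
  }

  structure(list(charts = rbind_all(charts),
                 soc = rbind_all(socs),
                 baselines = rbind_all(baselines),
                 evaluations = evals,
                 followups = rbind_all(followups),
                 chart_annotations = if (length(annotations))
                   rbind_all(annotations)
                 else data.frame(couple_id = character(), cycle_index = integer(),
                                 barrier_withdrawal = logical()),
                 truth_cycles = rbind_all(truth),
                 day_status_counts = status_counts,
                 config = cfg),
            class = "crms_cohort")
}

# build a pregnancy evaluation from generator truth for the conception cycle
make_truth_evaluation <- function(cid, truth_row, couple_chart, rules, cfg) {
  k <- truth_row$cycle_index
  chart <- couple_chart[couple_chart$cycle_index == k, , drop = FALSE]
  cyc <- crms_cycle(cid, k, days = chart[, -(1:2)], source = "CHART_AND_SOC")
  cyc$peak_day <- as.integer(identify_peak_day(cyc))
  st <- classify_days(cyc, rules)
  cd <- truth_row$conception_day
  cd_status <- st$status[st$day_of_cycle == cd]
  cd_eod <- st$end_of_day_only[st$day_of_cycle == cd]
  cd_disc <- chart$discharge[chart$day_of_cycle == cd]
  achieving_intent <- truth_row$intention %in%
    c("TRYING_HARD_CONCEIVE", "CONCEIVE", "NEUTRAL")

  if (truth_row$barrier) {
    known <- stats::runif(1) < 0.8
    return(pregnancy_evaluation(
      cid, k, evaluation_done = TRUE,
      intercourse_on_known_fertile = if (cd_status == "FERTILE") TRUE else NA,
      fertile_day_type = if (cd_status == "FERTILE") "unknown" else "none",
      barrier_or_withdrawal_on_fertile = if (known) TRUE else NA,
      barrier_or_withdrawal_used = TRUE))
  }
  done <- stats::runif(1) < 0.9
  if (!done) {
    return(pregnancy_evaluation(cid, k, evaluation_done = FALSE,
                                info_sufficient = FALSE))
  }
  if (cd_status == "FERTILE") {
    near_peak <- !is.na(cyc$peak_day) && abs(cd - cyc$peak_day) <= 3
    ftype <- if (identical(cd_disc, "peak-type-mucus") || near_peak)
      "peak_type_or_count3" else "other_fertile"
    flags <- if (!achieving_intent && stats::runif(1) < 0.3)
      sample(c("taking_a_chance", "special_occasion"), 1L) else character(0)
    return(pregnancy_evaluation(cid, k, intercourse_on_known_fertile = TRUE,
                                fertile_day_type = ftype,
                                achieving_flags = flags))
  }
  if (cd_status == "UNKNOWN") {
    u <- stats::runif(1)
    if (u < 0.5) {
      return(pregnancy_evaluation(cid, k, intercourse_on_known_fertile = NA,
                                  fertile_day_type = "unknown",
                                  achieving_flags = "taking_a_chance"))
    } else if (u < 0.75) {
      return(pregnancy_evaluation(cid, k, misinterpretation = TRUE))
    }
    return(pregnancy_evaluation(cid, k, info_sufficient = FALSE))
  }
  # conception attributed to a day charted non-fertile
  if (isTRUE(cd_eod)) {
    flags <- if (stats::runif(1) < 0.5) "taking_a_chance" else character(0)
    return(pregnancy_evaluation(cid, k, end_of_day_ambiguous = TRUE,
                                achieving_flags = flags))
  }
  u <- stats::runif(1)
  if (u < 0.4) return(pregnancy_evaluation(cid, k, misinterpretation = TRUE))
  if (u < 0.6) return(pregnancy_evaluation(
    cid, k, teaching_deficiencies = sample(TEACHING_DEFICIENCY_CODES, 1L)))
  pregnancy_evaluation(cid, k)
}

#' Ground-truth report for a synthetic cohort
#'
#' Exact truth from generator internals: cumulative pregnancy probability
#' over 13 cycles per life-table intention stratum computed from the true
#' cycle intentions and conception events, and the true day-status
#' partition counts.
#'
#' @param cohort a `crms_cohort`
#' @return list: `truth_lifetable` (a `crms_lifetable` over true strata),
#'   `day_status_counts`, `n_pregnancies`, `n_cycles`, `n_couples`
#' @export
ground_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "crms_cohort"))
  tc <- cohort$truth_cycles
  strata <- lifetable_strata_of(tc$intention)
  expanded <- data.frame(couple_id = rep(tc$couple_id, lengths(strata)),
                         ordinal = rep(tc$cycle_index, lengths(strata)),
                         event = rep(tc$conceived, lengths(strata)),
                         stratum = unlist(strata), stringsAsFactors = FALSE)
  list(truth_lifetable = single_decrement(expanded, max_ordinal = 13L),
       day_status_counts = cohort$day_status_counts,
       n_pregnancies = sum(tc$conceived),
       n_cycles = nrow(tc),
       n_couples = length(unique(tc$couple_id)))
}

#' Write a cohort's streams to a directory in the package file formats
#'
#' @param cohort a `crms_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(charts = file.path(dir, "charts.tsv"),
             soc = file.path(dir, "soc.tsv"),
             baselines = file.path(dir, "baselines.tsv"),
             evaluations = file.path(dir, "evaluations.tsv"),
             followups = file.path(dir, "followups.tsv"),
             annotations = file.path(dir, "chart_annotations.tsv"))
  write_chart_file(cohort$charts, paths[["charts"]])
  write_soc_file(cohort$soc, paths[["soc"]])
  utils::write.table(cohort$baselines, paths[["baselines"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_evaluation_file(cohort$evaluations, paths[["evaluations"]])
  utils::write.table(cohort$followups, paths[["followups"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$chart_annotations, paths[["annotations"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
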