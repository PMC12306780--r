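test_that("classify_days handles the canonical day types", {
  cyc <- std_cycle(len = 28, peak = 14)
  st <- classify_days(cyc)

  expect_equal(nrow(st), 28)
  # menses bleeding fertile
  expect_true(all(st$status[1:4] == "FERTILE"))
  # mucus build-up and peak window fertile
  expect_true(all(st$status[10:17] == "FERTILE"))
  # peak-type mucus day fertile
  expect_equal(st$status[14], "FERTILE")
  # dry day at Peak+5 and beyond non-fertile
  expect_true(all(st$status[19:28] == "NON_FERTILE"))
  expect_false(any(st$end_of_day_only[19:28]))
  # Peak+4 non-fertile but end-of-day only
  expect_equal(st$status[18], "NON_FERTILE")
  expect_true(st$end_of_day_only[18])
  # pre-peak dry day non-fertile end-of-day only
  expect_equal(st$status[6], "NON_FERTILE")
  expect_true(st$end_of_day_only[6])
})

test_that("days lacking observations are UNKNOWN, and missingness is monotone", {
  days <- std_days()
  days$discharge[20] <- "unobserved"
  days$observation_frequency[20] <- "none"
  cyc <- crms_cycle("C1", 1L, days = days, source = "CHART_ONLY",
                    peak_day = 14L)
  st <- classify_days(cyc)
  expect_equal(st$status[20], "UNKNOWN")

  # adding an observation never leaves the day UNKNOWN
  for (disc in c("dry", "non-peak-mucus", "peak-type-mucus")) {
    cyc2 <- cyc
    cyc2$days$discharge[20] <- disc
    expect_false(classify_days(cyc2)$status[20] == "UNKNOWN")
  }
  # removing all observations always yields UNKNOWN
  cyc3 <- std_cycle()
  cyc3$days$discharge[7] <- "unobserved"
  cyc3$days$bleeding[7] <- "none"
  cyc3$days$observation_frequency[7] <- "none"
  expect_equal(classify_days(cyc3)$status[7], "UNKNOWN")
  # an unobserved-discharge day with menses bleeding is still classifiable
  cyc4 <- std_cycle()
  cyc4$days$discharge[2] <- "unobserved"
  expect_equal(classify_days(cyc4)$status[2], "FERTILE")
})

test_that("classify_days signals on missing charts and malformed codes", {
  soc_only <- crms_cycle("C1", 1L, length_days = 28L, source = "SOC_ONLY")
  expect_error(classify_days(soc_only), class = "crms_no_chart")
  bad <- std_cycle()
  bad$days$discharge[3] <- "sticky"
  expect_error(classify_days(bad), class = "crms_invalid_code")
  eod_bad <- std_days()
  eod_bad$intercourse_end_of_day[5] <- TRUE  # no intercourse that day
  expect_error(crms_cycle("C1", 1L, days = eod_bad, source = "CHART_ONLY"),
               class = "crms_invalid_code")
})

test_that("classification matches the independent oracle and is a partition", {
  set.seed(401)
  for (i in 1:1000) {
    cyc <- random_cycle()
    st <- classify_days(cyc)
    expect_identical(st$status, oracle_classify(cyc))
    # partition of the cycle's days
    expect_equal(nrow(st), cyc$length_days)
    expect_true(all(st$status %in% c("FERTILE", "NON_FERTILE", "UNKNOWN")))
    # determinism
    expect_identical(st, classify_days(cyc))
  }
})

test_that("post-peak consistency holds on random cycles", {
  set.seed(402)
  for (i in 1:200) {
    cyc <- random_cycle()
    if (is.na(cyc$peak_day)) next
    st <- classify_days(cyc)
    after4 <- st$day_of_cycle > cyc$peak_day + 4
    dry <- cyc$days$discharge == "dry" & !(cyc$days$bleeding %in% c("H", "M", "L"))
    expect_true(all(st$status[after4 & dry] == "NON_FERTILE"))
    window <- st$day_of_cycle >= cyc$peak_day + 1 & st$day_of_cycle <= cyc$peak_day + 3
    observed <- st$status != "UNKNOWN"
    expect_true(all(st$status[window & observed] == "FERTILE"))
  }
})

test_that("identify_peak_day returns the last peak-type day and flags double peaks", {
  cyc <- std_cycle(peak = 14)
  expect_equal(as.integer(identify_peak_day(cyc)), 14L)
  # idempotent
  expect_equal(as.integer(identify_peak_day(cyc)), 14L)

  none <- std_cycle()
  none$days$discharge[none$days$discharge == "peak-type-mucus"] <- "non-peak-mucus"
  pk <- identify_peak_day(none)
  expect_true(is.na(pk))
  expect_false(attr(pk, "possible_double_peak"))

  dbl <- std_cycle(peak = 13)
  dbl$days$discharge[12:13] <- "peak-type-mucus"
  dbl$days$discharge[18] <- "peak-type-mucus"
  pk <- identify_peak_day(dbl)
  expect_equal(as.integer(pk), 18L)
  expect_true(attr(pk, "possible_double_peak"))
})

test_that("is_peak_type_mucus reads the discharge code", {
  expect_true(is_peak_type_mucus(list(discharge = "peak-type-mucus")))
  expect_false(is_peak_type_mucus(list(discharge = "dry")))
  expect_false(is_peak_type_mucus(list(discharge = "non-peak-mucus")))
  expect_error(is_peak_type_mucus(list(discharge = "unobserved")),
               class = "crms_unobserved")
})

test_that("cycle-length imputation is the half-up rounded median", {
  expect_equal(impute_cycle_length(c(28, 30, 29)), 29L)
  expect_equal(impute_cycle_length(28), 28L)
  expect_equal(impute_cycle_length(c(27, 28, 30, 33)), 29L)
  expect_error(impute_cycle_length(numeric(0)), class = "crms_no_lengths")
})

test_that("pregnancy surveillance flags lengthened post-peak phases and delays", {
  cyc <- crms_cycle("C1", 5L, length_days = 31L, source = "SOC_ONLY",
                    peak_day = 14L)
  expect_true(flag_possible_pregnancy(cyc, postpeak_threshold_days = 17))
  short <- crms_cycle("C1", 5L, length_days = 26L, source = "SOC_ONLY",
                      peak_day = 14L)
  expect_false(flag_possible_pregnancy(short, postpeak_threshold_days = 17))
  # menses delay alone triggers
  expect_true(flag_possible_pregnancy(short, next_start_delay_days = 8))
  # no peak: falls back to delay; signals when that too is unknown
  nopeak <- crms_cycle("C1", 5L, length_days = 26L, source = "SOC_ONLY")
  expect_error(flag_possible_pregnancy(nopeak), class = "crms_peak_unknown")
  expect_true(flag_possible_pregnancy(nopeak, next_start_delay_days = 10))
})

test_that("surveillance detects simulated pregnancies with high sensitivity", {
  # conceive-heavy world so pregnancies accumulate quickly
  mix <- c(TRYING_HARD_CONCEIVE = 1, CONCEIVE = 0, NEUTRAL = 0, AVOID = 0,
           TRYING_HARD_AVOID = 0, ABSTAIN = 0)
  co <- generate_cohort(sim_config(n_couples = 600, seed = 403,
                                   intention_mix = mix,
                                   intention_persistence = 1,
                                   chart_missing_rate = 0))
  tp <- co$truth_cycles[co$truth_cycles$conceived, ]
  expect_gt(nrow(tp), 400)
  flagged <- vapply(seq_len(nrow(tp)), function(i) {
    cyc <- crms_cycle(tp$couple_id[i], tp$cycle_index[i],
                      length_days = tp$length_days[i], source = "SOC_ONLY",
                      peak_day = tp$peak_day[i])
    flag_possible_pregnancy(cyc, postpeak_threshold_days = 17)
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("chart files round-trip exactly and rule tables read back", {
  co <- small_cohort(n = 5, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chart_file(co$charts, path)
  back <- read_chart_file(path)
  rownames(back) <- NULL; rownames(co$charts) <- NULL
  expect_identical(back, co$charts[, names(back)])

  rules <- default_rule_table()
  rpath <- withr::local_tempfile(fileext = ".conf")
  write_rule_table(rules, rpath)
  back_rules <- read_rule_table(rpath)
  expect_equal(back_rules$version, rules$version)
  expect_equal(back_rules$count_of_three, rules$count_of_three)
  expect_equal(back_rules$menses_codes, rules$menses_codes)
})
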