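test_that("single-decrement closed forms", {
  # 10 couples, one pregnancy at ordinal 1, everyone else completes 13 cycles
  cycles <- rbind(
    data.frame(couple_id = 1, stratum = "all", ordinal = 1, event = TRUE),
    expand.grid(couple_id = 2:10, ordinal = 1:13)[, c("couple_id", "ordinal")] |>
      transform(stratum = "all", event = FALSE))
  lt <- single_decrement(cycles)
  expect_equal(lt$summary$cp_final, 0.1)
  expect_equal(lt$risk$n_at_risk[1], 10)
  expect_equal(lt$risk$withdrawals[1], 0)

  # zero pregnancies anywhere
  cycles$event <- FALSE
  expect_equal(single_decrement(cycles)$summary$cp_final, 0)
})

test_that("risk rows are pure counts: shrinking the cohort only changes counts", {
  set.seed(701)
  coh <- random_lt_cohort(n = 30)
  lt_full <- single_decrement(coh$cycles)
  drop_id <- 30
  lt_small <- single_decrement(coh$cycles[coh$cycles$couple_id != drop_id, ])
  kept <- coh$cycles[coh$cycles$couple_id == drop_id, ]
  for (o in 1:13) {
    d_n <- sum(kept$ordinal == o)
    d_e <- sum(kept$ordinal == o & kept$event)
    expect_equal(lt_full$risk$n_at_risk[o] - lt_small$risk$n_at_risk[o], d_n)
    expect_equal(lt_full$risk$events[o] - lt_small$risk$events[o], d_e)
  }
})

test_that("constant fecundability is recovered (closed form 1 - 0.92^13)", {
  set.seed(702)
  n <- 500; p <- 0.08
  t_event <- rgeom(n, p) + 1L
  time <- pmin(t_event, 13L)
  event <- t_event <= 13L
  cycles <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(couple_id = i, stratum = "all", ordinal = seq_len(time[i]),
               event = c(rep(FALSE, time[i] - 1L), event[i]))
  }))
  cp <- single_decrement(cycles)$summary$cp_final
  truth <- 1 - (1 - p)^13
  mc_se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(cp - truth), 3 * mc_se)
})

test_that("CP matches 1 - Kaplan-Meier survival from the survival package", {
  skip_if_not_installed("survival")
  set.seed(703)
  for (i in 1:100) {
    coh <- random_lt_cohort(n = sample(5:30, 1), p = runif(1, 0.05, 0.4))
    lt <- single_decrement(coh$cycles)
    km <- survival::survfit(survival::Surv(coh$time, coh$event) ~ 1)
    s13 <- summary(km, times = 13, extend = TRUE)$surv
    expect_equal(lt$summary$cp_final, 1 - s13, tolerance = 1e-12)
  }
})

test_that("multiple-decrement reduces to single-decrement with one cause", {
  set.seed(704)
  n <- 40
  t_raw <- rgeom(n, 0.12) + 1L
  months <- pmin(t_raw, 12L)
  preg <- t_raw <= 12L
  couples <- data.frame(couple_id = seq_len(n), months_observed = months,
                        cause = ifelse(preg, "ACHIEVING", NA))
  md <- multiple_decrement(couples)
  cycles <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(couple_id = i, stratum = "all", ordinal = seq_len(months[i]),
               event = c(rep(FALSE, months[i] - 1L), preg[i]))
  }))
  sd12 <- single_decrement(cycles, max_ordinal = 12L)$summary$cp_final
  expect_equal(md$net_rates$net_rate_per_100 / 100, sd12, tolerance = 1e-12)
})

test_that("multiple-decrement is symmetric and satisfies the accounting identity", {
  couples <- data.frame(
    couple_id = 1:12, months_observed = rep(c(2L, 5L, 9L, 12L), 3),
    cause = c("A", "B", NA, "A", "B", NA, "A", "B", NA, "A", "B", NA))
  md <- multiple_decrement(couples, drop_causes = character(0))
  nr <- md$net_rates
  expect_equal(nr$net_rate_per_100[nr$cause == "A"],
               nr$net_rate_per_100[nr$cause == "B"])
  expect_equal(sum(nr$net_rate_per_100) / 100 + md$continuation, 1,
               tolerance = 1e-9)
})

test_that("a hand-enumerable five-couple table matches the brute-force oracle", {
  couples <- data.frame(
    couple_id = 1:5,
    months_observed = c(3L, 3L, 6L, 8L, 12L),
    cause = c("ACHIEVING", NA, "METHOD", "ACHIEVING", NA))
  md <- multiple_decrement(couples)
  # independent brute-force: explicit month-by-month bookkeeping
  n_m <- sapply(1:12, function(m) sum(couples$months_observed >= m))
  e <- function(cz, m) sum(couples$months_observed == m &
                             couples$cause %in% cz)
  q_ach <- sapply(1:12, function(m) e("ACHIEVING", m) / n_m[m])
  q_met <- sapply(1:12, function(m) e("METHOD", m) / n_m[m])
  p_all <- 1 - q_ach - q_met
  cum <- cumprod(c(1, p_all[-12]))
  expect_equal(md$net_rates$net_rate_per_100[md$net_rates$cause == "ACHIEVING"],
               100 * sum(q_ach * cum), tolerance = 1e-12)
  expect_equal(md$net_rates$net_rate_per_100[md$net_rates$cause == "METHOD"],
               100 * sum(q_met * cum), tolerance = 1e-12)
  expect_equal(md$continuation, prod(p_all), tolerance = 1e-12)
  # couples with non-CrMS pregnancies are removed entirely
  couples2 <- rbind(couples, data.frame(couple_id = 6, months_observed = 2L,
                                        cause = "NON_CRMS"))
  md2 <- multiple_decrement(couples2)
  expect_equal(md2$net_rates, md$net_rates)
  expect_equal(md2$n_couples, 5)
})

test_that("timelines start at the later of consent and first intercourse", {
  starts <- c(0, 29, 57, 86, 115)  # five cycle starts
  tl <- build_timeline(starts, consent_date = 40, first_intercourse_date = 90)
  expect_equal(tl$entry_date, 86)
  expect_equal(tl$ordinals$ordinal, c(NA, NA, NA, 1L, 2L))
  # consent mid-cycle-2, intercourse from the start: entry = cycle 2 start
  tl2 <- build_timeline(starts, consent_date = 40, first_intercourse_date = 40)
  expect_equal(tl2$entry_date, 29)
  expect_error(build_timeline(starts, consent_date = 40, exit_date = 10),
               class = "crms_invalid_timeline")
  # month binning from the entry date
  tl3 <- build_timeline(starts, consent_date = 0, exit_date = 365)
  expect_equal(tl3$month_of(0), 1L)
  expect_equal(tl3$month_of(30.44), 2L)
  expect_equal(tl3$n_months, 12L)
})

test_that("sensitivity arms collapse when their axis is inert", {
  co <- small_cohort(n = 50, seed = 705, barrier_prob = 0,
                     soc_completion_geom_p = 1)  # everyone answers on day 1
  res <- analyze_cohort(co$charts, co$soc, co$baselines, co$evaluations,
                        co$followups, co$chart_annotations)
  g <- res$sensitivity
  for (s in unique(g$stratum)) {
    rows <- g[g$stratum == s, ]
    # no barrier cycles: excluded == included
    for (w in unique(rows$window)) {
      a <- rows[rows$window == w & rows$barrier == "excluded", ]
      b <- rows[rows$window == w & rows$barrier == "included", ]
      expect_equal(a$cp_final, b$cp_final)
      expect_equal(a$cycles, b$cycles)
    }
    # all SOC on day 1: window arms identical
    for (bb in unique(rows$barrier)) {
      a <- rows[rows$barrier == bb & rows$window == "within_window", ]
      b <- rows[rows$barrier == bb & rows$window == "all", ]
      expect_equal(a$cp_final, b$cp_final)
    }
  }
})

test_that("flagging every cycle barrier-positive empties the excluded arm", {
  co <- small_cohort(n = 10, seed = 706)
  keys <- unique(co$charts[c("couple_id", "cycle_index")])
  all_flagged <- data.frame(couple_id = keys$couple_id,
                            cycle_index = keys$cycle_index,
                            barrier_withdrawal = TRUE)
  events <- data.frame(couple_id = keys$couple_id,
                       cycle_index = keys$cycle_index,
                       ordinal = keys$cycle_index, event = FALSE)
  g <- sensitivity_grid(co$soc, events, all_flagged)
  excl <- g[g$barrier == "excluded", ]
  expect_true(nrow(excl) == 0 || all(excl$cycles == 0))
})
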