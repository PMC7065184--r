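toy_records <- data.frame(
  time = c(1, 2, 3, 4, 4, 5),
  event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))

test_that("Kaplan-Meier estimates match the hand-computed product-limit table", {
  km <- km_estimate(toy_records)
  # by hand: S(1)=5/6, S(3)=5/6*3/4, S(4)=...*2/3, S(5)=0
  expect_equal(survival_at(km, 1), 5 / 6, tolerance = 1e-12)
  expect_equal(survival_at(km, 3), 0.625, tolerance = 1e-12)
  expect_equal(survival_at(km, 4), 5 / 12, tolerance = 1e-12)
  expect_equal(survival_at(km, 5), 0, tolerance = 1e-12)
  expect_equal(survival_at(km, 0), 1)
  # right-continuity: value holds until the next event
  expect_equal(survival_at(km, 3.9), 0.625, tolerance = 1e-12)
})

test_that("KM reduces to the ECDF complement without censoring and is monotone", {
  set.seed(16)
  for (i in 1:10) {
    times <- round(runif(10, 1, 100), 1)
    km <- km_estimate(data.frame(time = times, event = TRUE))
    for (t in c(10, 50, 90)) {
      if (t >= max(times)) next  # extrapolation beyond follow-up warns
      expect_equal(survival_at(km, t), mean(times > t), tolerance = 1e-12)
    }
    expect_true(all(diff(km$surv) <= 1e-12))
    # record order does not matter
    km2 <- km_estimate(data.frame(time = rev(times), event = TRUE))
    expect_equal(km2$surv, km$surv)
  }
  all_cens <- km_estimate(data.frame(time = c(10, 20, 30), event = FALSE))
  expect_equal(survival_at(all_cens, 25), 1)
  two_events <- km_estimate(data.frame(time = c(rep(100, 8), 20, 40),
                                       event = c(rep(FALSE, 8), TRUE, TRUE)))
  expect_equal(survival_at(two_events, 60), 0.8, tolerance = 1e-12)
  expect_error(km_estimate(data.frame(time = -1, event = TRUE)), "negative")
  expect_warning(survival_at(km_estimate(toy_records), 99), "extrapolat")
})

test_that("log-rank test matches the hand-computed O-E table", {
  rec <- data.frame(time = c(1, 3, 5, 2, 4, 6),
                    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                    group = rep(c("A", "B"), each = 3))
  lr <- logrank_test(rec)
  # by hand: O_A=2, E_A=1.4, Var=0.74 -> chi2 = 0.36/0.74
  expect_equal(lr$statistic, 0.36 / 0.74, tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(0.36 / 0.74, 1, lower.tail = FALSE))
  # two identical groups: statistic 0, p 1
  same <- data.frame(time = rep(c(5, 10, 15), 2),
                     event = rep(c(TRUE, FALSE, TRUE), 2),
                     group = rep(c("x", "y"), each = 3))
  lr0 <- logrank_test(same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # invariant under group relabelling
  relab <- same
  relab$group <- ifelse(relab$group == "x", "y", "x")
  expect_equal(logrank_test(relab)$statistic, lr0$statistic)
  expect_error(logrank_test(data.frame(time = 1, event = TRUE, group = "a")),
               "two groups")
})

test_that("log-rank type-I error is near nominal under the null", {
  set.seed(17)
  reject <- 0; reps <- 1000
  for (i in seq_len(reps)) {
    rec <- data.frame(time = rexp(60, 0.02), event = TRUE,
                      group = rep(c("a", "b"), each = 30))
    cens <- runif(60, 0, 100)
    rec$event <- rec$time <= cens
    rec$time <- pmin(rec$time, cens)
    if (logrank_test(rec)$p_value < 0.05) reject <- reject + 1
  }
  expect_gte(reject / reps, 0.03)
  expect_lte(reject / reps, 0.07)
})

test_that("reverse Kaplan-Meier follow-up matches hand computation", {
  # all censored at 60: median follow-up 60
  fu <- reverse_km_followup(data.frame(time = rep(60, 5), event = FALSE))
  expect_true(fu$reached)
  expect_equal(fu$median, 60)
  # all events: reverse curve never drops, median not reached
  fu2 <- reverse_km_followup(data.frame(time = c(5, 10, 20), event = TRUE))
  expect_false(fu2$reached)
  expect_true(is.na(fu2$median))
  # mixed toy set with flipped indicators: curve drops to 0.8 at t=2 then
  # 0.533 at t=4, so the median is the first time S <= 0.5 -> not reached
  fu3 <- reverse_km_followup(toy_records)
  expect_false(fu3$reached)
  # flipping one late censoring makes the median land at that time
  rec <- data.frame(time = c(10, 20, 30, 40), event = c(TRUE, FALSE, FALSE, FALSE))
  fu4 <- reverse_km_followup(rec)
  expect_true(fu4$reached)
  expect_equal(fu4$median, 30)
})

test_that("group survival summary reads curves at the horizon and compares groups", {
  set.seed(18)
  rec <- rbind(
    simulate_survival(120, 0.9, "good", censor_window = c(60, 180)),
    simulate_survival(120, 0.4, "poor", censor_window = c(60, 180)))
  ss <- survival_summary(rec, horizon = 60, reference_group = "poor")
  expect_setequal(ss$by_group$group, c("good", "poor"))
  expect_gt(ss$by_group$survival[ss$by_group$group == "good"],
            ss$by_group$survival[ss$by_group$group == "poor"])
  expect_lt(ss$logrank$p_value, 0.001)
  expect_equal(nrow(ss$pairwise), 1)
  # stage subsetting by exact match
  rec$stage <- rep(c("IA", "II"), length.out = nrow(rec))
  ss1 <- survival_summary(rec, subset_stage = c("I", "IA", "IB"))
  expect_equal(sum(ss1$by_group$n), sum(rec$stage == "IA"))
  expect_error(survival_summary(rec, subset_stage = "IV"), "no records")
})

test_that("exponential rates solved from 5-year survival reproduce it", {
  expect_equal(solve_exponential_rate(1), 0)
  expect_equal(solve_exponential_rate(exp(-1)), 1 / 60)
  expect_error(solve_exponential_rate(0), "rfs_5yr")
  expect_error(solve_exponential_rate(1.2), "rfs_5yr")
  # survival function of the solved rate hits the target exactly
  for (s in c(0.941, 0.922, 0.708)) {
    expect_equal(exp(-solve_exponential_rate(s) * 60), s, tolerance = 1e-12)
  }
})
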