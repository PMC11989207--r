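test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$times, c(0, 1, 2, 3))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  expect_equal(km$at_risk, c(3L, 3L, 2L, 1L))
  # all censored: curve stays at 1
  flat <- km_estimate(c(5, 9, 12), c(0, 0, 0))
  expect_true(all(flat$survival == 1))
  # events before censorings at a tied time
  tie <- km_estimate(c(1, 1), c(1, 0))
  expect_equal(tie$survival[length(tie$survival)], 0.5)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(km_estimate(c(1, 2), c(1, 2)), "0/1")
})

test_that("without censoring the KM curve is one minus the event-time ECDF", {
  set.seed(99)
  for (i in 1:10) {
    times <- round(stats::rexp(30, 0.2), 2)
    km <- km_estimate(times, rep(1, 30))
    for (j in seq_along(km$times)) {
      expect_equal(km$survival[j], mean(times > km$times[j]))
    }
  }
})

test_that("KM curve is monotone and agrees with the reference implementation", {
  set.seed(123)
  for (i in 1:10) {
    s <- random_survival_sample(40)
    km <- km_estimate(s$times, s$events)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$at_risk) <= 0))
    sf <- survival::survfit(survival::Surv(s$times, s$events) ~ 1)
    expect_equal(km$survival[match(sf$time, km$times)], sf$surv,
                 tolerance = 1e-12)
  }
})

test_that("event-free proportion reads the KM step function at a horizon", {
  # 4 events among 9 subjects, no censoring before the horizon
  times <- c(2, 4, 6, 8, rep(20, 5))
  events <- c(1, 1, 1, 1, rep(0, 5))
  expect_equal(event_free_proportion(times, events, 15), 5 / 9)
  expect_equal(event_free_proportion(times, events, 0), 1)
  expect_equal(event_free_proportion(c(3, 7), c(0, 0), 10), 1)
  expect_error(event_free_proportion(c(1, 2), c(1, 1), -1), "horizon")
})

test_that("log-rank test honors its contracts", {
  g <- list(times = c(1, 3, 5, 7), events = c(1, 0, 1, 0))
  same <- logrank_test(list(g, g))
  expect_equal(same$chi2, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  three <- logrank_test(list(
    list(times = c(1, 2, 9), events = c(1, 1, 0)),
    list(times = c(3, 4, 8), events = c(1, 0, 1)),
    list(times = c(5, 6, 7), events = c(0, 1, 1))))
  expect_identical(three$df, 2L)
  sep <- logrank_test(list(
    list(times = rep(1, 10), events = rep(1, 10)),
    list(times = rep(2, 10), events = rep(0, 10))))
  expect_gt(sep$chi2, 0)
  expect_lt(sep$p, 0.05)
  expect_error(logrank_test(list(g)), "two groups")
  expect_error(logrank_test(list(g, list(times = numeric(0),
                                         events = numeric(0)))),
               "no subjects")
})

test_that("log-rank chi-squared is invariant to group relabeling and matches survdiff", {
  set.seed(5)
  for (i in 1:8) {
    g1 <- random_survival_sample(25)
    g2 <- random_survival_sample(25)
    a <- logrank_test(list(g1, g2))
    b <- logrank_test(list(g2, g1))
    expect_equal(a$chi2, b$chi2, tolerance = 1e-10)
    sd <- survival::survdiff(
      survival::Surv(c(g1$times, g2$times), c(g1$events, g2$events)) ~
        rep(1:2, c(25, 25)))
    expect_equal(a$chi2, sd$chisq, tolerance = 1e-8)
  }
})
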