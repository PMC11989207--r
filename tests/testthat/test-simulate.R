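test_that("simulation config validates its parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n = 0), "positive integer")
  expect_error(simulation_config(ct_probs = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(simulation_config(dfs_hazards = c(low = -1, intermediate = 0,
                                                 high = 0)), "hazards")
  expect_error(simulation_config(mrtrg_link = 0), "positive")
  expect_error(simulation_config(cutoff = 120), "\\[0, 100\\]")
})

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(simulation_config(n = 100, seed = 17))
  b <- simulate_cohort(simulation_config(n = 100, seed = 17))
  expect_identical(a, b)
  c <- simulate_cohort(simulation_config(n = 100, seed = 18))
  expect_false(identical(a, c))
})

test_that("simulated cohorts are structurally valid patient records", {
  df <- simulate_cohort(simulation_config(n = 200, seed = 4))
  scored <- score_cohort(df)
  expect_true(all(encode_t_stage(df$ct_stage) %in% 2:4))
  expect_true(all(encode_t_stage(df$ypt_stage) <= encode_t_stage(df$ct_stage)))
  expect_true(all(encode_n_stage(df$ypn_stage) <= encode_n_stage(df$cn_stage)))
  expect_true(all(df$mrtrg %in% 1:5))
  expect_true(all(df$ptrg %in% 0:3))
  expect_true(all(df$dfs_months <= df$os_months))
  expect_true(all(df$dfs_months >= 0))
  # a death event always bounds the DFS time
  expect_true(all(df$dfs_event[df$os_event == 1] == 1))
  # mrTRG 1 forces radiologic complete response stages
  expect_true(all(df$rt_post_stage[df$mrtrg == 1] == "T0"))
  expect_true(all(df$rn_post_stage[df$mrtrg == 1] == "N0"))
  expect_false(any(is.na(scored$nar_path)))
})

test_that("pCR records carry the deep-response NAR value (12 - 3 cT)^2 / 9.61", {
  df <- simulate_cohort(simulation_config(n = 2000, seed = 21))
  scored <- score_cohort(df)
  pcr <- which(scored$pcr)
  expect_gt(length(pcr), 0)
  ct <- encode_t_stage(df$ct_stage[pcr])
  expect_equal(scored$nar_path[pcr], (12 - 3 * ct)^2 / 9.61)
  expect_true(all(scored$nar_path_cat[pcr] == "low"))
})

test_that("simulator recovers the configured pCR prevalence at large n", {
  df <- simulate_cohort(simulation_config(n = 10000, seed = 2024))
  scored <- score_cohort(df)
  rate <- mean(scored$pcr)
  se <- sqrt(0.43 * 0.57 / 10000)
  expect_lt(abs(rate - 0.43), 3 * se)
})

test_that("a positive immunoscore effect raises the pCR rate among IS-high", {
  df <- simulate_cohort(simulation_config(n = 10000, seed = 501))
  scored <- score_cohort(df)
  hi <- scored$pcr[scored$is_class == "high"]
  lo <- scored$pcr[scored$is_class == "low"]
  p_hi <- mean(hi); p_lo <- mean(lo)
  se <- sqrt(p_hi * (1 - p_hi) / length(hi) + p_lo * (1 - p_lo) / length(lo))
  expect_gt(p_hi - p_lo, 5 * se)
})

test_that("per-category hazards produce stochastically ordered KM curves", {
  cfg <- simulation_config(n = 10000, seed = 909,
                           dfs_hazards = c(low = 0, intermediate = 0.005,
                                           high = 0.01))
  scored <- score_cohort(simulate_cohort(cfg))
  km_at <- function(cat, t) {
    sel <- scored$nar_path_cat == cat
    event_free_proportion(scored$dfs_months[sel], scored$dfs_event[sel], t)
  }
  for (t in c(10, 20, 30, 40)) {
    expect_gte(km_at("low", t), km_at("intermediate", t))
    expect_gte(km_at("intermediate", t), km_at("high", t))
  }
})
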