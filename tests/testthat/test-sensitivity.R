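fx <- mqimp_fixture()
ev <- evaluate_from_first_level(fx$scores)

test_that("sensitive-indicator selection finds the published weak spots", {
  sel <- select_sensitive_indicators(ev, fx$counts)
  expect_equal(sel$dimensions, c("X4", "X6", "X8"))
  expect_equal(sel$secondaries$code, c("X4-2", "X6-1", "X6-2", "X8-3"))
  # X8-3 is the lowest-coverage indicator of all 27
  expect_equal(min(sel$secondaries$rate), 1 / 22)
  expect_equal(sel$secondaries$code[which.min(sel$secondaries$rate)], "X8-3")
  # uniform coverage: ties resolve to schema order
  uni <- dplyr::mutate(fx$counts, count = 11L)
  ev_uni <- evaluate_from_first_level(
    dplyr::mutate(fx$scores, dplyr::across(-policy_id, ~ 0.33)))
  sel_uni <- select_sensitive_indicators(ev_uni, uni, k_dimensions = 2, k_secondaries = 2)
  expect_equal(sel_uni$dimensions, c("X1", "X2"))
  expect_equal(sel_uni$secondaries$code, c("X1-1", "X1-2"))
  expect_warning(select_sensitive_indicators(ev, fx$counts, k_dimensions = 99),
                 regexp = "capped")
})

test_that("scenarios modify the target count as specified", {
  out <- apply_scenario(fx$counts, "X6-1", "full")
  expect_equal(out$count[out$code == "X6-1"], 22)
  part <- apply_scenario(fx$counts, "X6-1", "partial")
  expect_equal(part$count[part$code == "X6-1"], 10.4)
  expect_warning(sat <- apply_scenario(fx$counts, "X9-2", "full"), regexp = "saturated")
  expect_equal(sat$count, fx$counts$count)
  expect_error(apply_scenario(fx$counts, "X0-9", "full"), class = "pmcindex_input_error")
  down <- apply_scenario(fx$counts, "X6-1", "partial", mode = "round_down")
  expect_equal(down$count[down$code == "X6-1"], 10)
  up <- apply_scenario(fx$counts, "X6-1", "partial", mode = "round_up")
  expect_equal(up$count[up$code == "X6-1"], 11)
})

test_that("the three-scenario table reproduces the published sensitivity results", {
  sens <- run_sensitivity(fx$counts, c("X4-2", "X6-1", "X6-2", "X8-3"))
  expect_equal(sens$baseline, rep(6.29, 4))
  expect_equal(sens$full, c(6.50, 6.50, 6.50, 6.61))
  expect_equal(sens$partial[sens$target == "X6-1"], 6.32)
  expect_equal(sens$partial[sens$target == "X4-2"], 6.32)
  expect_false(any(sens$grade_changed))
  expect_true(all(as.character(sens$full_grade) == "Excellent"))
})

test_that("full-optimization shift obeys the closed form (n - count)/(3n)", {
  for (tg in c("X1-3", "X5-2", "X8-3")) {
    cnt <- fx$counts$count[fx$counts$code == tg]
    expected <- (sum(fx$counts$count) + (22 - cnt)) / 66
    out <- apply_scenario(fx$counts, tg, "full")
    expect_equal(sum(out$count) / 66, expected, tolerance = 1e-12)
    expect_gte(expected, sum(fx$counts$count) / 66) # monotone improvement
  }
})

test_that("stochastic partial mode is seed-reproducible and unbiased", {
  a <- apply_scenario(fx$counts, "X6-1", "partial", mode = "stochastic", seed = 5)
  b <- apply_scenario(fx$counts, "X6-1", "partial", mode = "stochastic", seed = 5)
  expect_identical(a, b)
  expect_error(apply_scenario(fx$counts, "X6-1", "partial", mode = "stochastic"),
               class = "pmcindex_input_error")
  draws <- vapply(1:200, function(s) {
    out <- apply_scenario(fx$counts, "X6-1", "partial", mode = "stochastic", seed = s)
    out$count[out$code == "X6-1"]
  }, numeric(1))
  # mean extra coverage matches the expected-value rule (2.4) within a
  # 99% normal-approximation band for 200 binomial draws
  extra <- draws - 8
  se <- sqrt(14 * (2.4 / 14) * (1 - 2.4 / 14) / 200)
  expect_lt(abs(mean(extra) - 2.4), 2.58 * se * 1.5)
})
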