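test_that("cumulative toxicity has the closed-form limit and monotonicity", {
  p1 <- c(0.05, 0.2, 0.5)
  expect_equal(cumulative_tox_prob(p1, tau = 4, decay = 1),
               1 - (1 - p1)^4)
  expect_equal(cumulative_tox_prob(0, 3, 1 / 3), 0)
  # monotone in p1 and in tau
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(cumulative_tox_prob(grid)) > 0))
  taus <- vapply(1:5, function(k) cumulative_tox_prob(0.2, tau = k),
                 numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_error(cumulative_tox_prob(1.2), "0, 1")
  expect_error(cumulative_tox_prob(0.3, tau = 0))
})

test_that("cycle-1 to full-follow-up conversion matches the scenario table", {
  full <- list(
    T1 = c(0.140, 0.166, 0.193, 0.219, 0.245, 0.270),
    T2 = c(0.140, 0.180, 0.219, 0.270, 0.332, 0.503),
    T3 = c(0.140, 0.270, 0.391, 0.503, 0.606, 0.701),
    T4 = c(0.391, 0.503, 0.556, 0.606, 0.655, 0.701),
    T5 = c(0.503, 0.556, 0.606, 0.655, 0.701, 0.746)
  )
  for (id in names(full)) {
    sc <- make_scenario(paste0(id, ".A1"))
    expect_equal(round(sc$tox_full, 3), full[[id]],
                 info = paste("safety pattern", id))
  }
  expect_equal(round(cumulative_tox_prob(0.3, 3, 1 / 3), 3), 0.391)
})

test_that("utility penalises toxicity above the threshold, strictly", {
  expect_equal(round(utility(0.5, 0.193), 2), 0.44)
  # at the threshold exactly the penalty is not triggered
  expect_equal(round(utility(0.5, 0.391), 2), 0.37)
  expect_equal(round(utility(0.3, 0.391), 2), 0.17)
  expect_equal(utility(0, 0), 0)
  # discontinuity at the threshold has magnitude omega2 * phi_tox
  eps <- 1e-9
  jump <- utility(0.5, 0.391) - utility(0.5, 0.391 + eps)
  expect_equal(jump, 1.09 * 0.391, tolerance = 1e-5)
  # non-increasing in toxicity for fixed activity
  pit <- seq(0, 1, by = 0.01)
  expect_true(all(diff(utility(0.6, pit)) < 0))
  expect_error(utility(1.2, 0.5), "0, 1")
})

test_that("scenario construction validates its invariants", {
  sc <- make_scenario("T2", "A3", act_cycle1_fraction = 1 / 6)
  expect_s3_class(sc, "dose_scenario")
  expect_equal(sc$act_cycle1, sc$act_full / 6)
  expect_true(all(sc$tox_cycle1 <= sc$tox_full))
  expect_equal(nrow(scenario_table()), 20)
  expect_error(make_scenario("T9.A1"), "unknown safety")
  expect_error(scenario_spec(c(2, 1), c(0.1, 0.2), c(0.1, 0.2)))
  expect_error(scenario_spec(c(1, 2), c(0.1, 1.2), c(0.1, 0.2)))
})

test_that("scenario files round-trip and the packaged fixture matches", {
  sc <- make_scenario("T4.A2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenario(sc, path)
  back <- read_scenario(path, id = "T4.A2")
  expect_equal(back$tox_cycle1, sc$tox_cycle1)
  expect_equal(back$tox_full, sc$tox_full)
  expect_equal(back$act_full, sc$act_full)

  fixture <- readr::read_csv(
    system.file("extdata", "table1_scenarios.csv", package = "lateobd"),
    show_col_types = FALSE)
  for (s in paste0("T", 1:5)) {
    expect_equal(fixture[[s]], make_scenario(s, "A1")$tox_cycle1, info = s)
  }
  for (a in paste0("A", 1:4)) {
    expect_equal(fixture[[a]], make_scenario("T1", a)$act_full, info = a)
  }
})

test_that("dose classification identifies the OBD and acceptable doses", {
  cl <- classify_doses(make_scenario("T2.A1"))
  expect_equal(attr(cl, "obd"), 3L) # 3.5 MBq
  expect_equal(which(cl$acceptable), 1:5)

  # toxicity exactly at target: judged by utility, 3.5 MBq wins
  expect_equal(attr(classify_doses(make_scenario("T3.A1")), "obd"), 3L)
  expect_equal(attr(classify_doses(make_scenario("T4.A1")), "obd"), 1L)
  expect_equal(attr(classify_doses(make_scenario("T2.A2")), "obd"), 5L)

  # all doses unsafe: no OBD, correct outcome is a safety stop
  cl5 <- classify_doses(make_scenario("T5.A1"))
  expect_true(attr(cl5, "no_obd"))
  expect_false(any(cl5$acceptable))
  expect_setequal(attr(cl5, "correct_stop_reasons"),
                  c("no_admissible", "lowest_unsafe", "hard_safety"))

  # all doses safe: no OBD either, correct outcome is the very-safe stop
  cl1 <- classify_doses(make_scenario("T1.A1"))
  expect_true(attr(cl1, "no_obd"))
  expect_true(all(cl1$acceptable))
  expect_equal(attr(cl1, "correct_stop_reasons"), "highest_very_safe")

  # only the top dose reaches the activity bound in T1.A4
  cl14 <- classify_doses(make_scenario("T1.A4"))
  expect_equal(which(cl14$acceptable), 6L)

  # zero activity everywhere: nothing acceptable
  dead <- scenario_spec(grid_doses, rep(0.1, 6), rep(0, 6))
  expect_false(any(classify_doses(dead)$acceptable))
})
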