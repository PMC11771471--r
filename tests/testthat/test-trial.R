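fast_mcmc <- mcmc_control(chains = 1, iter = 300, warmup = 300)

test_that("next-dose assignment maximises utility within the allowed set", {
  scores <- tibble::tibble(utility_mean = c(0.1, 0.2, 0.4, 0.4, 0.3, 0.5))
  expect_equal(assign_next_dose(scores, admissible = 2L, allowed = 1:6), 2L)
  # tie broken toward the lower dose
  expect_equal(assign_next_dose(scores, admissible = 3:4, allowed = 1:6), 3L)
  # best admissible dose blocked by the cap: best allowed dose instead
  expect_equal(assign_next_dose(scores, admissible = c(3L, 6L),
                                allowed = 1:4), 3L)
  # tie among allowed (0.4 at doses 3 and 4) resolves to the lower dose
  expect_equal(assign_next_dose(scores, admissible = 6L, allowed = 1:4), 3L)
  expect_true(is.na(assign_next_dose(scores, 6L, integer(0))))
})

test_that("trials are reproducible under a fixed seed", {
  sc <- make_scenario("T2.A1")
  for (d in c("joint_tite_crm", "model_assisted", "tite_b")) {
    r1 <- run_trial(sc, d, mcmc = fast_mcmc, seed = 14)
    r2 <- run_trial(sc, d, mcmc = fast_mcmc, seed = 14)
    expect_identical(r1$recommendation, r2$recommendation, info = d)
    expect_identical(r1$decisions, r2$decisions, info = d)
    expect_identical(r1$patients, r2$patients, info = d)
  }
})

test_that("designs on the same seed see the same patient stream", {
  sc <- make_scenario("T1.A2")
  a <- run_trial(sc, "joint_tite_crm", mcmc = fast_mcmc, seed = 8)
  b <- run_trial(sc, "tite_b", mcmc = fast_mcmc, seed = 8)
  shared <- seq_len(min(nrow(a$patients), nrow(b$patients)))
  same_dose <- a$patients$dose_index[shared] == b$patients$dose_index[shared]
  # wherever the two designs assigned the same dose, the latent event
  # times are identical
  expect_true(any(same_dose))
  expect_identical(a$patients$t_tox[shared][same_dose],
                   b$patients$t_tox[shared][same_dose])
})

test_that("a harmless dose range escalates to the top and stops very safe", {
  sc <- scenario_spec(grid_doses, tox_cycle1 = rep(0.001, 6),
                      act_full = rep(0.5, 6), id = "inert")
  r <- run_trial(sc, "joint_tite_crm", mcmc = fast_mcmc, seed = 3)
  expect_equal(r$stop_reason, "highest_very_safe")
  expect_true(is.na(r$recommendation))
  expect_false(any(r$patients$tox))
  # escalation never skips a level on the way up
  path <- r$patients |>
    dplyr::distinct(entry, dose_index) |>
    dplyr::arrange(entry)
  expect_true(all(diff(path$dose_index) <= 1))
})

test_that("an overdosed scenario stops for safety and spares patients", {
  sc <- make_scenario("T5.A1")
  reasons <- vapply(1:12, function(s) {
    run_trial(sc, "joint_tite_crm", mcmc = fast_mcmc, seed = s)$stop_reason
  }, character(1))
  expect_gt(sum(reasons %in% c("hard_safety", "lowest_unsafe",
                               "no_admissible")), 0)
})

test_that("cohort cadence differs between immediate and delayed designs", {
  sc <- make_scenario("T2.A2")
  tite <- run_trial(sc, "joint_tite_crm", mcmc = fast_mcmc, seed = 5)
  crm <- run_trial(sc, "joint_crm", mcmc = fast_mcmc, seed = 5)
  expect_equal(unique(diff(tite$decisions$time)), 1)
  expect_equal(unique(diff(crm$decisions$time)), 3)
  expect_equal(tite$duration_weeks, 6 * tite$duration_cycles)
})

test_that("no patient is assigned at or above an excluded dose", {
  sc <- make_scenario("T5.A2")
  for (s in 1:8) {
    r <- run_trial(sc, "joint_tite_crm", mcmc = fast_mcmc, seed = s)
    if (r$stop_reason %in% c("hard_safety", "lowest_unsafe")) next
    # reconstruct exclusions from cycle-1 DLTs as the trial saw them
    pat <- r$patients
    for (tt in sort(unique(pat$entry))) {
      seen <- pat$entry <= tt - 1
      counts <- tibble::tibble(
        dose_index = 1:6,
        events = tabulate(pat$dose_index[seen & pat$t_tox <= 1], 6),
        patients = tabulate(pat$dose_index[seen], 6))
      excl <- hard_safety_exclusion(counts, rule_config())
      if (!is.na(excl)) {
        expect_true(all(pat$dose_index[pat$entry >= tt] < excl))
      }
    }
  }
})

test_that("patients with a DLT contribute no later activity", {
  sc <- make_scenario("T4.A1")
  r <- run_trial(sc, "model_assisted", mcmc = fast_mcmc, seed = 6)
  pat <- r$patients
  hit <- pat$tox & pat$act
  # any patient with both events must have had activity before the DLT
  expect_true(all(pat$t_act[hit] <= pat$t_tox[hit]))
})

test_that("single-trial simulation summarises its own indicators", {
  sc <- make_scenario("T2.A1")
  sims <- simulate_trials(sc, "joint_tite_crm", n_sims = 1,
                          mcmc = fast_mcmc, seed = 20)
  r <- sims$results[[1]]
  truth <- classify_doses(sc)
  expect_equal(sims$oc$pct_correct,
               100 * as.numeric(!is.na(r$recommendation) &&
                                  r$recommendation == attr(truth, "obd")))
  expect_equal(sims$oc$mean_n, r$n_patients)
  expect_equal(sims$oc$n_sims, 1)
})
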