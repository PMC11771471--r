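test_that("admissible set applies both feasibility constraints", {
  all_good <- tibble::tibble(prob_safe = rep(1, 6), prob_active = rep(1, 6))
  expect_equal(admissible_set(all_good), 1:6)
  none <- tibble::tibble(prob_safe = rep(0, 6), prob_active = rep(1, 6))
  expect_equal(admissible_set(none), integer(0))
  mixed <- tibble::tibble(prob_safe = c(0.9, 0.5, 0.15, 0.05, 0.3, 0.12),
                          prob_active = c(0.05, 0.6, 0.2, 0.9, 0.11, 0.09))
  expect_equal(admissible_set(mixed), c(2L, 3L, 5L))
})

test_that("hard-safety boundary is exactly 3/3, 4/6, 5/9", {
  cfg <- rule_config()
  trigger <- function(e, n) {
    beta_exceed_prob(e, n, cfg$cycle1_cap) > cfg$zeta
  }
  # exhaustive enumeration over cohorts of three up to nine patients
  for (n in c(3, 6, 9)) {
    for (e in 0:n) {
      expected <- (n == 3 && e >= 3) || (n == 6 && e >= 4) ||
        (n == 9 && e >= 5)
      expect_equal(trigger(e, n), expected, info = paste(e, "of", n))
    }
  }
  # no data: prior only, P(p > 0.3) = 0.7 < 0.95
  expect_false(trigger(0, 0))

  counts <- tibble::tibble(events = c(0, 1, 4, 0, 0, 0),
                           patients = c(3, 6, 6, 3, 0, 0))
  expect_equal(hard_safety_exclusion(counts, cfg), 3L)
  counts$events[3] <- 3
  expect_true(is.na(hard_safety_exclusion(counts, cfg)))
})

test_that("K-fold cap limits escalation by dose value", {
  expect_true(k_fold_cap(2.5, 1.5, 2))
  expect_false(k_fold_cap(3.5, 1.5, 2))
  expect_true(k_fold_cap(7.0, 3.5, 2)) # exactly 2-fold is allowed
})

test_that("precision CVs use the scaled MAD over induced dose samples", {
  cfg <- rule_config()
  make_fit <- function(mtd, act_dose) {
    draws <- tibble::tibble(
      .chain = 1L, .iter = seq_along(mtd),
      beta_tox0 = qlogis(cfg$pi_tox_target) - mtd, beta_tox1 = 1,
      beta_act0 = qlogis(cfg$pi_act_target) - act_dose, beta_act1 = 1,
      psi = 0)
    structure(list(draws = draws), class = "joint_fit")
  }
  # degenerate draws: zero CV, rule satisfied
  f <- make_fit(rep(4, 10), rep(3, 10))
  expect_equal(unname(cv_precision(f, cfg)), c(0, 0))
  # median 4, raw MAD 1 -> CV = 1.4826 / 4 = 0.371 > 0.30
  f2 <- make_fit(c(3, 4, 5), c(3, 4, 5))
  expect_equal(unname(cv_precision(f2, cfg))[1], 1.4826 / 4,
               tolerance = 1e-12)
  # non-positive median leaves the CV undefined
  f3 <- make_fit(c(-2, -1, 0), c(3, 4, 5))
  expect_true(is.na(cv_precision(f3, cfg)[1]))
  # prior-only draws are far too diffuse to satisfy the rule
  f4 <- fit_joint(empty_obs(), grid_doses, iter = 500, warmup = 500,
                  seed = 9)
  expect_gt(cv_precision(f4, cfg)[1], 0.3)
})

test_that("stopping rules fire in their precedence order", {
  cfg <- rule_config()
  counts0 <- tibble::tibble(dose_index = 1:6, events = rep(0L, 6),
                            patients = rep(0L, 6))
  base <- list(n_patients = 12, cycle1_counts = counts0,
               lowest_excluded = NA_integer_, admissible = 1:6,
               next_dose = 2, n_at_next = 3, dosed_lowest = TRUE,
               dosed_highest = FALSE, n_followed = 12, cv = NULL,
               config = cfg)
  go <- function(...) {
    args <- utils::modifyList(base, list(...))
    do.call(check_stopping, args)
  }
  expect_false(go()$stopped)
  # rule 1: empty admissible set
  expect_equal(go(admissible = integer(0))$reason, "no_admissible")
  # rule 2: 2/3 cycle-1 DLTs at the lowest dose
  c2 <- counts0
  c2$events[1] <- 2L
  c2$patients[1] <- 3L
  expect_equal(go(cycle1_counts = c2)$reason, "lowest_unsafe")
  # rule 3: needs more than 0/3 clean patients at the top dose
  c3 <- counts0
  c3$patients[6] <- 3L
  expect_equal(1 - beta_exceed_prob(0, 3, 0.3), 1 - 0.7^4,
               tolerance = 1e-12)
  expect_false(go(cycle1_counts = c3, dosed_highest = TRUE)$stopped)
  c3$patients[6] <- 6L
  expect_equal(go(cycle1_counts = c3, dosed_highest = TRUE)$reason,
               "highest_very_safe")
  # rule 4: recommended dose already carries C_suff patients
  expect_equal(go(n_at_next = 30)$reason, "sufficient_info")
  # rule 5: precise enough, with enough followed patients
  expect_equal(go(cv = c(0.1, 0.2), n_followed = 30)$reason, "precision")
  expect_false(go(cv = c(0.1, 0.2), n_followed = 10)$stopped)
  expect_false(go(cv = c(0.1, 0.5), n_followed = 30)$stopped)
  # rule 6 beats everything
  expect_equal(go(lowest_excluded = 1L, admissible = integer(0))$reason,
               "hard_safety")
  # rule 7
  expect_equal(go(n_patients = 60)$reason, "max_patients")
  # precedence: max patients is reported before no-admissible
  expect_equal(go(n_patients = 60, admissible = integer(0))$reason,
               "max_patients")
  # idempotence
  expect_identical(go(admissible = integer(0)),
                   go(admissible = integer(0)))
})

test_that("relaxed mode disables the exploratory stopping rules", {
  cfg <- rule_config(relaxed = TRUE)
  counts <- tibble::tibble(dose_index = 1:6,
                           events = c(2L, rep(0L, 5)),
                           patients = c(3L, 0L, 0L, 0L, 0L, 6L))
  dec <- check_stopping(n_patients = 12, cycle1_counts = counts,
                        lowest_excluded = NA_integer_, admissible = 1:6,
                        next_dose = 2, n_at_next = 45, dosed_lowest = TRUE,
                        dosed_highest = TRUE, n_followed = 45,
                        cv = c(0.01, 0.01), config = cfg)
  expect_false(dec$stopped)
  # hard stops still apply
  dec2 <- check_stopping(n_patients = 60, cycle1_counts = counts,
                         lowest_excluded = NA_integer_, admissible = 1:6,
                         config = cfg)
  expect_equal(dec2$reason, "max_patients")
})
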