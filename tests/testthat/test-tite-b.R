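test_that("power model evaluates correctly", {
  expect_equal(power_model_prob(0.30, 0), 0.30)
  expect_equal(power_model_prob(0.30, log(2)), 0.09)
  expect_equal(power_model_prob(0.02, -50), 1)
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(power_model_prob(p, 0.7)) > 0))
})

test_that("candidate-model count shrinks with accrual and floors at one", {
  expect_equal(titeb_n_candidates(0, 60), 11L)
  expect_equal(titeb_n_candidates(30, 60), 3L) # ceiling(0.25 * 11)
  expect_equal(titeb_n_candidates(59, 60), 1L)
  expect_equal(titeb_n_candidates(60, 60), 1L)
  cfg <- titeb_config()
  expect_equal(nrow(cfg$act_skeletons), 2 * length(cfg$tox_skeleton) - 1)
})

test_that("toxicity estimator agrees with a Monte-Carlo prior integral", {
  cfg <- titeb_config()
  # no data: plain prior expectation of p^exp(theta)
  est0 <- titeb_tox_estimates(empty_obs(), cfg)
  set.seed(12)
  th <- rnorm(2e5, 0, sqrt(cfg$prior_var))
  mc0 <- vapply(cfg$tox_skeleton, function(p) mean(p^exp(th)), numeric(1))
  expect_equal(est0, mc0, tolerance = 2e-3)

  # with data: importance weighting by the likelihood under the prior
  obs <- fixture_obs()
  est <- titeb_tox_estimates(obs, cfg)
  skel <- cfg$tox_skeleton[obs$dose_level]
  lw <- vapply(th, function(t) {
    psi <- skel^exp(t)
    sum(ifelse(obs$y_tox == 1, log(psi), log(1 - obs$w_tox * psi)))
  }, numeric(1))
  w <- exp(lw - max(lw))
  mc <- vapply(cfg$tox_skeleton, function(p) {
    sum(p^exp(th) * w) / sum(w)
  }, numeric(1))
  expect_equal(est, mc, tolerance = 2e-3)

  # a clean run of DLT-free complete observations shifts estimates down
  clean <- tibble::tibble(dose_level = rep(4L, 12), y_act = 0L, y_tox = 0L,
                          w_act = 1, w_tox = 1)
  expect_true(all(titeb_tox_estimates(clean, cfg) < est0))
})

test_that("working-model probabilities normalise and identify the truth", {
  cfg <- titeb_config()
  f0 <- fit_titeb(empty_obs(), cfg)
  expect_equal(f0$kappa, rep(1 / 11, 11))
  expect_equal(sum(f0$kappa), 1, tolerance = 1e-12)

  # data generated from skeleton row 3 concentrates kappa on model 3
  set.seed(33)
  lev <- rep(1:6, each = 10)
  dat <- tibble::tibble(dose_level = lev,
                        y_act = rbinom(60, 1, cfg$act_skeletons[3, lev]),
                        y_tox = 0L, w_act = 1, w_tox = 1)
  f3 <- fit_titeb(dat, cfg)
  expect_equal(which.max(f3$kappa), 3L)
  expect_equal(sum(f3$kappa), 1, tolerance = 1e-12)
})

test_that("safety gate and randomisation behave as specified", {
  cfg <- titeb_config()
  fake <- structure(list(pi_tox_hat = c(0.1, 0.25, 0.38, 0.45, 0.6, 0.9),
                         kappa = rep(1 / 11, 11),
                         act_means = matrix(0.5, 11, 6), config = cfg,
                         doses = 1:6, n_obs = 0L), class = "titeb_fit")
  expect_equal(titeb_safe_set(fake), 1:3)
  expect_equal(titeb_safe_set(fake, xi = 0.05), integer(0))

  f0 <- fit_titeb(empty_obs(), cfg)
  r <- titeb_randomization(f0, n = 0, N = 60)
  expect_equal(sum(r$r_star), 1, tolerance = 1e-12)
  # every model recommending the same dose: degenerate randomisation
  same <- fake
  same$act_means <- matrix(rep(c(0.9, rep(0.1, 5)), each = 11), 11, 6)
  r2 <- titeb_randomization(same, n = 30, N = 60, allowed = 1:3)
  expect_equal(r2$r_star[1], 1)

  # a single working model reduces to deterministic selection
  cfg1 <- titeb_config(act_skeletons = matrix(c(0.2, 0.3, 0.4, 0.5,
                                                0.59, 0.59), 1, 6),
                       model_weights = 1)
  f1 <- fit_titeb(empty_obs(), cfg1)
  r1 <- titeb_randomization(f1, n = 0, N = 60, allowed = 1:6)
  expect_equal(sum(r1$r_star > 0), 1)
  expect_equal(which(r1$r_star > 0), 5L) # plateau tie resolved downward
})

test_that("randomisation keeps the top candidate models by kappa", {
  cfg <- titeb_config()
  fake <- structure(list(pi_tox_hat = rep(0.1, 6),
                         kappa = c(0.3, 0.25, 0.2, 0.1, 0.05, 0.04,
                                   0.02, 0.02, 0.01, 0.005, 0.005),
                         act_means = cfg$act_skeletons, config = cfg,
                         doses = 1:6, n_obs = 0L), class = "titeb_fit")
  # n = 45 of 60: L' = ceiling(0.0625 * 11) = 1 -> only model 1 remains,
  # whose best dose is dose 1
  r <- titeb_randomization(fake, n = 45, N = 60, allowed = 1:6)
  expect_equal(which(r$r_star > 0), 1L)
  # n = 30: L' = 3, models 1-3 recommend doses 1, 2, 3
  r3 <- titeb_randomization(fake, n = 30, N = 60, allowed = 1:6)
  expect_equal(which(r3$r_star > 0), 1:3)
  expect_equal(r3$r_star[1:3], c(0.3, 0.25, 0.2) / 0.75)
})
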