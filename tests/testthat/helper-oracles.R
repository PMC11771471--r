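# Independent brute-force oracles and shared fixtures for the tests.

# Joint Gumbel-logistic log-likelihood computed directly from the cell
# formula (no flooring, no compiled code).
oracle_joint_loglik <- function(data, beta_tox, beta_act, psi) {
  gT <- data$w_tox * plogis(beta_tox[1] + beta_tox[2] * data$dose)
  gA <- data$w_act * plogis(beta_act[1] + beta_act[2] * data$dose)
  g <- (exp(psi) - 1) / (exp(psi) + 1)
  corr <- gA * (1 - gA) * gT * (1 - gT) * g
  cell <- ifelse(data$y_act == 1,
                 ifelse(data$y_tox == 1, gA * gT + corr,
                        gA * (1 - gT) - corr),
                 ifelse(data$y_tox == 1, (1 - gA) * gT - corr,
                        (1 - gA) * (1 - gT) + corr))
  sum(log(cell))
}

# Dynamic-Beta log-likelihood by direct per-patient products.
oracle_ma_loglik <- function(data, b_tox, b_act) {
  pT <- 1 - cumprod(1 - b_tox)
  pA <- 1 - cumprod(1 - b_act)
  pt <- data$w_tox * pT[data$dose_level]
  pa <- data$w_act * pA[data$dose_level]
  sum(log(ifelse(data$y_tox == 1, pt, 1 - pt))) +
    sum(log(ifelse(data$y_act == 1, pa, 1 - pa)))
}

# Mixed six-patient fixture with partial follow-up; events carry weight 1.
fixture_obs <- function() {
  tibble::tibble(
    dose = c(1.5, 1.5, 2.5, 3.5, 3.5, 4.5),
    dose_level = c(1L, 1L, 2L, 3L, 3L, 4L),
    y_act = c(0L, 1L, 0L, 1L, 0L, 0L),
    y_tox = c(0L, 0L, 1L, 0L, 1L, 0L),
    w_act = c(1 / 3, 1, 2 / 3, 1, 0.4, 2 / 3),
    w_tox = c(1 / 3, 2 / 3, 1, 1, 1, 2 / 3)
  )
}

empty_obs <- function() {
  tibble::tibble(dose = numeric(0), dose_level = integer(0),
                 y_act = integer(0), y_tox = integer(0),
                 w_act = numeric(0), w_tox = numeric(0))
}

# A degenerate fitted object whose per-dose probability draws repeat a
# single truth vector; reuses the ma_fit scoring path.
degenerate_fit <- function(tox, act, doses, n_draws = 4) {
  structure(list(tox = matrix(tox, n_draws, length(doses), byrow = TRUE),
                 act = matrix(act, n_draws, length(doses), byrow = TRUE),
                 doses = doses, n_obs = 0L),
            class = "ma_fit")
}

grid_doses <- c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0)
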