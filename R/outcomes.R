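#' Correlated late-onset outcome generator
#'
#' Event times for toxicity and activity are drawn from a bivariate
#' lognormal: log times are bivariate normal with per-dose marginal
#' parameters matched to the cycle-1 and full-follow-up probabilities of
#' each outcome, and log-scale correlation `rho` (-1/2 in the base
#' setting, so early activity goes with later toxicity).  An event is
#' observed only if it falls inside the follow-up window; activity is
#' additionally censored at the DLT time because a patient leaves the
#' trial on DLT.
#'
#' @name outcome_generator
NULL

#' Match lognormal event-time parameters to two interval probabilities
#'
#' Finds the unique `(meanlog, sdlog)` for which the event time satisfies
#' `P(T <= 1) = p_cycle1` and `P(T <= tau) = p_full` (time unit = one
#' cycle).  Closed form: with `z1 = qnorm(p_cycle1)` and
#' `zf = qnorm(p_full)`, `sdlog = log(tau) / (zf - z1)` and
#' `meanlog = -z1 * sdlog`.
#'
#' @param p_cycle1,p_full Probabilities of an event by the end of cycle 1
#'   and by the end of follow-up; must satisfy `0 < p_cycle1 < p_full < 1`.
#' @param tau Follow-up length in cycles (> 1).
#' @return A tibble with columns `meanlog` and `sdlog`.
#' @export
match_lognormal_params <- function(p_cycle1, p_full, tau = 3) {
  stopifnot(length(p_cycle1) == length(p_full), tau > 1)
  if (any(p_cycle1 <= 0 | p_full >= 1 | p_cycle1 >= p_full)) {
    stop("need 0 < p_cycle1 < p_full < 1 to match a lognormal marginal",
         call. = FALSE)
  }
  z1 <- qnorm(p_cycle1)
  zf <- qnorm(p_full)
  sdlog <- log(tau) / (zf - z1)
  tibble::tibble(meanlog = -z1 * sdlog, sdlog = sdlog)
}

#' Per-dose lognormal truth for a scenario
#'
#' @param scenario A `dose_scenario`.
#' @return A tibble of class `outcome_model`, one row per dose, with the
#'   matched `(meanlog, sdlog)` of the toxicity and activity event times
#'   and attributes `rho` and `tau`.
#' @export
outcome_model <- function(scenario) {
  stopifnot(inherits(scenario, "dose_scenario"))
  tau <- attr(scenario, "tau")
  tox <- match_lognormal_params(scenario$tox_cycle1, scenario$tox_full, tau)
  act <- match_lognormal_params(scenario$act_cycle1, scenario$act_full, tau)
  out <- tibble::tibble(
    dose_mbq = scenario$dose_mbq,
    meanlog_tox = tox$meanlog, sdlog_tox = tox$sdlog,
    meanlog_act = act$meanlog, sdlog_act = act$sdlog
  )
  structure(out, rho = attr(scenario, "event_time_corr"), tau = tau,
            class = c("outcome_model", class(out)))
}

#' Draw correlated standard-normal pairs
#'
#' One pair per (potential) patient.  Keeping these latent normals fixed
#' while varying the dose makes the outcome stream common across designs
#' run on the same seed: a patient's event times at any dose are a
#' deterministic transform of their pair.
#'
#' @param n Number of pairs.
#' @param rho Correlation.
#' @return An `n` x 2 matrix.
#' @export
draw_latent_normals <- function(n, rho = -0.5) {
  stopifnot(n >= 1, rho > -1, rho < 1)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

#' Event times at a dose from latent normal pairs
#'
#' @param model An [outcome_model()].
#' @param dose_index Dose level (row of `model`).
#' @param z Matrix of latent standard-normal pairs (toxicity first
#'   column).
#' @return A tibble with columns `t_tox` and `t_act` in cycles.
#' @export
outcome_times <- function(model, dose_index, z) {
  stopifnot(inherits(model, "outcome_model"),
            dose_index >= 1, dose_index <= nrow(model))
  m <- model[dose_index, ]
  tibble::tibble(
    t_tox = exp(m$meanlog_tox + m$sdlog_tox * z[, 1]),
    t_act = exp(m$meanlog_act + m$sdlog_act * z[, 2])
  )
}

#' Sample outcome-time pairs at one dose
#'
#' @inheritParams outcome_times
#' @param n Number of patients.
#' @return A tibble with columns `t_tox` and `t_act`.
#' @export
sample_outcomes <- function(model, dose_index, n) {
  z <- draw_latent_normals(n, attr(model, "rho"))
  outcome_times(model, dose_index, z)
}

#' Time-to-event weights for partially followed patients
#'
#' The weight of an incomplete observation is the completed fraction of
#' follow-up, `u / tau`, with `u` the number of completed cycles (capped
#' at `tau`).  An observed event gets weight 1.  Activity censored by an
#' earlier DLT gets weight `(DLT time - entry) / tau`.
#'
#' @param entry Entry time (cycles).
#' @param current_time Current trial time (>= entry).
#' @param tau Follow-up length in cycles.
#' @param tox_time,act_time Event times since entry, or `NA` when the
#'   event has not been generated/observed.  Vectorised over patients.
#' @return A tibble with logical `tox`, `act` and numeric `w_tox`,
#'   `w_act` columns.
#' @export
tite_weights <- function(entry, current_time, tau = 3,
                         tox_time = NA_real_, act_time = NA_real_) {
  stopifnot(all(current_time >= entry))
  n <- max(length(entry), length(current_time),
           length(tox_time), length(act_time))
  entry <- rep_len(entry, n)
  current_time <- rep_len(current_time, n)
  tox_time <- rep_len(tox_time, n)
  act_time <- rep_len(act_time, n)

  follow <- pmin(current_time - entry, tau)
  u <- pmin(floor(follow), tau)
  tox <- !is.na(tox_time) & tox_time <= follow
  cens <- follow
  cens[tox] <- pmin(cens[tox], tox_time[tox])
  act <- !is.na(act_time) & act_time <= cens
  w_tox <- u / tau
  w_tox[tox] <- 1
  w_act <- u / tau
  w_act[tox & !act] <- tox_time[tox & !act] / tau
  w_act[act] <- 1
  tibble::new_tibble(list(tox = tox, act = act, w_tox = w_tox,
                          w_act = w_act), nrow = n)
}

#' Observe latent outcomes at a trial horizon
#'
#' Applies the follow-up window and DLT censoring to latent event times:
#' toxicity is observed iff `t_tox <= min(horizon - entry, tau)`;
#' activity iff `t_act <= min(horizon - entry, tau, t_tox)`.
#'
#' @param times Tibble with `t_tox`, `t_act` (cycles since entry).
#' @param entry Entry times (cycles).
#' @param horizon Current trial time (cycles).
#' @param tau Follow-up length.
#' @return A tibble with `tox`, `act`, `w_tox`, `w_act`, and the elapsed
#'   follow-up `follow_up` (capped at `tau`).
#' @export
observe_outcomes <- function(times, entry, horizon, tau = 3) {
  w <- tite_weights(entry, horizon, tau,
                    tox_time = times$t_tox, act_time = times$t_act)
  w$follow_up <- pmin(horizon - rep_len(entry, nrow(w)), tau)
  w
}
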