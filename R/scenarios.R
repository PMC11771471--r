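#' Simulation scenarios: dose grids, true outcome probabilities and utility
#'
#' The simulation study investigates six doses of a targeted alpha therapy
#' (1.5, 2.5, 3.5, 4.5, 6.0 and 7.0 MBq) followed for `tau = 3` treatment
#' cycles of six weeks each.  A scenario combines one of five safety
#' patterns (`T1`--`T5`, cycle-1 DLT probabilities per dose) with one of
#' four activity patterns (`A1`--`A4`, full-follow-up activity
#' probabilities per dose).  Full-follow-up DLT probabilities are derived
#' from the cycle-1 values by assuming the conditional per-cycle DLT
#' probability decays by a factor of 1/3 in each later cycle.
#'
#' @name scenarios
NULL

.default_doses <- c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0)

.safety_patterns <- list(
  T1 = c(0.100, 0.120, 0.140, 0.160, 0.180, 0.200),
  T2 = c(0.100, 0.130, 0.160, 0.200, 0.250, 0.400),
  T3 = c(0.100, 0.200, 0.300, 0.400, 0.500, 0.600),
  T4 = c(0.300, 0.400, 0.450, 0.500, 0.550, 0.600),
  T5 = c(0.400, 0.450, 0.500, 0.550, 0.600, 0.650)
)

.activity_patterns <- list(
  A1 = c(0.300, 0.400, 0.500, 0.500, 0.500, 0.500),
  A2 = c(0.200, 0.300, 0.400, 0.500, 0.600, 0.700),
  A3 = c(0.100, 0.150, 0.200, 0.300, 0.500, 0.700),
  A4 = c(0.100, 0.120, 0.140, 0.160, 0.180, 0.200)
)

#' Cumulative DLT probability over a multi-cycle follow-up
#'
#' Converts a cycle-1 DLT probability into the probability of a DLT at any
#' point in a `tau`-cycle follow-up, assuming the conditional probability
#' of a DLT in cycle `c` (given no DLT before) is `p1 * decay^(c-1)`.
#' With `decay = 1` this reduces to `1 - (1 - p1)^tau`.
#'
#' @param p1 Cycle-1 DLT probability (vectorised).
#' @param tau Number of follow-up cycles (integer, >= 1).
#' @param decay Per-cycle conditional reduction factor in (0, 1].
#' @return Cumulative DLT probability over `tau` cycles.
#' @examples
#' cumulative_tox_prob(0.3) # 0.391, the full-follow-up toxicity target
#' @export
cumulative_tox_prob <- function(p1, tau = 3, decay = 1 / 3) {
  stopifnot(is.numeric(p1), is.numeric(tau), length(tau) == 1, tau >= 1,
            tau == as.integer(tau), length(decay) == 1,
            decay > 0, decay <= 1)
  if (any(p1 < 0 | p1 > 1, na.rm = TRUE)) {
    stop("`p1` must lie in [0, 1]", call. = FALSE)
  }
  hazards <- outer(p1, decay^(seq_len(tau) - 1))
  1 - apply(1 - hazards, 1, prod)
}

#' Utility weights and toxicity penalty threshold
#'
#' The dose-selection utility is
#' `U(piA, piT) = piA - omega1 * piT - omega2 * piT * 1(piT > phi_tox)`:
#' activity minus a linear toxicity cost, with an additional penalty once
#' the toxicity probability strictly exceeds the threshold `phi_tox`
#' (the full-follow-up toxicity target, 0.391).
#'
#' @param omega1 Linear toxicity weight.
#' @param omega2 Penalty weight applied above the threshold.
#' @param phi_tox Toxicity probability threshold triggering the penalty.
#' @return A list of class `utility_params`.
#' @export
utility_params <- function(omega1 = 0.33, omega2 = 1.09, phi_tox = 0.391) {
  stopifnot(omega1 >= 0, omega2 >= 0, phi_tox > 0, phi_tox < 1)
  structure(list(omega1 = omega1, omega2 = omega2, phi_tox = phi_tox),
            class = "utility_params")
}

#' Dose-selection utility of an (activity, toxicity) probability pair
#'
#' @param pi_act,pi_tox Probabilities of activity and toxicity over the
#'   full follow-up (vectorised, recycled to common length).
#' @param params A [utility_params()] object.
#' @return Utility values; the penalty indicator is strict
#'   (`pi_tox > phi_tox`), so a dose sitting exactly at the threshold is
#'   not penalised.
#' @examples
#' utility(0.5, 0.193) # 0.44 at the plateau dose of a safe scenario
#' @export
utility <- function(pi_act, pi_tox, params = utility_params()) {
  stopifnot(inherits(params, "utility_params"))
  if (any(pi_act < 0 | pi_act > 1 | pi_tox < 0 | pi_tox > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pi_act - params$omega1 * pi_tox -
    params$omega2 * pi_tox * (pi_tox > params$phi_tox)
}

#' Construct a simulation scenario
#'
#' Builds the per-dose truth table for one safety/activity combination.
#' Either give a combined id (`"T2.A1"`) or the two pattern names.
#' Custom truths can be supplied through `scenario_spec()`.
#'
#' @param safety Safety pattern name (`"T1"`..`"T5"`) or a combined id
#'   such as `"T2.A1"`.
#' @param activity Activity pattern name (`"A1"`..`"A4"`); ignored when
#'   `safety` is a combined id.
#' @param tau Follow-up length in cycles.
#' @param act_cycle1_fraction Fraction of the full-follow-up activity
#'   probability already realised by the end of cycle 1 (1/3 in the base
#'   setting; 1/6 and 1/2 are the alternative time trends).
#' @param decay Per-cycle conditional DLT decay used to derive
#'   full-follow-up toxicity from the cycle-1 values.
#' @param event_time_corr Correlation of log event times in the outcome
#'   generator.
#' @return A tibble of class `dose_scenario` with one row per dose and
#'   columns `dose_mbq`, `tox_cycle1`, `tox_full`, `act_full`,
#'   `act_cycle1`, plus attributes `id`, `tau`, `act_cycle1_fraction` and
#'   `event_time_corr`.
#' @examples
#' make_scenario("T2.A1")
#' @export
make_scenario <- function(safety = "T1", activity = "A1", tau = 3,
                          act_cycle1_fraction = 1 / 3, decay = 1 / 3,
                          event_time_corr = -0.5) {
  if (grepl(".", safety, fixed = TRUE)) {
    parts <- strsplit(safety, ".", fixed = TRUE)[[1]]
    safety <- parts[1]
    activity <- parts[2]
  }
  if (!safety %in% names(.safety_patterns)) {
    stop("unknown safety pattern: ", safety, call. = FALSE)
  }
  if (!activity %in% names(.activity_patterns)) {
    stop("unknown activity pattern: ", activity, call. = FALSE)
  }
  scenario_spec(
    dose_mbq = .default_doses,
    tox_cycle1 = .safety_patterns[[safety]],
    act_full = .activity_patterns[[activity]],
    tau = tau, act_cycle1_fraction = act_cycle1_fraction,
    decay = decay, event_time_corr = event_time_corr,
    id = paste0(safety, ".", activity)
  )
}

#' @rdname make_scenario
#' @param dose_mbq Strictly increasing positive dose values.
#' @param tox_cycle1 Per-dose cycle-1 DLT probabilities.
#' @param act_full Per-dose full-follow-up activity probabilities.
#' @param id Scenario label.
#' @export
scenario_spec <- function(dose_mbq, tox_cycle1, act_full, tau = 3,
                          act_cycle1_fraction = 1 / 3, decay = 1 / 3,
                          event_time_corr = -0.5, id = "custom") {
  stopifnot(length(dose_mbq) >= 2, all(dose_mbq > 0),
            all(diff(dose_mbq) > 0),
            length(tox_cycle1) == length(dose_mbq),
            length(act_full) == length(dose_mbq),
            all(tox_cycle1 >= 0 & tox_cycle1 <= 1),
            all(act_full >= 0 & act_full <= 1),
            tau >= 1, act_cycle1_fraction > 0, act_cycle1_fraction < 1,
            event_time_corr > -1, event_time_corr < 1)
  out <- tibble::tibble(
    dose_mbq = dose_mbq,
    tox_cycle1 = tox_cycle1,
    tox_full = cumulative_tox_prob(tox_cycle1, tau = tau, decay = decay),
    act_full = act_full,
    act_cycle1 = act_cycle1_fraction * act_full
  )
  structure(out, id = id, tau = tau,
            act_cycle1_fraction = act_cycle1_fraction,
            decay = decay, event_time_corr = event_time_corr,
            class = c("dose_scenario", class(out)))
}

#' All packaged scenarios
#'
#' @return A tibble with one row per safety x activity combination and a
#'   list-column `scenario` of [make_scenario()] objects.
#' @export
scenario_table <- function() {
  grid <- tidyr::expand_grid(safety = names(.safety_patterns),
                             activity = names(.activity_patterns))
  dplyr::mutate(grid,
    id = paste0(.data$safety, ".", .data$activity),
    scenario = purrr::map2(.data$safety, .data$activity, make_scenario)
  )
}

#' Read or write a scenario file
#'
#' Scenario files are plain CSV with columns `dose_mbq`, `tox_cycle1` and
#' `act_full`; scalar settings are passed as arguments.  A fixture with
#' the packaged safety/activity patterns in wide form ships in
#' `system.file("extdata", "table1_scenarios.csv", package = "lateobd")`.
#'
#' @param path CSV file path.
#' @inheritParams make_scenario
#' @inheritParams scenario_spec
#' @return `read_scenario()` returns a `dose_scenario`;
#'   `write_scenario()` invisibly returns `path`.
#' @export
read_scenario <- function(path, tau = 3, act_cycle1_fraction = 1 / 3,
                          decay = 1 / 3, event_time_corr = -0.5,
                          id = basename(path)) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("dose_mbq", "tox_cycle1", "act_full") %in% names(df)))
  scenario_spec(df$dose_mbq, df$tox_cycle1, df$act_full, tau = tau,
                act_cycle1_fraction = act_cycle1_fraction, decay = decay,
                event_time_corr = event_time_corr, id = id)
}

#' @rdname read_scenario
#' @param scenario A `dose_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "dose_scenario"))
  readr::write_csv(scenario[c("dose_mbq", "tox_cycle1", "act_full")], path)
  invisible(path)
}

#' Classify doses of a scenario as OBD, acceptable or unacceptable
#'
#' A dose is *acceptable* when it is truly safe
#' (`tox_full <= pi_tox_target`) and truly active
#' (`act_full >= pi_act_target`).  The OBD is the acceptable dose with
#' the highest utility.  When no dose is acceptable there is no OBD, and
#' the correct trial outcome is an early stop for safety/futility.  When
#' *all* doses are safe there is also no OBD: the dose range sits below
#' the toxicity target and the correct outcome is to stop because the
#' highest dose is very safe, so that a higher dose set can be
#' investigated.
#'
#' @param scenario A `dose_scenario`.
#' @param pi_tox_target Full-follow-up toxicity target.
#' @param pi_act_target Lower bound on target activity.
#' @param params Utility parameters.
#' @return A tibble with per-dose `utility`, `acceptable` and `label`
#'   columns; attributes `obd` (dose index or `NA`), `no_obd` and
#'   `correct_stop_reasons` (stop reasons counted as a correct trial
#'   outcome when there is no OBD).
#' @export
classify_doses <- function(scenario, pi_tox_target = 0.391,
                           pi_act_target = 0.2,
                           params = utility_params()) {
  stopifnot(inherits(scenario, "dose_scenario"))
  out <- tibble::as_tibble(scenario)
  out$utility <- utility(out$act_full, out$tox_full, params)
  out$acceptable <- out$tox_full <= pi_tox_target &
    out$act_full >= pi_act_target
  all_safe <- all(out$tox_full <= pi_tox_target)
  if (!any(out$acceptable) || all_safe) {
    obd <- NA_integer_
  } else {
    acc <- which(out$acceptable)
    obd <- acc[which.max(out$utility[acc])]
  }
  out$label <- ifelse(out$acceptable, "acceptable", "unacceptable")
  if (!is.na(obd)) out$label[obd] <- "OBD"
  reasons <- if (!is.na(obd)) {
    character(0)
  } else if (all_safe) {
    "highest_very_safe"
  } else {
    c("no_admissible", "lowest_unsafe", "hard_safety")
  }
  structure(out, obd = obd, no_obd = is.na(obd),
            correct_stop_reasons = reasons,
            class = c("dose_classification", class(out)))
}
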