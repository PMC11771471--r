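#' Trial state machine
#'
#' Runs one simulated trial of any of the four designs on a common
#' patient stream.  Cohorts of three enter at the start of each cycle;
#' the first cohort receives the lowest dose and escalation proceeds one
#' level per cycle while no DLT has been observed.  On the first
#' observed DLT the design's model takes over dose assignment
#' permanently.  Decisions are taken at cycle boundaries; the
#' complete-follow-up joint CRM instead takes a decision (and admits a
#' new cohort) only every `tau` cycles, once the previous cohort is
#' fully followed.
#'
#' @name trial_engine
NULL

.designs <- c("joint_tite_crm", "joint_crm", "model_assisted", "tite_b")

#' MCMC settings for trial fitting
#'
#' @param chains Number of chains.
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup (adaptation) iterations per chain.
#' @param thin Keep every `thin`-th post-warmup state.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, iter = 1000, warmup = 1000, thin = 1) {
  stopifnot(chains >= 1, iter >= 2, warmup >= 10, thin >= 1)
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 thin = thin),
            class = "mcmc_control")
}

# Dose assignment among scored candidates: argmax posterior mean
# utility, ties broken toward the lower dose (which.max picks the
# first, i.e. lowest, index).
.best_utility_dose <- function(scores, candidates) {
  if (length(candidates) == 0) return(NA_integer_)
  candidates[which.max(scores$utility_mean[candidates])]
}

#' Pick the next dose for a utility-based design
#'
#' Argmax posterior mean utility within the admissible doses that are
#' also assignable (not excluded, within the K-fold cap); when the cap
#' blocks every admissible dose, the best assignable dose is chosen
#' instead so that the experimented range can expand.  Ties go to the
#' lower dose.
#'
#' @param scores Output of [score_doses()].
#' @param admissible Admissible dose indices.
#' @param allowed Assignable dose indices (exclusions and K-fold cap).
#' @return A dose index, or `NA` when nothing is assignable.
#' @export
assign_next_dose <- function(scores, admissible, allowed) {
  pick <- .best_utility_dose(scores, intersect(admissible, allowed))
  if (is.na(pick)) pick <- .best_utility_dose(scores, allowed)
  pick
}

#' Run one simulated trial
#'
#' @param scenario A `dose_scenario` defining the simulation truth.
#' @param design One of `"joint_tite_crm"`, `"joint_crm"`,
#'   `"model_assisted"`, `"tite_b"`.
#' @param config A [rule_config()].
#' @param mcmc An [mcmc_control()].
#' @param cohort_size Patients per cohort.
#' @param seed Optional integer seed; fixes the whole patient stream and
#'   all design randomness, so two designs run on the same seed see
#'   identical latent outcomes.
#' @param prior Model prior: a [joint_prior()], [ma_prior()] or
#'   [titeb_config()] matching the design (defaults used when `NULL`).
#' @return An object of class `trial_result`: a list with
#'   `recommendation` (dose index or `NA`), `stop_reason`, `n_patients`,
#'   `duration_cycles`, `duration_weeks`, per-patient tibble `patients`,
#'   per-decision tibble `decisions`, and metadata.
#' @export
run_trial <- function(scenario, design = .designs, config = rule_config(),
                      mcmc = mcmc_control(), cohort_size = 3, seed = NULL,
                      prior = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(scenario, "dose_scenario"),
            inherits(config, "rule_config"))
  if (!is.null(seed)) set.seed(seed)
  tau <- attr(scenario, "tau")
  J <- nrow(scenario)
  values <- scenario$dose_mbq
  model <- outcome_model(scenario)
  z <- draw_latent_normals(config$n_max, attr(scenario, "event_time_corr"))
  step <- if (design == "joint_crm") tau else 1
  if (is.null(prior)) {
    prior <- switch(design, model_assisted = ma_prior(),
                    tite_b = titeb_config(), joint_prior())
  }

  patients <- tibble::tibble(id = integer(), dose_index = integer(),
                             entry = numeric(), t_tox = numeric(),
                             t_act = numeric())
  add_cohort <- function(pat, dose_index, entry) {
    n_new <- min(cohort_size, config$n_max - nrow(pat))
    if (n_new <= 0) return(pat)
    ids <- nrow(pat) + seq_len(n_new)
    times <- outcome_times(model, dose_index, z[ids, , drop = FALSE])
    dplyr::bind_rows(pat, tibble::tibble(
      id = ids, dose_index = dose_index, entry = entry,
      t_tox = times$t_tox, t_act = times$t_act))
  }
  patients <- add_cohort(patients, 1L, 0)

  stage <- "rule_escalation"
  lowest_excluded <- NA_integer_
  t <- 0
  decisions <- list()
  final_fit <- NULL
  final_scores <- NULL
  final_rstar <- NULL
  stop_reason <- "max_patients"

  repeat {
    t <- t + step
    obs <- observe_outcomes(patients[c("t_tox", "t_act")],
                            patients$entry, t, tau)
    if (stage == "rule_escalation" && any(obs$tox)) stage <- "model_based"

    followed <- patients$entry <= t - 1
    counts <- tibble::new_tibble(list(
      dose_index = seq_len(J),
      events = tabulate(patients$dose_index[followed &
                                              patients$t_tox <= 1], J),
      patients = tabulate(patients$dose_index[followed], J)), nrow = J)
    new_excl <- hard_safety_exclusion(counts, config)
    both <- c(lowest_excluded, new_excl)
    both <- both[!is.na(both)]
    lowest_excluded <- if (length(both)) min(both) else NA_integer_

    not_excluded <- if (is.na(lowest_excluded)) seq_len(J) else
      seq_len(J)[seq_len(J) < lowest_excluded]
    max_value <- max(values[patients$dose_index])
    allowed <- intersect(not_excluded,
                         which(k_fold_cap(values, max_value, config$fold)))

    fit <- NULL
    scores <- NULL
    admissible <- NULL
    cv <- NULL
    rstar <- NULL
    if (stage == "rule_escalation") {
      candidate <- min(max(patients$dose_index) + 1L, J)
      next_dose <- if (candidate %in% allowed) candidate else {
        ok <- allowed[allowed <= candidate]
        if (length(ok) == 0) NA_integer_ else max(ok)
      }
    } else {
      dat <- tibble::new_tibble(list(
        dose = values[patients$dose_index],
        dose_level = patients$dose_index,
        y_act = as.integer(obs$act), y_tox = as.integer(obs$tox),
        w_act = obs$w_act, w_tox = obs$w_tox
      ), nrow = nrow(patients))
      if (design %in% c("joint_tite_crm", "joint_crm")) {
        fit <- fit_joint(dat, values, prior = prior, chains = mcmc$chains,
                         iter = mcmc$iter, warmup = mcmc$warmup,
                         thin = mcmc$thin)
        cv <- cv_precision(fit, config)
      } else if (design == "model_assisted") {
        fit <- fit_ma(dat, values, prior = prior, chains = mcmc$chains,
                      iter = mcmc$iter, warmup = mcmc$warmup,
                      thin = mcmc$thin)
      } else {
        fit <- fit_titeb(dat, config = prior)
      }
      if (design == "tite_b") {
        admissible <- intersect(titeb_safe_set(fit), not_excluded)
        assignable <- intersect(admissible, allowed)
        if (length(assignable) > 0) {
          rstar <- titeb_randomization(fit, nrow(patients), config$n_max,
                                       allowed = assignable)
          next_dose <- sample(rstar$dose_index, 1, prob = rstar$r_star)
        } else {
          next_dose <- NA_integer_
        }
      } else {
        scores <- score_doses(fit, pi_tox_target = config$pi_tox_target,
                              pi_act_target = config$pi_act_target)
        admissible <- intersect(admissible_set(scores, config),
                                not_excluded)
        next_dose <- assign_next_dose(scores, admissible, allowed)
      }
    }

    decision <- check_stopping(
      n_patients = nrow(patients), cycle1_counts = counts,
      lowest_excluded = lowest_excluded, admissible = admissible,
      next_dose = next_dose,
      n_at_next = if (is.na(next_dose)) 0 else
        sum(patients$dose_index == next_dose),
      dosed_lowest = any(patients$dose_index == 1L),
      dosed_highest = any(patients$dose_index == J),
      n_followed = sum(followed), cv = cv, config = config
    )
    decisions[[length(decisions) + 1]] <- list(
      time = t, stage = stage, n_patients = nrow(patients),
      next_dose = as.integer(next_dose), stopped = decision$stopped,
      reason = decision$reason
    )
    final_fit <- fit
    final_scores <- scores
    final_rstar <- rstar
    if (decision$stopped) {
      stop_reason <- decision$reason
      break
    }
    if (is.na(next_dose)) {
      # assignable set empty without a triggered stop: treat as
      # no-admissible (all remaining doses blocked)
      stop_reason <- "no_admissible"
      break
    }
    patients <- add_cohort(patients, next_dose, t)
  }

  recommendation <- .final_recommendation(
    stop_reason, design, patients, t, tau, values, prior, mcmc, config,
    lowest_excluded, final_fit, final_scores, final_rstar)

  obs <- observe_outcomes(patients[c("t_tox", "t_act")],
                          patients$entry, t, tau)
  patients$tox <- obs$tox
  patients$act <- obs$act
  structure(list(
    recommendation = recommendation, stop_reason = stop_reason,
    n_patients = nrow(patients), duration_cycles = t,
    duration_weeks = 6 * t, patients = patients,
    decisions = dplyr::bind_rows(decisions), design = design,
    scenario_id = attr(scenario, "id"), seed = seed
  ), class = "trial_result")
}

# Terminal dose recommendation.  Stops for safety or futility recommend
# no dose; informative stops recommend from a model fitted to all data
# observed at the stop time.
.final_recommendation <- function(stop_reason, design, patients, t, tau,
                                  values, prior, mcmc, config,
                                  lowest_excluded, fit, scores, rstar) {
  if (stop_reason %in% c("hard_safety", "no_admissible", "lowest_unsafe",
                         "highest_very_safe")) {
    return(NA_integer_)
  }
  J <- length(values)
  not_excluded <- if (is.na(lowest_excluded)) seq_len(J) else
    seq_len(J)[seq_len(J) < lowest_excluded]
  if (is.null(fit)) {
    obs <- observe_outcomes(patients[c("t_tox", "t_act")],
                            patients$entry, t, tau)
    dat <- tibble::new_tibble(list(
      dose = values[patients$dose_index],
      dose_level = patients$dose_index,
      y_act = as.integer(obs$act), y_tox = as.integer(obs$tox),
      w_act = obs$w_act, w_tox = obs$w_tox
    ), nrow = nrow(patients))
    fit <- switch(design,
      model_assisted = fit_ma(dat, values, prior = prior,
                              chains = mcmc$chains, iter = mcmc$iter,
                              warmup = mcmc$warmup, thin = mcmc$thin),
      tite_b = fit_titeb(dat, config = prior),
      fit_joint(dat, values, prior = prior, chains = mcmc$chains,
                iter = mcmc$iter, warmup = mcmc$warmup,
                thin = mcmc$thin))
  }
  if (design == "tite_b") {
    safe <- intersect(titeb_safe_set(fit), not_excluded)
    if (length(safe) == 0) return(NA_integer_)
    if (is.null(rstar)) {
      rstar <- titeb_randomization(fit, nrow(patients), config$n_max,
                                   allowed = safe)
    }
    return(rstar$dose_index[which.max(rstar$r_star)])
  }
  if (is.null(scores)) {
    scores <- score_doses(fit, pi_tox_target = config$pi_tox_target,
                          pi_act_target = config$pi_act_target)
  }
  admissible <- intersect(admissible_set(scores, config), not_excluded)
  .best_utility_dose(scores, admissible)
}

#' @export
print.trial_result <- function(x, ...) {
  rec <- if (is.na(x$recommendation)) "none" else
    paste0("dose level ", x$recommendation)
  cat("Trial (", x$design, ", scenario ", x$scenario_id, "): ",
      x$n_patients, " patients, ", x$duration_cycles, " cycles; ",
      "recommendation: ", rec, " (stop: ", x$stop_reason, ")\n", sep = "")
  invisible(x)
}

#' Simulate operating characteristics of a design
#'
#' Runs `n_sims` independent trials (seeds `seed + 1:n_sims`, so
#' different designs run with the same `seed` see the same patient
#' streams) and aggregates them with [aggregate_results()].
#'
#' @inheritParams run_trial
#' @param n_sims Number of simulated trials.
#' @param seed Base integer seed.
#' @param keep_trials Keep the individual `trial_result` objects.
#' @return A list of class `trial_sims` with elements `oc` (one-row
#'   operating-characteristics tibble) and, optionally, `results`.
#' @export
simulate_trials <- function(scenario, design = .designs, n_sims = 100,
                            config = rule_config(), mcmc = mcmc_control(),
                            cohort_size = 3, seed = 1,
                            prior = NULL, keep_trials = TRUE) {
  design <- match.arg(design)
  results <- purrr::map(seq_len(n_sims), function(i) {
    run_trial(scenario, design, config = config, mcmc = mcmc,
              cohort_size = cohort_size, seed = seed + i, prior = prior)
  })
  oc <- aggregate_results(results, scenario, config = config, seed = seed)
  structure(list(oc = oc, results = if (keep_trials) results),
            class = "trial_sims")
}

#' @export
print.trial_sims <- function(x, ...) {
  print(x$oc)
  invisible(x)
}
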