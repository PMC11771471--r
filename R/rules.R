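#' Admissibility, enforcement and stopping rules
#'
#' Shared trial-conduct rules: the posterior admissibility constraints,
#' the hard-safety exclusion (a model-free Beta-Binomial monitor of
#' cycle-1 DLTs), the K-fold dose-skipping cap, and the seven stopping
#' rules.  In *relaxed* mode the exploratory stopping rules
#' (lowest-dose-unsafe, highest-dose-very-safe, sufficient information,
#' precision) are disabled so that the designs can be studied without
#' early stopping.
#'
#' @name rules
NULL

#' Rule configuration
#'
#' @param pi_tox_target Full-follow-up toxicity target (the MTD
#'   definition and the safety constraint threshold).
#' @param pi_act_target Lower bound on target full-follow-up activity.
#' @param q_tox,q_act Feasibility thresholds of the admissibility
#'   constraints `P(piT < pi_tox_target) > q_tox` and
#'   `P(piA > pi_act_target) > q_act`.
#' @param zeta Certainty threshold of the hard-safety exclusion.
#' @param cycle1_cap Cycle-1 DLT probability bound of the hard-safety
#'   rule and the safety-monitor stopping rules.
#' @param fold Maximum multiple of the highest experimented dose value
#'   allowed for the next assignment.
#' @param c_suff Sufficient-information patient count.
#' @param n_max Maximum number of patients.
#' @param cv_threshold Coefficient-of-variation threshold of the
#'   precision stopping rule.
#' @param safety_monitor_threshold Posterior probability threshold of
#'   the lowest-dose-unsafe / highest-dose-very-safe rules.
#' @param relaxed Disable stopping rules 2-5 (safety monitors,
#'   sufficient information, precision).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(pi_tox_target = 0.391, pi_act_target = 0.2,
                        q_tox = 0.1, q_act = 0.1, zeta = 0.95,
                        cycle1_cap = 0.3, fold = 2, c_suff = 30,
                        n_max = 60, cv_threshold = 0.30,
                        safety_monitor_threshold = 0.80,
                        relaxed = FALSE) {
  probs <- c(pi_tox_target, pi_act_target, q_tox, q_act, zeta,
             cycle1_cap, cv_threshold, safety_monitor_threshold)
  stopifnot(all(probs > 0 & probs < 1), fold > 1, c_suff >= 1, n_max >= 1)
  structure(list(pi_tox_target = pi_tox_target,
                 pi_act_target = pi_act_target,
                 q_tox = q_tox, q_act = q_act, zeta = zeta,
                 cycle1_cap = cycle1_cap, fold = fold, c_suff = c_suff,
                 n_max = n_max, cv_threshold = cv_threshold,
                 safety_monitor_threshold = safety_monitor_threshold,
                 relaxed = relaxed),
            class = "rule_config")
}

#' Posterior admissible dose set
#'
#' Doses satisfying both feasibility constraints
#' `P(piT < pi_tox_target) > q_tox` and `P(piA > pi_act_target) > q_act`.
#'
#' @param scores Per-dose posterior summaries from [score_doses()] (needs
#'   `prob_safe` and `prob_active`).
#' @param config A [rule_config()].
#' @return Integer dose indices (possibly empty).
#' @export
admissible_set <- function(scores, config = rule_config()) {
  which(scores$prob_safe > config$q_tox &
          scores$prob_active > config$q_act)
}

#' Posterior probability that a binomial rate exceeds a cap
#'
#' `P(p > cap)` under `p ~ Beta(1 + events, 1 + n - events)` (a uniform
#' prior updated with the observed cycle-1 DLT counts).
#'
#' @param events,n DLT count and patient count.
#' @param cap Probability bound.
#' @return Posterior exceedance probability.
#' @export
beta_exceed_prob <- function(events, n, cap = 0.3) {
  stopifnot(all(events >= 0), all(events <= n))
  1 - pbeta(cap, 1 + events, 1 + n - events)
}

#' Hard-safety exclusion from cycle-1 DLT counts
#'
#' A dose (and all doses above it) is permanently excluded when the
#' Beta(1,1)-posterior probability that its cycle-1 DLT rate exceeds
#' `cycle1_cap` is above `zeta`.  With the default `zeta = 0.95` and
#' cohorts of three this triggers at 3/3, 4/6 and 5/9 DLTs.
#'
#' @param counts Tibble with per-dose `events` and `patients` (cycle-1
#'   DLT counts, all doses in order).
#' @param config A [rule_config()].
#' @return The lowest excluded dose index, or `NA_integer_` if none.
#' @export
hard_safety_exclusion <- function(counts, config = rule_config()) {
  stopifnot(all(counts$events <= counts$patients))
  p <- beta_exceed_prob(counts$events, counts$patients, config$cycle1_cap)
  hit <- which(p > config$zeta)
  if (length(hit) == 0) NA_integer_ else min(hit)
}

#' K-fold dose-skipping cap
#'
#' @param candidate_value Proposed dose value.
#' @param highest_value Highest dose value experimented so far.
#' @param fold Maximum allowed multiple.
#' @return `TRUE` when `candidate_value <= fold * highest_value`.
#' @export
k_fold_cap <- function(candidate_value, highest_value, fold = 2) {
  stopifnot(all(candidate_value > 0), all(highest_value > 0))
  candidate_value <= fold * highest_value
}

#' Precision of the MTD and target-activity dose
#'
#' Per posterior draw, the MTD is the dose at which the toxicity curve
#' crosses the toxicity target, `(qlogis(target) - beta0) / beta1`, and
#' the target-activity dose is defined analogously from the activity
#' curve.  The coefficient of variation of each induced sample is the
#' scaled median absolute deviation (consistency constant 1.4826)
#' divided by the median; a non-positive median leaves the CV undefined
#' and the precision rule untriggered.
#'
#' @param fit A `joint_fit`.
#' @param config A [rule_config()].
#' @return Named vector `c(cv_mtd, cv_act_dose)` (possibly `NA`).
#' @export
cv_precision <- function(fit, config = rule_config()) {
  stopifnot(inherits(fit, "joint_fit"))
  cv <- function(x) {
    m <- median(x)
    if (!is.finite(m) || m <= 0) return(NA_real_)
    mad(x) / m
  }
  d <- fit$draws
  mtd <- (qlogis(config$pi_tox_target) - d$beta_tox0) / d$beta_tox1
  da <- (qlogis(config$pi_act_target) - d$beta_act0) / d$beta_act1
  c(cv_mtd = cv(mtd), cv_act_dose = cv(da))
}

.stop_reasons <- c("no_admissible", "lowest_unsafe", "highest_very_safe",
                   "sufficient_info", "precision", "hard_safety",
                   "max_patients", "none")

.stop_decision <- function(reason = "none") {
  reason <- match.arg(reason, .stop_reasons)
  list(stopped = reason != "none", reason = reason)
}

#' Evaluate the stopping rules
#'
#' Rules are evaluated in a fixed precedence order: hard safety (lowest
#' dose excluded), maximum patients, no admissible doses, lowest dose
#' deemed unsafe, highest dose deemed very safe, sufficient information
#' at the recommended dose, and precision.  Safety monitors use the same
#' Beta(1,1) cycle-1 machinery as the hard-safety rule.  In relaxed mode
#' only hard safety, no-admissible and maximum patients apply.
#'
#' @param n_patients Patients assigned so far.
#' @param cycle1_counts Per-dose tibble of cycle-1 `events` and
#'   `patients` among patients with at least one cycle of follow-up.
#' @param lowest_excluded Lowest hard-safety-excluded dose index or
#'   `NA`.
#' @param admissible Admissible dose indices after exclusions, or `NULL`
#'   while the trial is still in rule-based escalation (the constraint
#'   is model-based).
#' @param next_dose Dose index recommended for the next cohort (used by
#'   the sufficient-information rule), or `NA`.
#' @param n_at_next Patients already assigned to `next_dose`.
#' @param dosed_lowest,dosed_highest Whether at least one cohort has
#'   been assigned to the lowest / highest dose.
#' @param n_followed Patients with at least one cycle of follow-up.
#' @param cv Output of [cv_precision()], or `NULL` when the design has
#'   no invertible dose-response curve (model-assisted and TITE-B).
#' @param config A [rule_config()].
#' @return A list with `stopped` and `reason` (one of `no_admissible`,
#'   `lowest_unsafe`, `highest_very_safe`, `sufficient_info`,
#'   `precision`, `hard_safety`, `max_patients`, `none`).
#' @export
check_stopping <- function(n_patients, cycle1_counts, lowest_excluded,
                           admissible = NULL, next_dose = NA,
                           n_at_next = 0, dosed_lowest = TRUE,
                           dosed_highest = FALSE, n_followed = 0,
                           cv = NULL, config = rule_config()) {
  J <- nrow(cycle1_counts)
  thr <- config$safety_monitor_threshold
  if (!is.na(lowest_excluded) && lowest_excluded == 1L) {
    return(.stop_decision("hard_safety"))
  }
  if (n_patients >= config$n_max) {
    return(.stop_decision("max_patients"))
  }
  if (!is.null(admissible) && length(admissible) == 0) {
    return(.stop_decision("no_admissible"))
  }
  if (!config$relaxed) {
    c1 <- cycle1_counts[1, ]
    if (dosed_lowest && c1$patients > 0 &&
        beta_exceed_prob(c1$events, c1$patients, config$cycle1_cap) > thr) {
      return(.stop_decision("lowest_unsafe"))
    }
    cJ <- cycle1_counts[J, ]
    if (dosed_highest && cJ$patients > 0 &&
        1 - beta_exceed_prob(cJ$events, cJ$patients, config$cycle1_cap) > thr) {
      return(.stop_decision("highest_very_safe"))
    }
    if (!is.na(next_dose) && n_at_next >= config$c_suff) {
      return(.stop_decision("sufficient_info"))
    }
    if (!is.null(cv) && n_followed >= config$c_suff &&
        all(is.finite(cv)) && all(cv < config$cv_threshold)) {
      return(.stop_decision("precision"))
    }
  }
  .stop_decision("none")
}
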