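#' Operating-characteristics aggregation and display
#'
#' Summaries over repeated simulated trials: percentage of correct OBD
#' selections (or correct stops when the scenario has no OBD),
#' percentage of acceptable selections, mean sample size, mean duration
#' and mean number of patients assigned to truly unsafe doses, each with
#' Monte-Carlo standard errors where applicable.
#'
#' @name reporting
NULL

#' Aggregate simulated trials into an operating-characteristics record
#'
#' A *correct* outcome is selection of the true OBD or, in scenarios
#' without an OBD, a stop for one of the scenario's correct stop
#' reasons (safety/futility stops when no dose is acceptable; the
#' highest-dose-very-safe stop when every dose is safe).  An
#' *acceptable* outcome is selection of any truly safe and active dose,
#' or a correct stop in a no-OBD scenario.
#'
#' @param results List of `trial_result` objects from one
#'   scenario/design.
#' @param scenario The `dose_scenario` the trials were simulated from.
#' @param config The [rule_config()] used (targets feed the truth
#'   labels).
#' @param params Utility parameters for the truth labels.
#' @param seed Seed recorded in the output.
#' @return A one-row tibble of class `oc_record`.
#' @export
aggregate_results <- function(results, scenario, config = rule_config(),
                              params = utility_params(), seed = NA) {
  stopifnot(length(results) > 0)
  truth <- classify_doses(scenario, pi_tox_target = config$pi_tox_target,
                          pi_act_target = config$pi_act_target,
                          params = params)
  obd <- attr(truth, "obd")
  stop_ok <- attr(truth, "correct_stop_reasons")
  unsafe <- which(truth$tox_full > config$pi_tox_target)

  per <- purrr::map_dfr(results, function(r) {
    rec <- r$recommendation
    correct <- if (!is.na(obd)) {
      !is.na(rec) && rec == obd
    } else {
      is.na(rec) && r$stop_reason %in% stop_ok
    }
    acceptable <- (!is.na(rec) && truth$acceptable[rec]) ||
      (is.na(obd) && is.na(rec) && r$stop_reason %in% stop_ok)
    tibble::tibble(
      correct = correct, acceptable = acceptable, n = r$n_patients,
      duration = r$duration_cycles,
      unsafe_n = sum(r$patients$dose_index %in% unsafe)
    )
  })
  n_sims <- nrow(per)
  pct <- function(x) 100 * mean(x)
  se_pct <- function(x) 100 * sqrt(mean(x) * (1 - mean(x)) / n_sims)
  out <- tibble::tibble(
    scenario = attr(scenario, "id"),
    design = results[[1]]$design,
    activity_fraction = attr(scenario, "act_cycle1_fraction"),
    relaxed = config$relaxed,
    pct_correct = pct(per$correct), se_correct = se_pct(per$correct),
    pct_acceptable = pct(per$acceptable),
    se_acceptable = se_pct(per$acceptable),
    mean_n = mean(per$n), se_n = sd(per$n) / sqrt(n_sims),
    mean_duration_cycles = mean(per$duration),
    mean_duration_weeks = 6 * mean(per$duration),
    mean_unsafe_patients = mean(per$unsafe_n),
    n_sims = n_sims, seed = as.numeric(seed)
  )
  class(out) <- c("oc_record", class(out))
  out
}

#' Write or read operating-characteristics tables
#'
#' Plain-CSV round trip of [aggregate_results()] output (rows from
#' several scenarios/designs can be bound first).
#'
#' @param records An `oc_record` tibble (possibly many rows).
#' @param path CSV path.
#' @return `write_oc()` invisibly returns `path`; `read_oc()` returns
#'   the tibble.
#' @export
write_oc <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_oc
#' @export
read_oc <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("oc_record", class(out))
  out
}

#' Plot operating characteristics
#'
#' Grouped bar chart of one metric across scenarios and designs.
#'
#' @param object An `oc_record` tibble.
#' @param metric Column to plot (`"pct_correct"`, `"pct_acceptable"`,
#'   `"mean_n"`, `"mean_duration_weeks"` or
#'   `"mean_unsafe_patients"`).
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.oc_record <- function(object, metric = "pct_correct", ...) {
  stopifnot(metric %in% names(object))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$scenario, y = .data[[metric]],
                               fill = .data$design)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "Scenario", y = metric, fill = "Design") +
    ggplot2::theme_minimal()
}

#' @export
plot.oc_record <- function(x, ...) print(autoplot(x, ...))
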