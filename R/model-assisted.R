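#' Model-assisted dynamic-Beta design
#'
#' The model-assisted comparator replaces the dose-response curves with a
#' monotone dynamic Beta model: per-dose increments `b_j` in (0, 1) with
#' Beta priors induce non-decreasing outcome probabilities
#' `p_j = p_{j-1} + (1 - p_{j-1}) b_j` (with `p_1 = b_1`).  Each
#' endpoint has its own increment vector; the endpoints enter the
#' likelihood independently with the same TITE weights as the joint
#' model, and dose selection uses the same utility.
#'
#' @name model_assisted
NULL

#' Induced monotone probabilities from increments
#'
#' @param increments Vector in `[0, 1]`.
#' @return Non-decreasing probability vector of the same length.
#' @export
induced_probs <- function(increments) {
  stopifnot(all(increments >= 0 & increments <= 1))
  1 - cumprod(1 - increments)
}

#' Beta prior hyperparameters of the dynamic-Beta model
#'
#' Defaults are the published calibration for a six-dose grid.
#'
#' @param a_tox,b_tox,a_act,b_act Per-dose Beta shape vectors.
#' @return A list of class `ma_prior`.
#' @export
ma_prior <- function(a_tox = c(0.05, 0.1, 0.2, 0.25, 0.3, 0.35),
                     b_tox = c(0.95, 0.9, 0.8, 0.75, 0.7, 0.65),
                     a_act = c(0.2, 0.3, 0.4, 0.45, 0.5, 0.6),
                     b_act = c(0.95, 0.9, 0.8, 0.75, 0.7, 0.65)) {
  stopifnot(all(c(a_tox, b_tox, a_act, b_act) > 0),
            length(b_tox) == length(a_tox),
            length(a_act) == length(a_tox),
            length(b_act) == length(a_tox))
  structure(list(a_tox = a_tox, b_tox = b_tox,
                 a_act = a_act, b_act = b_act),
            class = "ma_prior")
}

#' Weighted log-likelihood of the dynamic-Beta model
#'
#' Independent weighted Bernoulli terms per endpoint with success
#' probability `w * p_{j[i]}` at the patient's dose level.
#'
#' @param data Tibble with columns `dose_level` (1-based), `y_act`,
#'   `y_tox`, `w_act`, `w_tox`.
#' @param b_tox,b_act Increment vectors in (0, 1).
#' @return Log-likelihood (0 for empty data).
#' @export
ma_log_lik <- function(data, b_tox, b_act) {
  stopifnot("dose_level" %in% names(data))
  .check_obs(data, need_dose = FALSE)
  if (nrow(data) == 0) return(0)
  cpp_ma_loglik(b_tox, b_act, as.integer(data$dose_level),
                as.integer(data$y_act), as.integer(data$y_tox),
                data$w_act, data$w_tox)
}

#' Fit the dynamic-Beta model by MCMC
#'
#' Adaptive random-walk Metropolis on a probit reparameterisation of the
#' 2J increments (each increment is the Beta-prior quantile of a
#' standard-normal probability), which keeps the sampler well scaled
#' under the strongly U-shaped Beta priors.
#'
#' @param data Observations (see [ma_log_lik()]); may have zero rows.
#' @param doses Dose values of the grid.
#' @param prior An [ma_prior()].
#' @inheritParams fit_joint
#' @return An object of class `ma_fit` with per-dose posterior
#'   probability draws for both endpoints.
#' @export
fit_ma <- function(data, doses, prior = ma_prior(), chains = 2,
                   iter = 1000, warmup = 1000, thin = 1, seed = NULL) {
  stopifnot(inherits(prior, "ma_prior"),
            length(doses) == length(prior$a_tox))
  .check_obs(data, need_dose = FALSE)
  if (!is.null(seed)) set.seed(seed)
  J <- length(doses)
  lev <- if (nrow(data) == 0) integer(0) else as.integer(data$dose_level)
  ya <- as.integer(data$y_act)
  yt <- as.integer(data$y_tox)
  raw <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    init <- rnorm(2 * J, 0, 0.5)
    res <- cpp_mcmc_ma(lev, ya, yt, data$w_act, data$w_tox,
                       prior$a_tox, prior$b_tox, prior$a_act, prior$b_act,
                       init, warmup, iter, thin)
    raw[[ch]] <- res$draws
    acc[ch] <- res$accept_rate
  }
  mat <- do.call(rbind, raw)
  rhat <- .split_rhat(mat, chains)
  u_tox <- pnorm(mat[, seq_len(J), drop = FALSE])
  u_act <- pnorm(mat[, J + seq_len(J), drop = FALSE])
  inc_tox <- vapply(seq_len(J), function(j)
    stats::qbeta(u_tox[, j], prior$a_tox[j], prior$b_tox[j]),
    numeric(nrow(mat)))
  inc_act <- vapply(seq_len(J), function(j)
    stats::qbeta(u_act[, j], prior$a_act[j], prior$b_act[j]),
    numeric(nrow(mat)))
  tox <- t(apply(inc_tox, 1, induced_probs))
  act <- t(apply(inc_act, 1, induced_probs))
  structure(list(tox = tox, act = act, accept_rate = mean(acc),
                 rhat = rhat,
                 converged = all(is.na(rhat) | rhat < 1.1),
                 chains = chains, doses = doses, prior = prior,
                 data = data, n_obs = nrow(data)),
            class = "ma_fit")
}

#' @rdname prob_draws
#' @export
prob_draws.ma_fit <- function(fit, ...) {
  list(tox = fit$tox, act = fit$act)
}

#' @export
tidy.ma_fit <- function(x, ...) {
  per_dose <- function(mat, endpoint) {
    tibble::tibble(
      term = paste0("p_", endpoint, "_", seq_len(ncol(mat))),
      estimate = colMeans(mat),
      std.error = apply(mat, 2, sd),
      conf.low = apply(mat, 2, quantile, 0.025),
      conf.high = apply(mat, 2, quantile, 0.975)
    )
  }
  dplyr::bind_rows(per_dose(x$tox, "tox"), per_dose(x$act, "act"))
}

#' @export
glance.ma_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_draws = nrow(x$tox),
                 chains = x$chains, accept_rate = x$accept_rate,
                 max_rhat = suppressWarnings(max(x$rhat, na.rm = TRUE)),
                 converged = x$converged)
}

#' @export
print.ma_fit <- function(x, ...) {
  cat("Dynamic-Beta model-assisted fit:", x$n_obs, "observations,",
      nrow(x$tox), "posterior draws\n")
  print(tidy(x))
  invisible(x)
}
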