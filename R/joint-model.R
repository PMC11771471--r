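#' Joint TITE-CRM model
#'
#' The proposed design models toxicity and activity with two-parameter
#' logistic dose-response curves, down-weights incomplete follow-up by
#' the completed fraction of follow-up (TITE weighting), and joins the
#' two weighted Bernoulli margins with a Gumbel association model whose
#' parameter `psi` captures the within-patient dependence of the two
#' outcomes.  The joint posterior of the five parameters is sampled by
#' adaptive random-walk Metropolis MCMC.
#'
#' @name joint_tite_crm
NULL

#' Two-parameter logistic dose-response probability
#'
#' `plogis(beta0 + beta1 * dose)`, evaluated overflow-safely.
#'
#' @param dose Dose value(s).
#' @param beta0,beta1 Intercept and slope.
#' @return Probabilities in (0, 1).
#' @export
logistic_prob <- function(dose, beta0, beta1) {
  plogis(beta0 + beta1 * dose)
}

#' Gumbel-joined cell probabilities for two Bernoulli margins
#'
#' Returns the four joint probabilities `p_ab` of (activity = a,
#' DLT = b) with margins `g_act`, `g_tox` and association
#' `(e^psi - 1)/(e^psi + 1)`.  `psi = 0` gives independence.  The
#' correction term can push a cell slightly negative for extreme inputs;
#' cells are floored at `floor_at` and renormalised before use in the
#' likelihood.
#'
#' @param g_act,g_tox Marginal (weighted) probabilities in `[0, 1]`.
#' @param psi Association parameter.
#' @param floor_at Lower floor applied to each cell (0 disables).
#' @return A tibble with columns `p00`, `p01`, `p10`, `p11` (activity
#'   index first) summing to 1 row-wise.
#' @export
gumbel_cell_probs <- function(g_act, g_tox, psi, floor_at = 1e-12) {
  stopifnot(all(g_act >= 0 & g_act <= 1), all(g_tox >= 0 & g_tox <= 1))
  g <- tanh(psi / 2)
  corr <- g_act * (1 - g_act) * g_tox * (1 - g_tox) * g
  cells <- tibble::tibble(
    p00 = (1 - g_act) * (1 - g_tox) + corr,
    p01 = (1 - g_act) * g_tox - corr,
    p10 = g_act * (1 - g_tox) - corr,
    p11 = g_act * g_tox + corr
  )
  if (floor_at > 0) {
    cells <- dplyr::mutate(cells, dplyr::across(
      dplyr::everything(), ~ pmax(.x, floor_at)))
    tot <- rowSums(cells)
    cells <- cells / tot
  }
  cells
}

#' Normal priors of the joint logistic model
#'
#' Independent normal priors on the intercept and the log slope of each
#' logistic curve, and a vague normal prior on the association `psi`.
#' Defaults: toxicity intercept `log(1/16)` (sd 1) and log slope
#' `log(1/4)` (variance 2), calibrated for this dose range; activity
#' intercept -3 and log slope -0.2 (sd 1 each), giving prior mean
#' activity above 0.3 at every dose, increasing with dose, with about
#' one patient per dose of prior information; `psi ~ N(0, 100)`.
#'
#' @param c1_tox,v1_tox Toxicity intercept prior mean and variance.
#' @param c2_tox,v2_tox Toxicity log-slope prior mean and variance.
#' @param c1_act,v1_act Activity intercept prior mean and variance.
#' @param c2_act,v2_act Activity log-slope prior mean and variance.
#' @param psi_var Prior variance of `psi` (mean 0).
#' @return A list of class `joint_prior` with `mean` and `var` vectors in
#'   the order (tox intercept, tox log slope, act intercept, act log
#'   slope, psi).
#' @export
joint_prior <- function(c1_tox = log(1 / 16), c2_tox = log(1 / 4),
                        v1_tox = 1, v2_tox = 2,
                        c1_act = -3, c2_act = -0.2,
                        v1_act = 1, v2_act = 1, psi_var = 100) {
  vars <- c(v1_tox, v2_tox, v1_act, v2_act, psi_var)
  stopifnot(all(vars > 0))
  structure(list(mean = c(c1_tox, c2_tox, c1_act, c2_act, 0), var = vars),
            class = "joint_prior")
}

.check_obs <- function(data, need_dose = TRUE) {
  cols <- c(if (need_dose) "dose", "y_act", "y_tox", "w_act", "w_tox")
  stopifnot(all(cols %in% names(data)))
  if (nrow(data) == 0) return(invisible(data))
  stopifnot(all(data$y_act %in% 0:1), all(data$y_tox %in% 0:1),
            all(data$w_act >= 0 & data$w_act <= 1),
            all(data$w_tox >= 0 & data$w_tox <= 1))
  if (any(data$y_tox == 1 & data$w_tox < 1) ||
      any(data$y_act == 1 & data$w_act < 1)) {
    stop("an observed event must carry weight 1", call. = FALSE)
  }
  invisible(data)
}

#' Weighted joint log-likelihood
#'
#' Product over patients of the Gumbel cell probability of the observed
#' (activity, toxicity) pair, at margins weighted by follow-up.
#'
#' @param data Tibble of observations with columns `dose`, `y_act`,
#'   `y_tox`, `w_act`, `w_tox`.
#' @param beta_tox,beta_act Length-2 vectors `(intercept, slope)`,
#'   slopes > 0.
#' @param psi Association parameter.
#' @return Log-likelihood (0 for empty data).
#' @export
joint_log_lik <- function(data, beta_tox, beta_act, psi) {
  .check_obs(data)
  stopifnot(all(is.finite(c(beta_tox, beta_act, psi))),
            beta_tox[2] > 0, beta_act[2] > 0)
  if (nrow(data) == 0) return(0)
  th <- c(beta_tox[1], log(beta_tox[2]), beta_act[1], log(beta_act[2]), psi)
  cpp_joint_loglik(th, data$dose, as.integer(data$y_act),
                   as.integer(data$y_tox), data$w_act, data$w_tox)
}

.split_rhat <- function(mat, chains) {
  # split-Rhat over chains split in half; mat is (chains * iter) x d
  d <- ncol(mat)
  iter <- nrow(mat) / chains
  half <- floor(iter / 2)
  if (half < 2) return(rep(NA_real_, d))
  vapply(seq_len(d), function(k) {
    x <- matrix(mat[, k], nrow = iter)
    splits <- cbind(x[seq_len(half), , drop = FALSE],
                    x[half + seq_len(half), , drop = FALSE])
    m <- ncol(splits)
    w <- mean(apply(splits, 2, var))
    b <- half * var(colMeans(splits))
    if (w == 0) return(NA_real_)
    sqrt(((half - 1) / half * w + b / half) / w)
  }, numeric(1))
}

#' Fit the joint TITE-CRM model by MCMC
#'
#' Adaptive random-walk Metropolis on (toxicity intercept, log toxicity
#' slope, activity intercept, log activity slope, psi); adaptation runs
#' during warmup only.  With no data the sampler draws from the prior.
#'
#' @param data Observations (see [joint_log_lik()]); may have zero rows.
#' @param doses Dose values of the grid (used when scoring).
#' @param prior A [joint_prior()].
#' @param chains,iter,warmup,thin MCMC settings: `iter` post-warmup draws
#'   per chain, kept every `thin` iterations.
#' @param seed Optional integer seed.
#' @return An object of class `joint_fit` with elements `draws` (tibble
#'   of natural-scale parameter draws), `accept_rate`, `rhat`,
#'   `converged`, `doses`, `prior`, `data`.
#' @export
fit_joint <- function(data, doses, prior = joint_prior(), chains = 2,
                      iter = 1000, warmup = 1000, thin = 1, seed = NULL) {
  .check_obs(data)
  stopifnot(inherits(prior, "joint_prior"), chains >= 1, iter >= 2)
  if (!is.null(seed)) set.seed(seed)
  d0 <- if (nrow(data) == 0) numeric(0) else data$dose
  ya <- as.integer(data$y_act)
  yt <- as.integer(data$y_tox)
  raw <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    init <- prior$mean + c(rnorm(4, 0, 0.3), rnorm(1, 0, 1))
    res <- cpp_mcmc_joint(d0, ya, yt, data$w_act, data$w_tox,
                          prior$mean, prior$var, init, warmup, iter, thin)
    raw[[ch]] <- res$draws
    acc[ch] <- res$accept_rate
  }
  mat <- do.call(rbind, raw)
  rhat <- .split_rhat(mat, chains)
  names(rhat) <- c("beta_tox0", "log_beta_tox1", "beta_act0",
                   "log_beta_act1", "psi")
  draws <- tibble::new_tibble(list(
    .chain = rep(seq_len(chains), each = iter),
    .iter = rep(seq_len(iter), chains),
    beta_tox0 = mat[, 1], beta_tox1 = exp(mat[, 2]),
    beta_act0 = mat[, 3], beta_act1 = exp(mat[, 4]),
    psi = mat[, 5]
  ), nrow = nrow(mat))
  structure(list(draws = draws, accept_rate = mean(acc), rhat = rhat,
                 converged = all(is.na(rhat) | rhat < 1.1),
                 doses = doses, prior = prior, data = data,
                 n_obs = nrow(data)),
            class = "joint_fit")
}

#' Per-dose posterior probability draws
#'
#' @param fit A fitted design model.
#' @param ... Passed to methods.
#' @return A list with matrices `tox` and `act` (draws x doses) of
#'   full-follow-up (weight 1) outcome probabilities.
#' @export
prob_draws <- function(fit, ...) UseMethod("prob_draws")

#' @rdname prob_draws
#' @export
prob_draws.joint_fit <- function(fit, ...) {
  d <- fit$draws
  tox <- vapply(fit$doses,
                function(x) logistic_prob(x, d$beta_tox0, d$beta_tox1),
                numeric(nrow(d)))
  act <- vapply(fit$doses,
                function(x) logistic_prob(x, d$beta_act0, d$beta_act1),
                numeric(nrow(d)))
  list(tox = tox, act = act)
}

.score_from_draws <- function(tox, act, doses, params, pi_tox_target,
                              pi_act_target) {
  u <- utility(act, tox, params)
  tibble::new_tibble(list(
    dose_index = seq_along(doses),
    dose = doses,
    pr_tox = colMeans(tox),
    pr_act = colMeans(act),
    prob_safe = colMeans(tox < pi_tox_target),
    prob_active = colMeans(act > pi_act_target),
    utility_mean = colMeans(u),
    utility_at_mean = utility(colMeans(act), colMeans(tox), params)
  ), nrow = length(doses))
}

#' Posterior dose scores: outcome probabilities, feasibility and utility
#'
#' For each dose: posterior mean full-follow-up toxicity and activity,
#' the feasibility probabilities `P(piT < target)` and `P(piA > target)`
#' used by the admissibility constraints, and the utility.  The headline
#' utility is the posterior mean of `U(piA, piT)` over draws, which
#' respects the nonlinearity of the penalty; the utility of the
#' posterior-mean probabilities is reported alongside.
#'
#' @param fit A `joint_fit` or `ma_fit`.
#' @param params Utility parameters.
#' @param pi_tox_target,pi_act_target Full-follow-up targets.
#' @param ... Unused.
#' @return A tibble with one row per dose.
#' @export
score_doses <- function(fit, params = utility_params(),
                        pi_tox_target = 0.391, pi_act_target = 0.2, ...) {
  p <- prob_draws(fit)
  .score_from_draws(p$tox, p$act, fit$doses, params,
                    pi_tox_target, pi_act_target)
}

#' @export
tidy.joint_fit <- function(x, ...) {
  pars <- c("beta_tox0", "beta_tox1", "beta_act0", "beta_act1", "psi")
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
}

#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_draws = nrow(x$draws),
                 chains = max(x$draws$.chain),
                 accept_rate = x$accept_rate,
                 max_rhat = suppressWarnings(max(x$rhat, na.rm = TRUE)),
                 converged = x$converged)
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("Joint TITE-CRM fit:", x$n_obs, "observations,",
      nrow(x$draws), "posterior draws",
      if (!x$converged) "(convergence flagged)" else "", "\n")
  print(tidy(x))
  invisible(x)
}
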