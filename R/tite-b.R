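#' TITE-B comparator design
#'
#' The TITE-B design fits independent one-parameter power models
#' `p^exp(theta)` to toxicity and activity, using the same TITE weights
#' as the joint model.  Toxicity uses a single skeleton; activity
#' averages over `L = 2J - 1` working-model skeletons with posterior
#' model probabilities `kappa_l` proportional to prior weight times
#' marginal likelihood.  Dose assignment randomises over the doses
#' recommended by the top candidate models within a safety-gated set;
#' the number of candidate models shrinks as the trial accrues.
#'
#' @name tite_b
NULL

#' Default activity working-model skeletons
#'
#' The 11 x 6 matrix of activity skeletons for a six-dose grid: rows
#' 1-6 peak at each dose in turn (plateau value 0.59), rows 7-11
#' are monotone profiles plateauing earlier and earlier.
#'
#' @return An 11 x 6 matrix.
#' @export
titeb_default_skeletons <- function() {
  rbind(
    c(0.59, 0.50, 0.40, 0.30, 0.20, 0.12),
    c(0.50, 0.59, 0.50, 0.40, 0.30, 0.20),
    c(0.40, 0.50, 0.59, 0.50, 0.40, 0.30),
    c(0.30, 0.40, 0.50, 0.59, 0.50, 0.40),
    c(0.20, 0.30, 0.40, 0.50, 0.59, 0.50),
    c(0.12, 0.20, 0.30, 0.40, 0.50, 0.59),
    c(0.20, 0.30, 0.40, 0.50, 0.59, 0.59),
    c(0.30, 0.40, 0.50, 0.59, 0.59, 0.59),
    c(0.40, 0.50, 0.59, 0.59, 0.59, 0.59),
    c(0.50, 0.59, 0.59, 0.59, 0.59, 0.59),
    c(0.59, 0.59, 0.59, 0.59, 0.59, 0.59)
  )
}

#' TITE-B configuration
#'
#' @param tox_skeleton Increasing prior guesses of per-dose DLT
#'   probability.
#' @param act_skeletons L x J matrix of activity skeletons (one working
#'   model per row); `L = 2J - 1` for the default construction.
#' @param model_weights Prior working-model weights `h(l)` (default
#'   equal, summing to 1).
#' @param delta Shrinkage exponent of the candidate-model count
#'   `L' = ceiling(((N - n)/N)^delta * L)`.
#' @param xi Maximum acceptable DLT rate over the full follow-up used to
#'   gate the safe dose set (the full-follow-up toxicity target).
#' @param prior_var Variance of the `N(0, prior_var)` prior on the power
#'   parameters `theta` and `beta_l`.
#' @return A list of class `titeb_config`.
#' @export
titeb_config <- function(tox_skeleton = c(0.02, 0.06, 0.12, 0.20, 0.30, 0.40),
                         act_skeletons = titeb_default_skeletons(),
                         model_weights = NULL, delta = 2, xi = 0.391,
                         prior_var = 1.34) {
  stopifnot(all(diff(tox_skeleton) > 0),
            all(tox_skeleton > 0 & tox_skeleton < 1),
            all(act_skeletons > 0 & act_skeletons < 1),
            ncol(act_skeletons) == length(tox_skeleton),
            delta > 0, xi > 0, xi < 1, prior_var > 0)
  L <- nrow(act_skeletons)
  if (is.null(model_weights)) model_weights <- rep(1 / L, L)
  stopifnot(length(model_weights) == L,
            abs(sum(model_weights) - 1) < 1e-8)
  structure(list(tox_skeleton = tox_skeleton,
                 act_skeletons = act_skeletons,
                 model_weights = model_weights, delta = delta, xi = xi,
                 prior_var = prior_var),
            class = "titeb_config")
}

#' One-parameter power-model probability
#'
#' @param skeleton_p Skeleton probability in (0, 1).
#' @param param Power parameter; the probability is
#'   `skeleton_p^exp(param)`.
#' @return Probability in (0, 1), increasing in `skeleton_p`.
#' @export
power_model_prob <- function(skeleton_p, param) {
  stopifnot(all(skeleton_p > 0 & skeleton_p < 1))
  skeleton_p^exp(param)
}

# Weighted power-model log-likelihood over a grid of parameter values.
# skel_obs: skeleton value at each patient's dose; returns one value per
# grid point.  The w^y factor is constant in the parameter and dropped.
.power_loglik_grid <- function(grid, skel_obs, y, w) {
  if (length(y) == 0) return(rep(0, length(grid)))
  e <- exp(grid)
  lp <- outer(e, log(skel_obs))         # grid x obs: log psi
  psi <- exp(lp)
  ll1 <- lp %*% y                       # sum_i y_i * log psi_i
  q <- 1 - sweep(psi, 2, w, `*`)
  q[q < 1e-300] <- 1e-300
  ll0 <- log(q) %*% (1 - y)
  as.numeric(ll1 + ll0)
}

# Deterministic trapezoid quadrature over the normal prior.
.power_grid <- function(prior_var, n_grid = 201, width = 8) {
  s <- sqrt(prior_var)
  grid <- seq(-width * s, width * s, length.out = n_grid)
  list(grid = grid, wq = dnorm(grid, 0, s) * (grid[2] - grid[1]))
}

#' Posterior per-dose toxicity estimates of the TITE-B power model
#'
#' Posterior mean of `p_j^exp(theta)` at each dose, computed by
#' one-dimensional quadrature of the weighted likelihood against the
#' normal prior.
#'
#' @param data Observations with columns `dose_level`, `y_tox`, `w_tox`
#'   (activity columns ignored).
#' @param config A [titeb_config()].
#' @return Vector of per-dose posterior DLT-rate estimates.
#' @export
titeb_tox_estimates <- function(data, config = titeb_config()) {
  stopifnot(inherits(config, "titeb_config"))
  p <- config$tox_skeleton
  skel_obs <- p[data$dose_level]
  gq <- .power_grid(config$prior_var)
  ll <- .power_loglik_grid(gq$grid, skel_obs, data$y_tox, data$w_tox)
  lik <- exp(ll - max(ll)) * gq$wq
  z <- sum(lik)
  if (!is.finite(z) || z <= 0) stop("toxicity integration failed")
  e <- exp(gq$grid)
  vapply(p, function(pj) sum(pj^e * lik) / z, numeric(1))
}

#' Activity working-model posterior probabilities and dose estimates
#'
#' For each working model l: the marginal likelihood of the weighted
#' activity data (quadrature over the normal prior on `beta_l`), the
#' posterior model probability `kappa_l`, and the per-dose posterior
#' mean activity under that model.
#'
#' @param data Observations with columns `dose_level`, `y_act`, `w_act`.
#' @param config A [titeb_config()].
#' @return A list with `kappa` (length L, sums to 1) and `act_means`
#'   (L x J matrix).
#' @export
titeb_activity_models <- function(data, config = titeb_config()) {
  stopifnot(inherits(config, "titeb_config"))
  Q <- config$act_skeletons
  L <- nrow(Q)
  J <- ncol(Q)
  gq <- .power_grid(config$prior_var)
  e <- exp(gq$grid)
  log_marg <- numeric(L)
  act_means <- matrix(NA_real_, L, J)
  for (l in seq_len(L)) {
    skel_obs <- Q[l, data$dose_level]
    ll <- .power_loglik_grid(gq$grid, skel_obs, data$y_act, data$w_act)
    m <- max(ll)
    lik <- exp(ll - m) * gq$wq
    z <- sum(lik)
    log_marg[l] <- m + log(z)
    for (j in seq_len(J)) act_means[l, j] <- sum(Q[l, j]^e * lik) / z
  }
  lk <- log(config$model_weights) + log_marg
  kappa <- exp(lk - max(lk))
  kappa <- kappa / sum(kappa)
  list(kappa = kappa, act_means = act_means)
}

#' Fit the TITE-B design
#'
#' @param data Observations with columns `dose_level`, `y_act`, `y_tox`,
#'   `w_act`, `w_tox`; may have zero rows.
#' @param config A [titeb_config()].
#' @return An object of class `titeb_fit` with `pi_tox_hat`, `kappa`,
#'   `act_means` and the config.
#' @export
fit_titeb <- function(data, config = titeb_config()) {
  if (nrow(data) > 0) .check_obs(data, need_dose = FALSE)
  pi_tox_hat <- titeb_tox_estimates(data, config)
  act <- titeb_activity_models(data, config)
  structure(list(pi_tox_hat = pi_tox_hat, kappa = act$kappa,
                 act_means = act$act_means, config = config,
                 doses = seq_along(config$tox_skeleton),
                 n_obs = nrow(data)),
            class = "titeb_fit")
}

#' Safety-gated dose set of the TITE-B design
#'
#' @param fit A `titeb_fit`.
#' @param xi Maximum acceptable full-follow-up DLT rate (defaults to the
#'   config value).
#' @return Indices of doses with estimated DLT rate strictly below `xi`
#'   (possibly empty).
#' @export
titeb_safe_set <- function(fit, xi = fit$config$xi) {
  which(fit$pi_tox_hat < xi)
}

# Per-model recommended dose within an allowed set: the allowed dose
# maximising posterior mean activity under that model, ties to the
# lower dose.
.titeb_model_doses <- function(fit, allowed) {
  vapply(seq_len(nrow(fit$act_means)), function(l) {
    v <- fit$act_means[l, allowed]
    allowed[which.max(v)]
  }, integer(1))
}

#' Adaptive randomisation probabilities of the TITE-B design
#'
#' Keeps the `L'` working models with the largest posterior
#' probabilities (ties at the cutoff admitted), where
#' `L' = ceiling(((N - n)/N)^delta * L)`, floored at 1 so a terminal
#' recommendation is always possible, and places mass on each candidate
#' model's recommended dose proportional to its `kappa`.
#'
#' @param fit A `titeb_fit`.
#' @param n Patients accrued so far.
#' @param N Maximum sample size.
#' @param allowed Dose indices eligible for assignment (safe,
#'   non-excluded, within the escalation cap).  Empty signals a
#'   no-admissible stop upstream.
#' @return A tibble with `dose_index` and `r_star` (sums to 1 over the
#'   support).
#' @export
titeb_randomization <- function(fit, n, N, allowed = titeb_safe_set(fit)) {
  stopifnot(n >= 0, n <= N, length(allowed) > 0)
  L <- length(fit$kappa)
  l_prime <- max(1L, as.integer(ceiling(((N - n) / N)^fit$config$delta * L)))
  cutoff <- sort(fit$kappa, decreasing = TRUE)[l_prime]
  candidates <- which(fit$kappa >= cutoff)
  s <- .titeb_model_doses(fit, allowed)
  r2 <- vapply(seq_along(fit$pi_tox_hat), function(j) {
    sum(fit$kappa[candidates][s[candidates] == j])
  }, numeric(1))
  tibble::tibble(dose_index = seq_along(r2), r_star = r2 / sum(r2))
}

#' Number of candidate working models at a given accrual
#'
#' @param n,N Current and maximum sample size.
#' @param delta Shrinkage exponent.
#' @param L Total number of working models.
#' @return `ceiling(((N - n)/N)^delta * L)`, floored at 1.
#' @export
titeb_n_candidates <- function(n, N, delta = 2, L = 11) {
  stopifnot(n >= 0, n <= N)
  max(1L, as.integer(ceiling(((N - n) / N)^delta * L)))
}

#' @export
tidy.titeb_fit <- function(x, ...) {
  tibble::tibble(dose_index = x$doses,
                 pi_tox_hat = x$pi_tox_hat,
                 skeleton = x$config$tox_skeleton)
}

#' @export
glance.titeb_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_models = length(x$kappa),
                 top_model = which.max(x$kappa),
                 top_kappa = max(x$kappa))
}

#' @export
print.titeb_fit <- function(x, ...) {
  cat("TITE-B fit:", x$n_obs, "observations;",
      "top working model", which.max(x$kappa), "\n")
  print(tidy(x))
  invisible(x)
}
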