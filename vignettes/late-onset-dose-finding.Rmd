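---
title: "Dose finding with late-onset toxicity and activity: models, rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose finding with late-onset toxicity and activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateobd)
```

## The problem

Seamless phase I/II trials aim at the optimal biological dose (OBD): a
dose that is both safe and sufficiently active. In multi-cycle
treatments such as targeted alpha therapy, both the dose-limiting
toxicity (DLT) and the activity response are binary events that can
occur in any of the $\tau$ follow-up cycles (here $\tau = 3$ cycles of
six weeks). Waiting for complete follow-up of each cohort before
dosing the next makes trials impractically long; ignoring pending
follow-up biases estimates. The joint TITE-CRM implemented here keeps
partially followed patients in the likelihood by down-weighting them,
and models both endpoints jointly.

## The joint model

Each endpoint has a two-parameter logistic dose-response curve,
$F(d, \beta) = \text{logit}^{-1}(\beta_0 + \beta_1 d)$, with the dose
$d$ entered as its actual value in MBq. A patient followed for $u$
completed cycles contributes with weight $w = u/\tau$; an observed
event carries weight 1, and an activity observation censored by an
earlier DLT at time $t_T$ carries $w^{(A)} = t_T/\tau$. The weighted
margins $G = wF$ are joined by a Gumbel model whose four cell
probabilities are the independence products plus a correction
$\pm G_A(1-G_A)G_T(1-G_T)\,\frac{e^\psi - 1}{e^\psi + 1}$, so
$\psi = 0$ recovers independence. The likelihood is the product over
patients of the cell probability of the observed outcome pair.

Doses are scored by the utility
$$U(\pi_A, \pi_T) = \pi_A - \omega_1 \pi_T -
  \omega_2 \pi_T\, \mathbb{1}(\pi_T > \phi_T),$$
with $\omega_1 = 0.33$, $\omega_2 = 1.09$ and
$\phi_T = \pi_T^* = 0.391$, the full-follow-up toxicity target
corresponding to a cycle-1 DLT probability of 0.3 when the conditional
per-cycle DLT probability decays by a factor 1/3. The indicator is
strict: a dose sitting exactly at the threshold is not penalised,
which is forced by the published truth tables (the boundary cells are
unpenalised there).

Priors follow the published calibration: toxicity intercept
$N(\log 1/16, 1)$ and log slope $N(\log 1/4, 2)$; activity intercept
$N(-3, 1)$ and log slope $N(-0.2, 1)$; $\psi \sim N(0, 100)$. Two
diagnostics of this choice reproduce on the raw-MBq dose scale: the
prior mean activity is 0.30–0.74, above 0.3 everywhere and increasing
with dose, and the average effective prior sample size is about one
patient per dose level. We therefore use raw MBq values as the dose
covariate (it also makes the 2-fold escalation cap well defined);
`fit_joint()` accepts any numeric dose vector should a standardised
scale be preferred.

### Utility aggregation

`score_doses()` reports both the posterior mean of $U(\pi_A, \pi_T)$
over draws (`utility_mean`, used for dose selection, since it
preserves the nonlinearity of the penalty: a dose whose toxicity
posterior straddles $\phi_T$ is partially penalised) and the utility
of the posterior means (`utility_at_mean`).

### MCMC

The five-parameter posterior (and the 12-increment posterior of the
model-assisted comparator) is sampled with an adaptive random-walk
Metropolis sampler written in C++: multivariate normal proposals whose
covariance adapts to the running empirical covariance (diminishing
adaptation, targeting 23.4% acceptance). These posteriors are
low-dimensional and well behaved, and this sampler is fast enough to
be refit at every decision of every simulated trial. Draws are
collected after warmup, optionally thinned; split-$\hat R$ and the
acceptance rate are exposed through `glance()`, and `converged` flags
$\hat R > 1.1$. Defaults are 2 chains of 1000 post-warmup draws;
simulation studies in the tests use 1 chain of 300–500 draws per fit,
which we found sufficient for dose ranking while keeping a full
operating-characteristics run in minutes. Heavy-tailed functionals of
the Beta increments (e.g. the prior mean of a Beta(0.05, 0.95)
increment) converge slowly under any MCMC; the tests use long thinned
chains for those checks.

The model-assisted increments are sampled on a probit scale through
the Beta-prior quantile function, so their strongly U-shaped priors
become a standard normal target.

## Comparator designs

* **Joint CRM**: the same joint model with every decision delayed
  until the previous cohort completes all $\tau$ cycles, so all
  weights equal 1. It is run by `run_trial(..., design = "joint_crm")`
  with a decision (and a new cohort) every $\tau$ cycles.
* **Model-assisted** (`"model_assisted"`): monotone dynamic-Beta model
  $p_j = p_{j-1} + (1-p_{j-1})b_j$ per endpoint with the published
  Beta priors; same TITE weights, same utility.
* **TITE-B** (`"tite_b"`): independent one-parameter power models
  $p^{e^\theta}$ with a toxicity skeleton (0.02, 0.06, 0.12, 0.20,
  0.30, 0.40) and $L = 2J-1 = 11$ activity skeletons; $N(0, 1.34)$
  priors integrated by deterministic quadrature (trapezoid over ±8
  prior SDs, 201 nodes — the tests verify agreement with Monte-Carlo
  integration to $10^{-3}$). Assignment randomises over the doses
  recommended by the top $L' = \lceil ((N-n)/N)^2 L \rceil$ models
  ($L'$ floored at 1 so a terminal recommendation always exists; ties
  at the $\kappa$ cutoff admit both models), within a safety-gated set
  $\hat\pi_T(d) < \xi$. We set $\xi = \pi_T^* = 0.391$, the maximum
  acceptable full-follow-up DLT rate. The terminal recommendation is
  the dose with the largest randomisation probability.

## Rules

Admissibility requires $P(\pi_T < \pi_T^*) > q_T$ and
$P(\pi_A > \pi_A^*) > q_A$ with $\pi_A^* = 0.2$. The thresholds
$q_T = q_A = 0.1$ are a package default: they are the conventional
feasibility bounds in this literature and are exposed in
`rule_config()` as an explicit assumption.

Enforcement: a hard-safety rule excludes a dose (and all above,
permanently) when the Beta(1,1)-posterior probability that its cycle-1
DLT rate exceeds 0.3 is above $\zeta = 0.95$ — equivalently at 3/3,
4/6 or 5/9 cycle-1 DLTs — and the next assignment may be at most a
2-fold increase over the highest experimented dose *value*.

Stopping evaluates, in a fixed precedence order (the published rules
are unordered; reason strings are stable API): hard safety at the
lowest dose; maximum patients ($n_{\max} = 60$); no admissible doses;
lowest dose deemed unsafe ($P(p_{1,d_1} > 0.3) > 0.8$); highest dose
deemed very safe ($P(p_{1,d_J} \le 0.3) > 0.8$); sufficient
information ($C_{\text{suff}} = 30$ patients already on the
recommended dose, counting patients *assigned*); precision
(CV(MTD) and CV$(d[\pi_A^*])$ both below 30%, CV computed as
1.4826·MAD/median of the per-draw curve inversions, once 30 patients
have a cycle of follow-up). The safety monitors use the same
model-free Beta(1,1) machinery as the hard-safety rule, for
consistency and model independence. The precision rule needs an
invertible dose-response curve and therefore applies only to the two
joint-logistic designs — not to the model-assisted design (as
published) and not to TITE-B, whose power models are defined per dose
level. `rule_config(relaxed = TRUE)` disables the four exploratory
rules for the "theoretical" setting.

## Synthetic outcomes

`outcome_model()` matches, per dose, a lognormal event-time
distribution to the cycle-1 and full-follow-up probabilities of each
endpoint (closed form from two normal quantiles), and patients' log
event times are bivariate normal with correlation $-1/2$ (early
activity weakly associated with later toxicity). Activity in cycle 1
is one third of the total activity probability by default;
`act_cycle1_fraction` of 1/6 or 1/2 gives the alternative time
trends. The activity marginal is a proper lognormal with no cure
fraction: "inactive" doses simply have small $P(t_A \le \tau)$ and
events beyond $\tau$ are never observed. Each simulated patient keeps
one latent standard-normal pair, so designs run on the same seed see
identical latent outcomes regardless of their dosing decisions.

What this generator does *not* emulate: dropout other than DLT,
accrual-rate variation (one cohort of three per decision cycle is
fixed), within-patient cycle effects, and any parametric dose-response
structure in the truth. Passing tests therefore speak to the designs'
behaviour under these stylised conditions, not to real-trial
performance.

## Numerical choices and degenerate inputs

Gumbel cells are floored at $10^{-12}$ and renormalised before the
log-likelihood, because the association correction can push a cell
slightly negative for extreme margins; this keeps the sampler stable
without materially changing inference. Lognormal matching requires
$0 < p_{\text{cycle1}} < p_{\text{full}} < 1$ and errors otherwise
(the degenerate equal-probability case has no solution). Ties in dose
selection resolve to the lower dose everywhere. A DLT observed
mid-cycle is acted on at the next scheduled decision (cycle
boundaries), consistent with the cohort cadence. When the 2-fold cap
blocks every admissible dose, the best assignable dose is used so the
experimented range can expand. Stops for safety or futility (hard
safety, no admissible doses, lowest unsafe, highest very safe) return
no dose; informative stops recommend the admissible dose maximising
posterior mean utility at the stop time.

## Known limitations

A monotone logistic cannot represent a plateau in activity. In
scenarios whose activity flattens while toxicity is still below
target (e.g. a plateau from the third dose upward), the fitted
activity curve keeps increasing and the fitted toxicity curve
under-extrapolates risk beyond the data, so the utility argmax tends
to sit one level above the truly optimal dose when the true utility
gap between neighbouring doses is small (about 0.02 in the hardest
scenario here). The effect is scenario-specific — selection is
markedly better when the truth is monotone in dose — and is shared by
any design built on these curves; the admissibility constraints and
the toxicity penalty bound, but do not remove, it.

## Problem sizes used in the tests

The test suite fits the joint model at up to $n = 200$ complete
observations for parameter recovery, checks the generator with
$2\times 10^5$ Monte-Carlo draws, and runs comparative operating
characteristics at 200 simulated trials per design/configuration with
single-chain fits of 300 draws; these sizes give Monte-Carlo errors
comfortably inside the asserted tolerances while a full run of the
suite completes in minutes.
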