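# Model and sampler configuration, parameter states, and the joint density.
#
# The model: for birth i in ethnic group j (1..7) and nativity class k (0 =
# US-born, 1 = foreign-born),
#   Y_ijk ~ Bernoulli(p_ijk)
#   logit p_ijk = delta_jk + sum_g alpha_gjk q_g(edu, centred) + sum_m beta_m x_m
# with hierarchical shrinkage within nativity class,
#   delta_jk   ~ N(mu_0k, 1/tau_0)
#   alpha_gjk  ~ N(mu_gk, 1/tau_g),  g = 1..3
#   mu_gk      ~ N(0, 1)
#   tau_g      ~ Gamma(shape 0.1, rate 0.1)
#   beta_m     ~ N(0, 10).
# Ethnic groups borrow strength within a nativity class through mu_gk; the
# precision tau_g, estimated from the data, sets how much is borrowed. By
# default each tau_g is shared across the two nativity classes (four
# precision terms in total); a per-nativity variant is available.

#' Specify the hierarchical PTB model
#'
#' @param knots spline knots (years of education).
#' @param mu_var prior variance of the hierarchical means `mu_gk`.
#' @param tau_shape,tau_rate gamma shape/rate of the precision priors.
#' @param beta_var prior variance of the covariate coefficients.
#' @param tau_structure `"shared"` (one `tau_g` per coefficient type, shared
#'   across nativity classes) or `"per_nativity"` (`tau_gk`).
#' @param adjustment `"age"` (maternal-age categories only) or `"full"`.
#' @param fixed_tau optional fixed value(s) for the precisions; when
#'   supplied, the tau-update is skipped and the precisions stay at this
#'   value (useful to study shrinkage as a function of tau). Either a single
#'   number or a vector/matrix shaped like the tau state.
#' @return an object of class `ptb_model_spec`.
#' @export
model_spec <- function(knots = default_knots, mu_var = 1,
                       tau_shape = 0.1, tau_rate = 0.1, beta_var = 10,
                       tau_structure = c("shared", "per_nativity"),
                       adjustment = c("age", "full"), fixed_tau = NULL) {
  stopifnot(mu_var > 0, tau_shape > 0, tau_rate > 0, beta_var > 0)
  structure(list(knots = check_knots(knots), mu_var = mu_var,
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 beta_var = beta_var,
                 tau_structure = match.arg(tau_structure),
                 adjustment = match.arg(adjustment),
                 fixed_tau = fixed_tau),
            class = "ptb_model_spec")
}

#' Configure the MCMC run
#'
#' Defaults are desk-scale (4 chains of 6,000 iterations, 1,000 burn-in,
#' thin 5); production-scale settings in the spirit of the original analysis
#' (one million iterations, 10,000 burn-in, thin 10) are available by
#' argument.
#'
#' @param chains number of chains (>= 1).
#' @param iterations total iterations per chain.
#' @param burnin discarded initial iterations (`iterations > burnin`).
#' @param thin retain every `thin`-th post-burn-in iteration.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param init_dispersion scale of the random dispersion of each chain's
#'   starting state.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 6000, burnin = 1000,
                        thin = 5, seed = 1, init_dispersion = 1) {
  stopifnot(chains >= 1, burnin >= 0, iterations > burnin, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 init_dispersion = init_dispersion),
            class = "mcmc_config")
}

n_groups <- 7L

tau_matrix <- function(tau, spec) {
  # tau as a 4 x 2 matrix (column per nativity class) whatever the structure
  if (spec$tau_structure == "shared") matrix(tau, 4, 2) else tau
}

#' Create a parameter state
#'
#' @param delta 7 x 2 matrix of group intercepts (log-odds).
#' @param alpha 3 x 7 x 2 array of spline coefficients.
#' @param mu 4 x 2 matrix of hierarchical means (row g = 0 for intercepts,
#'   1..3 for spline terms; column per nativity class).
#' @param tau precisions: length-4 vector (shared structure) or 4 x 2 matrix
#'   (per-nativity).
#' @param beta named covariate coefficients.
#' @return an object of class `ptb_state`.
#' @export
parameter_state <- function(delta, alpha, mu, tau, beta) {
  stopifnot(all(dim(delta) == c(7, 2)), all(dim(alpha) == c(3, 7, 2)),
            all(dim(mu) == c(4, 2)), all(tau > 0))
  structure(list(delta = delta, alpha = alpha, mu = mu, tau = tau,
                 beta = beta), class = "ptb_state")
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Bernoulli log-likelihood of a parameter state
#'
#' Sum over records of the Bernoulli log-probability with
#' `logit p = delta_jk + alpha_jk . q(centred) + beta . x`.
#'
#' @param state a `ptb_state`.
#' @param frame a model frame from [recode_cohort()].
#' @param basis a centred `spline_basis` evaluated at the frame's education
#'   values (built automatically from the state's dimensions if omitted).
#' @param adjustment which design columns enter (`"age"` or `"full"`);
#'   `beta` must have one value per column.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, frame, basis = NULL,
                           adjustment = c("full", "age")) {
  adjustment <- match.arg(adjustment)
  if (is.null(basis))
    basis <- center_basis(build_basis(frame$education))
  if (!all(dim(basis$Q) == c(nrow(frame), 3L)))
    stop("basis dimensions do not match the frame", call. = FALSE)
  cols <- design_columns(adjustment)
  if (length(state$beta) != length(cols))
    stop("beta length does not match the design", call. = FALSE)
  X <- as.matrix(frame[cols])
  jk <- cbind(frame$j, frame$k + 1L)
  eta <- state$delta[jk] +
    rowSums(basis$Q * t(matrix(state$alpha, 3, 14)[, frame$j + 7L * frame$k])) +
    drop(X %*% unname(state$beta))
  sum(frame$preterm * eta - log1pexp(eta))
}

#' Log prior density of a parameter state
#'
#' Normal priors on the hierarchical means and covariate coefficients, gamma
#' priors on the precisions, and the hierarchical normal layers for the
#' intercepts and spline coefficients. Non-positive precisions return
#' `-Inf`.
#'
#' @param state a `ptb_state`.
#' @param spec a `ptb_model_spec`.
#' @return scalar log prior density.
#' @export
log_prior <- function(state, spec) {
  if (any(state$tau <= 0)) return(-Inf)
  tm <- tau_matrix(state$tau, spec)
  lp <- sum(dnorm(state$mu, 0, sqrt(spec$mu_var), log = TRUE)) +
    sum(dgamma(unique_tau(state$tau, spec), spec$tau_shape,
               rate = spec$tau_rate, log = TRUE)) +
    sum(dnorm(state$beta, 0, sqrt(spec$beta_var), log = TRUE))
  for (k in 1:2) {
    lp <- lp + sum(dnorm(state$delta[, k], state$mu[1, k],
                         1 / sqrt(tm[1, k]), log = TRUE))
    for (g in 1:3)
      lp <- lp + sum(dnorm(state$alpha[g, , k], state$mu[g + 1, k],
                           1 / sqrt(tm[g + 1, k]), log = TRUE))
  }
  lp
}

unique_tau <- function(tau, spec) {
  if (spec$tau_structure == "shared") as.numeric(tau)[1:4] else as.numeric(tau)
}

#' One conjugate update of the hierarchical means and precisions
#'
#' Draws `mu_gk` from its normal-normal full conditional given the current
#' group coefficients and precisions, then each precision from its
#' gamma-normal full conditional (skipped when the spec fixes tau). All other
#' state components are untouched. Uses R's RNG.
#'
#' @param state a `ptb_state`.
#' @param spec a `ptb_model_spec`.
#' @return the updated `ptb_state`.
#' @export
gibbs_update_hyper <- function(state, spec) {
  coef_gk <- function(g, k) {
    if (g == 0) state$delta[, k] else state$alpha[g, , k]
  }
  tm <- tau_matrix(state$tau, spec)
  for (g in 0:3) {
    for (k in 1:2) {
      v <- coef_gk(g, k)
      prec <- 1 / spec$mu_var + length(v) * tm[g + 1, k]
      mean <- tm[g + 1, k] * sum(v) / prec
      state$mu[g + 1, k] <- rnorm(1, mean, 1 / sqrt(prec))
    }
  }
  if (is.null(spec$fixed_tau)) {
    if (spec$tau_structure == "shared") {
      tau <- numeric(4)
      for (g in 0:3) {
        dev2 <- sum(vapply(1:2, function(k)
          sum((coef_gk(g, k) - state$mu[g + 1, k])^2), numeric(1)))
        n_shrunk <- 2L * n_groups
        tau[g + 1] <- rgamma(1, spec$tau_shape + n_shrunk / 2,
                             rate = spec$tau_rate + dev2 / 2)
      }
      state$tau <- tau
    } else {
      for (g in 0:3) for (k in 1:2) {
        dev2 <- sum((coef_gk(g, k) - state$mu[g + 1, k])^2)
        state$tau[g + 1, k] <- rgamma(1, spec$tau_shape + n_groups / 2,
                                      rate = spec$tau_rate + dev2 / 2)
      }
    }
  }
  state
}

#' Polya-Gamma random variates
#'
#' Draws from the Polya-Gamma distribution PG(shape, z): exact Devroye
#' sampling for integer shapes up to 30, a moment-matched normal
#' approximation above. Vectorised; uses R's RNG.
#'
#' @param shape non-negative integer shape(s).
#' @param z tilting parameter(s), recycled against `shape`.
#' @return numeric vector of draws.
#' @export
rpg <- function(shape, z) {
  n <- max(length(shape), length(z))
  .rpg_cpp(as.integer(rep_len(shape, n)), as.numeric(rep_len(z, n)))
}
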