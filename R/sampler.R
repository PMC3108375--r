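# Posterior sampling by Polya-Gamma Gibbs.
#
# The Bernoulli likelihood is collapsed to binomial counts over unique
# design cells (stratum x education x covariate pattern), which leaves the
# posterior unchanged while letting one PG draw stand in for a whole cell:
# the sum of n iid PG(1, z) variables is PG(n, z). Given the PG variates,
# every coefficient block ((delta, alpha) per stratum, then beta) has a
# Gaussian full conditional, and the hierarchical means and precisions have
# normal/gamma conjugate updates, so the whole sampler is Gibbs with no
# tuning.

collapse_frame <- function(frame, cols) {
  dt <- data.table::as.data.table(frame[c("preterm", "j", "k", "education", cols)])
  cells <- dt[, list(y = sum(preterm), n = .N),
              by = c("j", "k", "education", cols)]
  as.data.frame(cells)
}

flatten_pars <- function(state, spec, beta_names) {
  eth <- abbreviate(hispanic_subgroups, 6)
  nat <- c("US", "FB")
  nm <- c(sprintf("delta[%s,%s]", rep(eth, 2), rep(nat, each = 7)),
          sprintf("alpha%d[%s,%s]", rep(1:3, 14),
                  rep(rep(eth, each = 3), 2), rep(nat, each = 21)),
          sprintf("mu%d[%s]", rep(0:3, 2), rep(nat, each = 4)),
          if (spec$tau_structure == "shared") sprintf("tau%d", 0:3)
          else sprintf("tau%d[%s]", rep(0:3, 2), rep(nat, each = 4)),
          sprintf("beta[%s]", beta_names))
  nm
}

state_to_vector <- function(state) {
  c(as.numeric(state$delta), as.numeric(state$alpha),
    as.numeric(state$mu), as.numeric(state$tau), as.numeric(state$beta))
}

#' Sample the posterior of the hierarchical PTB model
#'
#' Runs the Polya-Gamma Gibbs sampler: each iteration draws the PG
#' augmentation variables given the current linear predictor, then the
#' (intercept, spline) block of every stratum, the covariate coefficients,
#' and finally the hierarchical means and precisions from their conjugate
#' full conditionals. Chains start from dispersed random states and are
#' seeded as `config$seed + chain - 1`, so identical inputs give identical
#' draws.
#'
#' @param frame a model frame from [recode_cohort()]; every (j, k) stratum
#'   must be non-empty.
#' @param basis optional centred `spline_basis` for the frame's education
#'   values; built (and centred on the frame) if omitted.
#' @param spec a `ptb_model_spec`.
#' @param config an `mcmc_config`.
#' @param prior_only if `TRUE` the likelihood is switched off (zero-weight
#'   data) and the sampler targets the prior; used for prior-recovery
#'   checks.
#' @return an object of class `ptb_draws`: retained thinned draws as a
#'   3-d array `[kept iteration, chain, parameter]`, plus the spec, config,
#'   centring offsets, and iteration metadata.
#' @export
sample_posterior <- function(frame, basis = NULL, spec = model_spec(),
                             config = mcmc_config(), prior_only = FALSE) {
  cols <- design_columns(spec$adjustment)
  stopifnot_cols(frame, c("preterm", "j", "k", "education", cols), "model frame")
  present <- table(factor(frame$j, 1:7), factor(frame$k, 0:1))
  if (!prior_only && any(present == 0))
    stop("every (ethnicity, nativity) cell must be non-empty for fitting",
         call. = FALSE)
  if (is.null(basis)) basis <- center_basis(build_basis(frame$education),
                                            frame$education)
  cells <- collapse_frame(frame, cols)
  Qc <- sweep(rq_terms(cells$education, basis$knots), 2, basis$offsets)
  X <- as.matrix(cells[cols])
  kappa <- cells$y - cells$n / 2
  sidx <- cells$j + 7L * cells$k          # stratum id 1..14
  idx_list <- split(seq_len(nrow(cells)), factor(sidx, levels = 1:14))
  A_list <- lapply(idx_list, function(ii) cbind(1, Qc[ii, , drop = FALSE]))
  p <- length(cols)
  n_keep <- (config$iterations - config$burnin) %/% config$thin
  npar <- 14 + 42 + 8 + (if (spec$tau_structure == "shared") 4 else 8) + p
  pnames <- flatten_pars(list(), spec, cols)
  draws <- array(NA_real_, c(n_keep, config$chains, npar),
                 dimnames = list(NULL, paste0("chain", seq_len(config$chains)),
                                 pnames))
  overall <- if (prior_only) 0 else qlogis(max(min(mean(frame$preterm), 0.99), 0.01))
  for (ch in seq_len(config$chains)) {
    with_seed(config$seed + ch - 1L, {
      disp <- config$init_dispersion
      state <- parameter_state(
        delta = matrix(overall + rnorm(14, 0, 0.5 * disp), 7, 2),
        alpha = array(rnorm(42, 0, 0.05 * disp), c(3, 7, 2)),
        mu = matrix(rnorm(8, 0, 0.2 * disp), 4, 2),
        tau = if (spec$tau_structure == "shared")
          exp(rnorm(4, 0, 0.3 * disp)) else matrix(exp(rnorm(8, 0, 0.3 * disp)), 4, 2),
        beta = setNames(rnorm(p, 0, 0.1 * disp), cols))
      if (!is.null(spec$fixed_tau))
        state$tau <- if (spec$tau_structure == "shared")
          rep_len(as.numeric(spec$fixed_tau), 4) else
            matrix(rep_len(as.numeric(spec$fixed_tau), 8), 4, 2)
      kept <- 0L
      for (it in seq_len(config$iterations)) {
        theta_mat <- rbind(as.numeric(state$delta), matrix(state$alpha, 3, 14))
        eta_str <- numeric(nrow(cells))
        for (s in 1:14) {
          ii <- idx_list[[s]]
          if (length(ii)) eta_str[ii] <- drop(A_list[[s]] %*% theta_mat[, s])
        }
        xb <- drop(X %*% unname(state$beta))
        if (prior_only) {
          omega <- numeric(nrow(cells))
          kap <- numeric(nrow(cells))
        } else {
          omega <- .rpg_cpp(as.integer(cells$n), eta_str + xb)
          kap <- kappa
        }
        tm <- tau_matrix(state$tau, spec)
        for (s in 1:14) {
          ii <- idx_list[[s]]
          k <- (s - 1L) %/% 7L + 1L
          tau_eff <- tm[, k]
          m0 <- state$mu[, k]
          if (length(ii)) {
            A <- A_list[[s]]
            w <- omega[ii]
            P <- crossprod(A, w * A) + diag(tau_eff)
            b <- crossprod(A, kap[ii] - w * xb[ii]) + tau_eff * m0
          } else {
            P <- diag(tau_eff)
            b <- tau_eff * m0
          }
          U <- chol(P)
          mean_s <- backsolve(U, forwardsolve(t(U), b))
          theta <- drop(mean_s + backsolve(U, rnorm(4)))
          j <- (s - 1L) %% 7L + 1L
          state$delta[j, k] <- theta[1]
          state$alpha[, j, k] <- theta[-1]
          if (length(ii)) eta_str[ii] <- drop(A_list[[s]] %*% theta)
        }
        if (prior_only) {
          state$beta <- setNames(rnorm(p, 0, sqrt(spec$beta_var)), cols)
        } else {
          P <- crossprod(X, omega * X) + diag(1 / spec$beta_var, p)
          b <- crossprod(X, kap - omega * eta_str)
          U <- chol(P)
          mean_b <- backsolve(U, forwardsolve(t(U), b))
          state$beta <- setNames(drop(mean_b + backsolve(U, rnorm(p))), cols)
        }
        state <- gibbs_update_hyper(state, spec)
        if (!all(is.finite(state_to_vector(state))))
          stop(sprintf("sampler produced a non-finite state at iteration %d (chain %d)",
                       it, ch), call. = FALSE)
        if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
          kept <- kept + 1L
          draws[kept, ch, ] <- state_to_vector(state)
        }
      }
    })
  }
  structure(list(draws = draws, pars = pnames, spec = spec, config = config,
                 knots = basis$knots, offsets = basis$offsets,
                 design_cols = cols,
                 iterations_kept = n_keep,
                 ethnicities = hispanic_subgroups,
                 nativities = nativity_classes),
            class = "ptb_draws")
}

#' @export
print.ptb_draws <- function(x, ...) {
  cat(sprintf("ptb_draws: %d kept draws x %d chains x %d parameters\n",
              dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3]))
  cat(sprintf("  adjustment: %s; tau structure: %s; knots: %s\n",
              x$spec$adjustment, x$spec$tau_structure,
              paste(x$knots, collapse = ", ")))
  invisible(x)
}

# Draws for one named parameter, pooled across chains.
par_draws <- function(draws, par) {
  i <- match(par, draws$pars)
  if (is.na(i)) stop(sprintf("unknown parameter '%s'", par), call. = FALSE)
  as.numeric(draws$draws[, , i])
}

# Matrix of pooled draws for a set of parameters.
par_matrix <- function(draws, pars) {
  i <- match(pars, draws$pars)
  if (anyNA(i)) stop("unknown parameter name(s)", call. = FALSE)
  m <- draws$draws[, , i, drop = FALSE]
  dim(m) <- c(dim(draws$draws)[1] * dim(draws$draws)[2], length(i))
  colnames(m) <- pars
  m
}

#' Export retained draws as a long table
#'
#' @param draws a `ptb_draws` object.
#' @param path optional CSV path; when given, the table is written (with a
#'   sidecar JSON metadata file recording the spec and config) and the path
#'   returned invisibly.
#' @return data.frame with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
draws_long <- function(draws, path = NULL) {
  d <- draws$draws
  out <- data.frame(
    chain = rep(seq_len(dim(d)[2]), each = dim(d)[1], times = dim(d)[3]),
    iteration = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    parameter = rep(draws$pars, each = dim(d)[1] * dim(d)[2]),
    value = as.numeric(d))
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    meta <- list(spec = unclass(draws$spec), config = unclass(draws$config),
                 knots = draws$knots, offsets = draws$offsets,
                 design_cols = draws$design_cols)
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                      "_meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  out
}
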