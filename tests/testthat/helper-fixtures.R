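# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

eth_all <- ptbhier:::hispanic_subgroups
nat_all <- ptbhier:::nativity_classes
cond_all <- ptbhier:::condition_names

# One fully eligible registry row with overridable fields.
registry_row <- function(...) {
  row <- list(ethnicity = "Mexican", nativity = "US-born", education = 12L,
              mother_age = 25L, plurality = 1L, parity = 2L,
              kessner = "adequate", infant_sex = "female", tobacco = 0L,
              alcohol = 0L, preterm = 0L, birthweight_missing = 0L)
  for (cn in cond_all) row[[cn]] <- 0L
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

registry_fixture <- function(rows) do.call(rbind, rows)

# Minimal complete cohort covering all 14 strata (one record each, plus
# extras for a designated stratum).
all_strata_cohort <- function(extra = NULL) {
  rows <- list()
  for (e in eth_all) for (n in nat_all)
    rows[[length(rows) + 1L]] <- registry_row(ethnicity = e, nativity = n)
  base <- registry_fixture(rows)
  if (!is.null(extra)) base <- rbind(base, extra)
  base
}

# Random registry with injected missingness, for ledger property tests.
random_registry <- function(n, seed) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) registry_row(
      ethnicity = sample(c(eth_all, "Non-Hispanic"), 1),
      nativity = sample(nat_all, 1),
      education = sample(0:17, 1),
      mother_age = sample(16:44, 1),
      plurality = sample(c(1L, 1L, 1L, 2L), 1),
      kessner = sample(ptbhier:::kessner_levels, 1),
      preterm = rbinom(1, 1, 0.08)))
    reg <- registry_fixture(rows)
    for (col in c("education", "nativity", "ethnicity", "kessner", "parity"))
      reg[[col]][runif(n) < 0.08] <- NA
    reg$birthweight_missing <- as.integer(runif(n) < 0.02)
    reg
  })
}

# Toy model frame: all covariate indicators zero unless supplied.
toy_frame <- function(j, k, education, preterm,
                      design = NULL) {
  n <- length(preterm)
  fr <- data.frame(preterm = preterm, j = j, k = k, education = education)
  cols <- ptbhier::design_columns("full")
  for (cc in cols) fr[[cc]] <- 0L
  if (!is.null(design)) for (cc in names(design)) fr[[cc]] <- design[[cc]]
  fr
}

# Frame holding at least one record in every stratum.
full_strata_frame <- function(n_per = 2, seed = 1, p = 0.3) {
  withr::with_seed(seed, {
    grid <- expand.grid(j = 1:7, k = 0:1)
    parts <- lapply(seq_len(nrow(grid)), function(r)
      toy_frame(grid$j[r], grid$k[r],
                education = sample(0:17, n_per, replace = TRUE),
                preterm = rbinom(n_per, 1, p)))
    do.call(rbind, parts)
  })
}

random_state <- function(seed, tau_structure = "shared", p = 12) {
  withr::with_seed(seed, parameter_state(
    delta = matrix(rnorm(14, -2, 1), 7, 2),
    alpha = array(rnorm(42, 0, 0.2), c(3, 7, 2)),
    mu = matrix(rnorm(8, 0, 0.5), 4, 2),
    tau = if (tau_structure == "shared") rgamma(4, 2, 1)
          else matrix(rgamma(8, 2, 1), 4, 2),
    beta = setNames(rnorm(p, 0, 0.5), ptbhier::design_columns("full")[1:p])))
}

# --- Independent brute-force oracle for the joint log density -------------
# Deliberately written with scalar loops and dbinom/dnorm/dgamma so it shares
# no code path with the package implementation.
oracle_log_likelihood <- function(state, frame, Q, beta_cols) {
  ll <- 0
  for (i in seq_len(nrow(frame))) {
    j <- frame$j[i]; k <- frame$k[i] + 1L
    eta <- state$delta[j, k]
    for (g in 1:3) eta <- eta + state$alpha[g, j, k] * Q[i, g]
    for (m in seq_along(beta_cols))
      eta <- eta + state$beta[m] * frame[[beta_cols[m]]][i]
    ll <- ll + dbinom(frame$preterm[i], 1, 1 / (1 + exp(-eta)), log = TRUE)
  }
  ll
}

oracle_log_prior <- function(state, spec) {
  tm <- if (spec$tau_structure == "shared")
    cbind(as.numeric(state$tau), as.numeric(state$tau)) else state$tau
  taus <- if (spec$tau_structure == "shared") as.numeric(state$tau)[1:4]
          else as.numeric(state$tau)
  lp <- 0
  for (v in as.numeric(state$mu))
    lp <- lp + dnorm(v, 0, sqrt(spec$mu_var), log = TRUE)
  for (t in taus)
    lp <- lp + dgamma(t, spec$tau_shape, rate = spec$tau_rate, log = TRUE)
  for (b in as.numeric(state$beta))
    lp <- lp + dnorm(b, 0, sqrt(spec$beta_var), log = TRUE)
  for (k in 1:2) {
    for (j in 1:7) {
      lp <- lp + dnorm(state$delta[j, k], state$mu[1, k],
                       1 / sqrt(tm[1, k]), log = TRUE)
      for (g in 1:3)
        lp <- lp + dnorm(state$alpha[g, j, k], state$mu[g + 1, k],
                         1 / sqrt(tm[g + 1, k]), log = TRUE)
    }
  }
  lp
}

# Minimal hand-built draws object for summary-level tests.
fake_draws <- function(delta_draws, alpha_draws = NULL, beta_draws = NULL,
                       nchain = 1, offsets = c(0, 0, 0),
                       adjustment = "full") {
  nd <- nrow(delta_draws)
  cols <- ptbhier::design_columns(adjustment)
  p <- length(cols)
  if (is.null(alpha_draws)) alpha_draws <- matrix(0, nd, 42)
  if (is.null(beta_draws)) beta_draws <- matrix(0, nd, p)
  mu_draws <- matrix(0, nd, 8); tau_draws <- matrix(1, nd, 4)
  flat <- cbind(delta_draws, alpha_draws, mu_draws, tau_draws, beta_draws)
  spec <- model_spec(adjustment = adjustment)
  pnames <- ptbhier:::flatten_pars(list(), spec, cols)
  stopifnot(ncol(flat) == length(pnames))
  keep <- nd %/% nchain
  arr <- array(NA_real_, c(keep, nchain, length(pnames)),
               dimnames = list(NULL, paste0("chain", seq_len(nchain)), pnames))
  for (ch in seq_len(nchain))
    arr[, ch, ] <- flat[((ch - 1) * keep + 1):(ch * keep), ]
  structure(list(draws = arr, pars = pnames, spec = spec,
                 config = mcmc_config(chains = nchain, iterations = keep,
                                      burnin = 0, thin = 1),
                 knots = ptbhier:::default_knots, offsets = offsets,
                 design_cols = cols, iterations_kept = keep,
                 ethnicities = eth_all, nativities = nat_all),
            class = "ptb_draws")
}
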