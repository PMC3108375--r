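# Posterior sampler: determinism, prior recovery, parameter recovery on a
# single dominant stratum, shrinkage behaviour, and nativity separation.

quick_config <- function(seed = 7, chains = 2, iterations = 900,
                         burnin = 200, thin = 2)
  mcmc_config(chains = chains, iterations = iterations, burnin = burnin,
              thin = thin, seed = seed)

test_that("identical inputs give identical retained draws", {
  fr <- full_strata_frame(n_per = 40, seed = 3, p = 0.15)
  cfg <- quick_config(iterations = 300, burnin = 50)
  d1 <- sample_posterior(fr, spec = model_spec(), config = cfg)
  d2 <- sample_posterior(fr, spec = model_spec(), config = cfg)
  expect_identical(d1$draws, d2$draws)
  expect_equal(d1$iterations_kept, (300 - 50) %/% 2)
})

test_that("sampler insists on non-empty strata", {
  fr <- full_strata_frame(n_per = 5)
  fr <- fr[!(fr$j == 3 & fr$k == 1), ]
  expect_error(sample_posterior(fr, config = quick_config()), "non-empty")
})

test_that("with the likelihood disabled the sampler recovers the prior", {
  fr <- full_strata_frame(n_per = 2)
  cfg <- mcmc_config(chains = 2, iterations = 3200, burnin = 200, thin = 2,
                     seed = 11)
  dr <- sample_posterior(fr, spec = model_spec(adjustment = "age"),
                         config = cfg, prior_only = TRUE)
  dg <- diagnostics(dr, grep("^mu", dr$pars, value = TRUE))
  for (r in seq_len(nrow(dg))) {
    mcse <- dg$sd[r] / sqrt(dg$ess[r])
    expect_lt(abs(dg$mean[r] - 0), 3.5 * mcse)          # prior mean 0
    expect_lt(abs(dg$sd[r]^2 - 1), 3.5 * sqrt(2 / dg$ess[r]))  # prior var 1
  }
  bg <- diagnostics(dr, grep("^beta", dr$pars, value = TRUE))
  expect_lt(max(abs(bg$mean)), 4 * max(bg$sd / sqrt(bg$ess)))
  expect_equal(mean(bg$sd^2), 10, tolerance = 0.15)
})

test_that("a flat-risk cohort recovers the generating reference risk", {
  # dominant stratum of 20,000 records at risk 0.10, flat in education,
  # no covariate effects
  p <- make_table1_preset(scale = 0.0)
  p$strata$size <- rep(150L, 14)
  p$strata$size[3] <- 20000L  # US-born Puerto Rican stratum carries the mass
  p$strata[c("a1", "a2", "a3")] <- 0
  p$strata$intercept <- qlogis(0.10)
  p$beta[] <- 0
  p$contamination[] <- 0
  reg <- generate_registry(p, seed = 13)
  fr <- recode_cohort(apply_exclusions(reg, "age")$cohort)
  dr <- sample_posterior(fr, spec = model_spec(adjustment = "age"),
                         config = quick_config(seed = 17, iterations = 1200,
                                               burnin = 300))
  surf <- risk_surface(dr, keep_draws = TRUE)
  arr <- attr(surf, "risk_draws")
  est <- mean(arr[, 2, 1, 13])   # Puerto Rican, US-born, education 12
  psd <- sd(arr[, 2, 1, 13])
  tol <- 3 * sqrt(psd^2 + 0.1 * 0.9 / 20000)
  expect_lt(abs(est - 0.10), tol)
})

test_that("larger fixed precision shrinks coefficients toward the group mean", {
  fr <- full_strata_frame(n_per = 60, seed = 19, p = 0.2)
  gaps <- sapply(c(0.5, 50, 5000), function(tau_fix) {
    dr <- sample_posterior(fr,
                           spec = model_spec(adjustment = "age",
                                             fixed_tau = tau_fix),
                           config = quick_config(seed = 23, chains = 1,
                                                 iterations = 700,
                                                 burnin = 200))
    a1 <- colMeans(ptbhier:::par_matrix(dr, grep("^alpha1",
                                                 dr$pars, value = TRUE)))
    m1 <- colMeans(ptbhier:::par_matrix(dr, grep("^mu1", dr$pars,
                                                 value = TRUE)))
    mean(abs(a1 - rep(m1, each = 7)))
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("permuting foreign-born data leaves native-born posteriors unchanged", {
  p <- make_table1_preset(scale = 0.02)
  p$contamination[] <- 0
  reg <- generate_registry(p, seed = 29)
  fr <- recode_cohort(apply_exclusions(reg, "age")$cohort)
  fr2 <- fr
  fb <- which(fr2$k == 1)
  set.seed(31)
  fr2$j[fb] <- sample(fr2$j[fb])   # reshuffle ethnicity among foreign-born
  spec <- model_spec(adjustment = "age", tau_structure = "per_nativity")
  cfg <- quick_config(seed = 37, iterations = 1600, burnin = 300)
  d1 <- sample_posterior(fr, spec = spec, config = cfg)
  d2 <- sample_posterior(fr2, spec = spec, config = cfg)
  native_pars <- grep("US\\]$", grep("^(delta|alpha)", d1$pars, value = TRUE),
                      value = TRUE)
  g1 <- diagnostics(d1, native_pars)
  g2 <- diagnostics(d2, native_pars)
  mcse <- sqrt(g1$sd^2 / g1$ess + g2$sd^2 / g2$ess)
  expect_true(mean(abs(g1$mean - g2$mean) <= 4 * mcse) >= 0.9)
  # while foreign-born posteriors genuinely moved
  fb_pars <- grep("FB\\]$", grep("^delta", d1$pars, value = TRUE), value = TRUE)
  f1 <- diagnostics(d1, fb_pars); f2 <- diagnostics(d2, fb_pars)
  expect_gt(max(abs(f1$mean - f2$mean)), 0.05)
})
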