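# Posterior summaries: risk surfaces, risk differences, adjustment
# comparison, and the draw-wise aggregation discipline.

test_that("degenerate identical draws give point-mass risk 0.5", {
  dr <- fake_draws(matrix(0, 50, 14))
  surf <- risk_surface(dr)
  expect_true(all(surf$mean == 0.5))
  expect_true(all(surf$upper95 - surf$lower95 == 0))
})

test_that("single-draw closed form: risk = expit(delta) everywhere", {
  dr <- fake_draws(matrix(-2.5, 2, 14))
  surf <- risk_surface(dr)
  expect_equal(unique(surf$mean), plogis(-2.5), tolerance = 1e-12)
  expect_equal(unique(surf$median), plogis(-2.5), tolerance = 1e-12)
})

test_that("native-born entries below 8 years are flagged, not dropped", {
  dr <- fake_draws(matrix(-2, 10, 14))
  surf <- risk_surface(dr)
  us <- surf[surf$nativity == "US-born", ]
  expect_true(all(us$below_floor[us$education < 8]))
  expect_false(any(us$below_floor[us$education >= 8]))
  expect_false(any(surf$below_floor[surf$nativity == "Foreign-born"]))
  expect_equal(nrow(surf), 7 * 2 * 18)
})

test_that("risk differences are computed draw-wise with exact linearity", {
  # native risk 0.09, foreign 0.07 for every draw
  delta <- cbind(matrix(qlogis(0.09), 40, 7), matrix(qlogis(0.07), 40, 7))
  dr <- fake_draws(delta)
  rd <- risk_difference_surface(risk_surface(dr))
  expect_equal(unique(round(rd$mean, 12)), 0.02)
  expect_true(all(rd$upper95 - rd$lower95 < 1e-12))
  expect_equal(sort(unique(rd$education)), 8:17)

  # identical nativities: RD exactly zero
  dr0 <- fake_draws(cbind(matrix(-2, 10, 7), matrix(-2, 10, 7)))
  rd0 <- risk_difference_surface(risk_surface(dr0))
  expect_true(all(rd0$mean == 0))

  # posterior mean of RD equals difference of posterior means (linearity)
  set.seed(8)
  drr <- fake_draws(matrix(rnorm(100 * 14, -2, 0.7), 100, 14))
  surf <- risk_surface(drr)
  rdr <- risk_difference_surface(surf)
  arr <- attr(surf, "risk_draws")
  for (j in c(1, 4)) for (x in c(8, 17)) {
    want <- mean(arr[, j, 1, x + 1]) - mean(arr[, j, 2, x + 1])
    got <- rdr$mean[rdr$ethnicity == eth_all[j] & rdr$education == x]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("summaries are draw-wise: nonlinearity is preserved", {
  set.seed(9)
  delta <- matrix(rnorm(4000 * 14, -2, 1.5), 4000, 14)
  dr <- fake_draws(delta)
  surf <- risk_surface(dr)
  m_drawwise <- surf$mean[1]
  m_aggfirst <- plogis(mean(delta[, 1]))
  expect_equal(m_drawwise, mean(plogis(delta[, 1])), tolerance = 1e-10)
  expect_gt(abs(m_drawwise - m_aggfirst), 0.02)
})

test_that("surfaces without stored draws refuse to form differences", {
  dr <- fake_draws(matrix(-2, 5, 14))
  surf <- risk_surface(dr, keep_draws = FALSE)
  expect_error(risk_difference_surface(surf), "keep_draws")
})

test_that("adjustment comparison pairs grids and reports differences", {
  dr <- fake_draws(matrix(-2, 20, 14))
  rd <- risk_difference_surface(risk_surface(dr))
  cmp <- compare_adjustments(rd, rd)
  expect_true(all(cmp$difference == 0))
  expect_equal(nrow(cmp), 7 * 10)
  rd_short <- risk_difference_surface(risk_surface(dr), grid = 9:17)
  expect_error(compare_adjustments(rd, rd_short), "grids")
})

test_that("reference pattern controls the covariate design row", {
  pat <- reference_pattern()
  expect_true(all(attr(pat, "design") == 0))
  pat2 <- reference_pattern(age = "40+", tobacco = 1L)
  d <- attr(pat2, "design")
  expect_equal(unname(d["age40p"]), 1)
  expect_equal(unname(d["tobacco"]), 1)
  expect_equal(sum(d), 2)
  # a nonzero pattern moves the fitted risk by exactly beta . x
  nd <- 30
  beta <- matrix(0, nd, 12); beta[, 4] <- 0.45  # age40p column
  dr <- fake_draws(matrix(-2, nd, 14), beta_draws = beta)
  s_ref <- risk_surface(dr)
  s_40 <- risk_surface(dr, pattern = reference_pattern(age = "40+"))
  expect_equal(unique(round(s_40$mean, 10)),
               round(plogis(-2 + 0.45), 10))
  expect_equal(unique(round(s_ref$mean, 10)), round(plogis(-2), 10))
})

test_that("95% intervals cover the generating risk at close to nominal rate", {
  p <- make_table1_preset(scale = 0.04)
  p$contamination[] <- 0
  hits <- 0; reps <- 40
  for (r in seq_len(reps)) {
    reg <- generate_registry(p, seed = 1000 + r)
    fr <- recode_cohort(apply_exclusions(reg, "age")$cohort)
    dr <- sample_posterior(fr, spec = model_spec(adjustment = "age"),
                           config = mcmc_config(chains = 1, iterations = 500,
                                                burnin = 150, thin = 2,
                                                seed = r))
    surf <- risk_surface(dr)
    tr <- true_age_adjusted_risk(p, "Puerto Rican", "US-born", 12)
    row <- surf[surf$ethnicity == "Puerto Rican" &
                  surf$nativity == "US-born" & surf$education == 12, ]
    if (row$lower95 <= tr && tr <= row$upper95) hits <- hits + 1
  }
  # binomial band around nominal 95% for 40 replicates
  expect_gte(hits, qbinom(0.001, reps, 0.95))
})
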