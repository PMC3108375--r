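# Synthetic registry: preset calibration, generation, determinism, and the
# ground-truth risk oracle.

test_that("calibrated preset reproduces the published stratum structure", {
  p <- table1_preset()
  st <- p$strata
  expect_equal(st$size[st$ethnicity == "Mexican" &
                         st$nativity == "Foreign-born"], 38416L)
  expect_equal(st$edu_mean[st$ethnicity == "Puerto Rican" &
                             st$nativity == "US-born"], 12.3)
  expect_equal(sum(st$size), 259596L)
  expect_equal(sum(st$size[st$nativity == "US-born"]), 82427L)
  expect_equal(sum(st$size[st$nativity == "Foreign-born"]), 177169L)
})

test_that("education distributions hit the published moments after discretisation", {
  p <- table1_preset()
  for (i in seq_len(nrow(p$strata))) {
    m <- sum(0:17 * p$edu_probs[i, ])
    s <- sqrt(sum((0:17 - m)^2 * p$edu_probs[i, ]))
    expect_equal(m, p$strata$edu_mean[i], tolerance = 1e-4)
    expect_equal(s, p$strata$edu_sd[i], tolerance = 1e-3)
    expect_equal(sum(p$edu_probs[i, ]), 1, tolerance = 1e-9)
  }
})

test_that("intercept calibration matches the marginal PTB targets exactly", {
  p <- table1_preset()
  for (i in c(1, 2, 4, 8, 14)) {
    got <- marginal_true_risk(p, p$strata$ethnicity[i], p$strata$nativity[i])
    expect_equal(got, p$strata$ptb_target[i], tolerance = 1e-7)
  }
})

test_that("generation is deterministic given (params, seed) and leaves the RNG alone", {
  p <- make_table1_preset(scale = 0.003)
  set.seed(99); before <- rnorm(1)
  r1 <- generate_registry(p, seed = 5)
  r2 <- generate_registry(p, seed = 5)
  expect_identical(r1, r2)
  r3 <- generate_registry(p, seed = 6)
  expect_false(identical(r1, r3))
  set.seed(99)
  expect_identical(before, rnorm(1))
})

test_that("record count equals configured sizes plus contamination", {
  p <- make_table1_preset(scale = 0.003)
  reg <- generate_registry(p, seed = 2)
  n_cont <- sum(round(p$contamination * sum(p$strata$size)))
  expect_equal(nrow(reg), sum(p$strata$size) + n_cont)
  expect_true(all(reg$education[!is.na(reg$education)] %in% 0:17))
  expect_true(all(reg$preterm %in% 0:1))
})

test_that("degenerate intercepts force all outcomes to zero", {
  p <- make_table1_preset(scale = 0.002)
  p$strata$intercept <- -50
  reg <- generate_registry(p, seed = 3)
  expect_true(all(reg$preterm == 0))
})

test_that("missingness injection conserves rows and only touches its fields", {
  p <- make_table1_preset(scale = 0.005,
                          missingness = c(education = 0.2, kessner = 0.3),
                          contamination = c(non_hispanic = 0, under20 = 0,
                                            plural = 0))
  reg <- generate_registry(p, seed = 8)
  expect_equal(nrow(reg), sum(p$strata$size))
  expect_gt(sum(is.na(reg$education)), 0)
  expect_gt(sum(is.na(reg$kessner)), 0)
  expect_false(anyNA(reg$nativity))
  expect_false(anyNA(reg$preterm))
  frac <- mean(is.na(reg$education))
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / nrow(reg)))
})

test_that("true_risk matches hand arithmetic and its trivial limits", {
  p <- table1_preset()
  # flat dose-response: identical risk across the education range
  p0 <- p
  p0$strata[p0$strata$ethnicity == "Cuban", c("a1", "a2", "a3")] <- 0
  r <- true_risk(p0, "Cuban", "US-born", c(0, 17))
  expect_equal(r[1], r[2])
  # expit(0) at a neutral stratum
  p0$strata$intercept[p0$strata$ethnicity == "Cuban" &
                        p0$strata$nativity == "US-born"] <- 0
  p0$beta[] <- 0
  expect_equal(true_risk(p0, "Cuban", "US-born", 9), 0.5)
  # arbitrary stratum: hand-computed linear predictor
  st <- p$strata[p$strata$ethnicity == "Dominican" &
                   p$strata$nativity == "Foreign-born", ]
  x <- 15
  q <- c(x, (x - 8)^2 - (x - 13)^2, (x - 11)^2 - (x - 13)^2)
  eta <- st$intercept + sum(c(st$a1, st$a2, st$a3) * q)
  expect_equal(true_risk(p, "Dominican", "Foreign-born", x),
               1 / (1 + exp(-eta)), tolerance = 1e-12)
  expect_error(true_risk(p, "Martian", "US-born", 10), "no stratum")
  expect_error(true_risk(p, "Cuban", "US-born", 19), "0..17")
})

test_that("full-scale generation reproduces the published marginals within sampling error", {
  p <- table1_preset()
  reg <- full_registry()
  st <- p$strata
  for (i in c(2, 3, 8, 12)) {  # large strata across the table
    d <- reg[reg$ethnicity %in% st$ethnicity[i] &
               reg$nativity %in% st$nativity[i], ]
    d <- d[d$mother_age >= 20 & d$plurality == 1, ]
    phat <- mean(d$preterm)
    se <- sqrt(st$ptb_target[i] * (1 - st$ptb_target[i]) / nrow(d))
    expect_lt(abs(phat - st$ptb_target[i]), 4 * se)
  }
  # foreign-born Mexican mean education close to the published 8.7
  d <- reg[reg$ethnicity %in% "Mexican" & reg$nativity %in% "Foreign-born" &
             reg$mother_age >= 20 & reg$plurality == 1, ]
  se <- 3.4 / sqrt(nrow(d))
  expect_lt(abs(mean(d$education) - 8.7), 3 * se)
})

test_that("generator parameters survive a YAML round trip", {
  p <- make_table1_preset(scale = 0.001)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_generator_params(p, f)
  q <- read_generator_params(f)
  expect_equal(q$strata$intercept, p$strata$intercept, tolerance = 1e-9)
  expect_equal(q$edu_probs, p$edu_probs, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(q$missingness), unname(p$missingness))
  r1 <- generate_registry(p, 4); r2 <- generate_registry(q, 4)
  expect_identical(r1$preterm, r2$preterm)
})

test_that("registry tables round-trip through CSV with empty-field missingness", {
  p <- make_table1_preset(scale = 0.002,
                          missingness = c(education = 0.1, nativity = 0.05))
  reg <- generate_registry(p, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(nrow(back), nrow(reg))
  expect_equal(is.na(back$education), is.na(reg$education))
  expect_equal(back$preterm, reg$preterm)
})
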