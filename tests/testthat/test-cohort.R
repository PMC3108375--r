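# Cohort builder: exclusion ledger, recoding, and descriptive replication.

test_that("hand-built fixture yields the expected ledger and cohort", {
  reg <- registry_fixture(list(
    registry_row(), registry_row(plurality = 2L), registry_row(plurality = 3L),
    registry_row(mother_age = 18L), registry_row(education = NA),
    registry_row(ethnicity = "Puerto Rican", nativity = "Foreign-born"),
    registry_row(ethnicity = "Dominican"), registry_row(preterm = 1L),
    registry_row(education = 0L), registry_row(mother_age = 44L)))
  res <- apply_exclusions(reg, "age")
  expect_equal(nrow(res$cohort), 6L)
  expect_equal(res$ledger$removed, c(2L, 1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(attr(res$ledger, "input"), 10L)
  expect_equal(attr(res$ledger, "output"), 6L)
})

test_that("a fully eligible registry passes through unchanged", {
  reg <- all_strata_cohort()
  res <- apply_exclusions(reg, "full")
  expect_equal(res$ledger$removed, rep(0L, 8L))
  expect_identical(res$cohort, reg)
})

test_that("ledger conservation and idempotence hold on random registries", {
  for (seed in 1:8) {
    reg <- random_registry(80, seed)
    for (mode in c("age", "full")) {
      res <- apply_exclusions(reg, mode)
      expect_equal(attr(res$ledger, "input") - sum(res$ledger$removed),
                   attr(res$ledger, "output"))
      expect_equal(attr(res$ledger, "output"), nrow(res$cohort))
      again <- apply_exclusions(res$cohort, mode)
      expect_equal(sum(again$ledger$removed), 0L)
      expect_identical(again$cohort, res$cohort)
    }
  }
})

test_that("overlapping missingness is attributed to the first applicable rule", {
  reg <- registry_fixture(list(
    registry_row(nativity = NA, education = NA),  # counts against nativity
    registry_row()))
  res <- apply_exclusions(reg, "age")
  lg <- res$ledger
  expect_equal(lg$removed[lg$rule == "missing_nativity"], 1L)
  expect_equal(lg$removed[lg$rule == "missing_education"], 0L)
})

test_that("fully-adjusted mode additionally drops covariate missingness", {
  reg <- registry_fixture(list(registry_row(kessner = NA), registry_row()))
  expect_equal(attr(apply_exclusions(reg, "age")$ledger, "output"), 2L)
  res <- apply_exclusions(reg, "full")
  expect_equal(attr(res$ledger, "output"), 1L)
  expect_equal(res$ledger$removed[res$ledger$rule == "missing_covariate"], 1L)
})

test_that("recoding maps boundaries, caps education, and dichotomises risk", {
  cohort <- all_strata_cohort(registry_fixture(list(
    registry_row(mother_age = 20L), registry_row(mother_age = 40L),
    registry_row(education = 19L), registry_row(anemia = 1L),
    registry_row(parity = 0L), registry_row(parity = 5L),
    registry_row(kessner = "inadequate", infant_sex = "male",
                 tobacco = 1L, alcohol = 1L),
    registry_row(mother_age = 22L))))  # full reference pattern
  fr <- recode_cohort(cohort)
  n0 <- 14L
  expect_equal(as.character(fr$age_cat[n0 + 1]), "20-24")
  expect_equal(as.character(fr$age_cat[n0 + 2]), "40+")
  expect_equal(fr$education[n0 + 3], 17L)
  expect_equal(fr$medical_risk[n0 + 4], 1L)
  expect_equal(fr$parity0[n0 + 5], 1L)
  expect_equal(fr$parity5p[n0 + 6], 1L)
  last <- n0 + 7
  expect_equal(fr$kessner_inadequate[last], 1L)
  expect_equal(fr$male[last], 1L)
  expect_equal(fr$tobacco[last], 1L)
  expect_equal(fr$alcohol[last], 1L)
  # reference-pattern record maps to an all-zero design row
  expect_true(all(fr[n0 + 8, design_columns("full")] == 0))
  expect_equal(fr$j[1], 1L)
  expect_equal(fr$k[1], 0L)
})

test_that("recoding refuses unfiltered input", {
  expect_error(recode_cohort(all_strata_cohort(registry_row(mother_age = 18L))),
               "under 20")
  expect_error(recode_cohort(all_strata_cohort(registry_row(education = NA))),
               "missing")
})

test_that("descriptive table computes direct and weighted rates", {
  cohort <- registry_fixture(lapply(1:4, function(i)
    registry_row(ethnicity = "Cuban", preterm = as.integer(i == 1))))
  tab <- describe_cohort(cohort)
  row <- tab[tab$ethnicity == "Cuban" & tab$nativity == "US-born", ]
  expect_equal(row$ptb_pct, 25.0)
  expect_equal(row$n, 4L)
})

test_that("published subgroup rows aggregate to the published totals", {
  st <- ptbhier:::stratum_targets()
  tab <- data.frame(ethnicity = st$ethnicity, nativity = st$nativity,
                    n = st$size, nativity_pct = NA_real_,
                    ptb_pct = st$ptb_pct, edu_mean = st$edu_mean,
                    edu_sd = st$edu_sd, age35_pct = st$age35_pct,
                    adequate_pct = st$adequate_pct,
                    smoking_pct = st$smoking_pct,
                    drinking_pct = st$drinking_pct)
  agg <- aggregate_descriptives(tab)
  us <- agg[agg$nativity == "US-born", ]
  fb <- agg[agg$nativity == "Foreign-born", ]
  expect_equal(us$n, 82427L)
  expect_equal(fb$n, 177169L)
  expect_equal(us$ptb_pct, 8.83, tolerance = 0.005)
  expect_equal(fb$ptb_pct, 6.75, tolerance = 0.005)
  expect_equal(us$nativity_pct, 31.8, tolerance = 0.05)
  expect_equal(fb$nativity_pct, 68.2, tolerance = 0.05)
})

test_that("nativity percentages split a two-stratum subgroup as published", {
  # 1,073 vs 38,416 records: the published 2.7/97.3 split
  us <- registry_row()[rep(1, 1073), ]
  fb <- registry_row(nativity = "Foreign-born")[rep(1, 38416), ]
  tab <- describe_cohort(rbind(us, fb))
  mex <- tab[tab$ethnicity == "Mexican", ]
  expect_equal(round(mex$nativity_pct[mex$nativity == "US-born"], 1), 2.7)
  expect_equal(round(mex$nativity_pct[mex$nativity == "Foreign-born"], 1), 97.3)
})

test_that("describing the preset registry reproduces the published structure", {
  reg <- full_registry()
  cohort <- apply_exclusions(reg, "age")$cohort
  tab <- describe_cohort(cohort)
  st <- table1_preset()$strata
  for (i in seq_len(nrow(st))) {
    row <- tab[tab$ethnicity == st$ethnicity[i] &
                 tab$nativity == st$nativity[i], ]
    expect_equal(row$n, st$size[i])
    se <- sqrt(st$ptb_target[i] * (1 - st$ptb_target[i]) / st$size[i])
    expect_lt(abs(row$ptb_pct / 100 - st$ptb_target[i]), 4 * se)
    expect_lt(abs(row$edu_mean - st$edu_mean[i]),
              4 * st$edu_sd[i] / sqrt(st$size[i]))
  }
})

test_that("published accounting ledger reproduces the reported exclusion rate", {
  lg <- published_cohort_ledger()
  pct <- exclusion_percent(lg, "missing_any")
  expect_equal(round(pct, 1), 2.7)
  expect_equal(attr(lg, "output"), 338589L)
  expect_equal(attr(lg, "input") - sum(lg$removed), attr(lg, "output"))
})
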