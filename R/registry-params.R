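# Generator parameters for the synthetic birth registry.
#
# The generator emulates the structure of a city vital-statistics natality
# file: one row per birth with Hispanic subgroup, maternal nativity,
# completed years of education (0-17), maternal age, plurality, a preterm
# indicator (gestational age < 37 completed weeks), and the adjustment
# covariates. Ground truth is a logistic model per (subgroup, nativity)
# stratum: intercept + restricted quadratic spline in education + covariate
# effects, so every downstream estimate can be checked against the exact
# generating risk.

hispanic_subgroups <- c("Mexican", "Puerto Rican", "Cuban", "Dominican",
                        "Central American", "South American",
                        "Other/Unknown Hispanic")
nativity_classes <- c("US-born", "Foreign-born")

# Published descriptive statistics per (subgroup, nativity) stratum:
# population count, preterm %, education mean/SD, % aged 35+, % adequate
# prenatal care, % smoking and % drinking during pregnancy.
stratum_targets <- function() {
  x <- rbind(
    c(1073,  6.34, 12.9, 2.9, 14.26, 55.36, 2.06, 0.28),
    c(38416, 6.32,  8.7, 3.4,  7.34, 48.03, 0.18, 0.03),
    c(55751, 9.37, 12.3, 2.1, 12.42, 53.83, 7.66, 0.35),
    c(18062, 9.72, 11.9, 2.4, 18.74, 50.80, 7.18, 0.35),
    c(1360,  8.38, 14.3, 2.2, 22.06, 65.59, 3.54, 0.37),
    c(906,   8.28, 14.2, 2.5, 42.60, 65.23, 2.65, 0.33),
    c(8686,  7.61, 13.2, 2.1,  4.18, 57.68, 2.62, 0.17),
    c(57943, 6.82, 12.0, 2.7, 17.11, 51.69, 1.23, 0.13),
    c(1687,  7.17, 13.6, 2.1,  6.94, 58.15, 2.26, 0.18),
    c(17911, 7.00, 10.8, 3.4, 18.31, 51.89, 0.61, 0.11),
    c(3845,  7.13, 13.9, 2.1,  7.62, 59.90, 1.67, 0.08),
    c(35429, 5.70, 12.0, 3.2, 23.74, 51.39, 0.59, 0.08),
    c(10025, 8.16, 12.4, 2.0,  8.74, 51.89, 5.35, 0.22),
    c(8502,  5.65, 11.6, 2.8, 17.45, 50.12, 0.84, 0.07))
  colnames(x) <- c("size", "ptb_pct", "edu_mean", "edu_sd", "age35_pct",
                   "adequate_pct", "smoking_pct", "drinking_pct")
  data.frame(ethnicity = rep(hispanic_subgroups, each = 2),
             nativity = rep(nativity_classes, 7), x)
}

# Prevalences the descriptive table does not report, fixed at values typical
# of US urban natality files (see the methods vignette).
default_shared_prevalences <- function() {
  list(age35_split = c(0.78, 0.22),          # 35-39 vs 40+ within 35+
       age_under35_split = c(0.38, 0.34, 0.28), # 20-24, 25-29, 30-34
       parity = c(0.42, 0.53, 0.05),          # 0, 1-4, 5+
       kessner_rest_split = c(0.62, 0.38),    # intermediate vs inadequate
       male = 0.512,
       conditions = setNames(c(0.020, 0.030, 0.030, 0.007, 0.012, 0.001,
                               0.004, 0.006), condition_names))
}

# True covariate log-odds effects. Every non-reference level carries a
# positive effect so the reference pattern is genuinely the lowest-risk one.
default_covariate_effects <- function() {
  setNames(c(0.05, 0.10, 0.25, 0.45,   # age 25-29 ... 40+
             0.15, 0.25,               # parity 0, 5+
             0.25, 0.55,               # Kessner intermediate, inadequate
             0.10, 0.35, 0.15, 0.90),  # male, tobacco, alcohol, medical risk
           design_cols_full)
}

# True spline coefficients per stratum. Parameterised through the linear
# slopes the restricted basis implies: slope below the first knot is a1;
# slope above the last knot is a1 + 10*a2 + 4*a3 for knots (8, 11, 13).
# Native-born strata (and island-born Puerto Ricans) get a steep protective
# gradient above the knot span; other foreign-born strata get a much flatter
# curve with a shallow maximum near 10-12 years.
default_spline_truth <- function() {
  steep <- c(0.01, -0.012, 0)    # tail slope -0.11 log-odds/year
  flat  <- c(0.02, -0.0055, 0)   # tail slope -0.035 log-odds/year
  alpha <- matrix(NA_real_, 14, 3,
                  dimnames = list(NULL, c("a1", "a2", "a3")))
  usborn <- rep(c(TRUE, FALSE), 7)
  alpha[usborn, ] <- matrix(steep, sum(usborn), 3, byrow = TRUE)
  alpha[!usborn, ] <- matrix(flat, sum(!usborn), 3, byrow = TRUE)
  alpha[4, ] <- steep  # foreign-born (island-born) Puerto Rican
  alpha
}

# Match the discretised-truncated-normal education distribution on 0..17 to
# a target mean/SD by adjusting the latent normal's location and scale.
# Matching the *discrete* moments matters: plugging the printed moments into
# the latent normal would bias low-education strata by the 0/17 truncation.
education_distribution <- function(mean, sd) {
  grid <- 0:17
  probs_of <- function(mu, sigma) {
    p <- pnorm(grid + 0.5, mu, sigma) - pnorm(grid - 0.5, mu, sigma)
    p / sum(p)
  }
  moments <- function(p) {
    m <- sum(grid * p)
    c(m, sqrt(sum((grid - m)^2 * p)))
  }
  obj <- function(par) {
    mo <- moments(probs_of(par[1], exp(par[2])))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  setNames(probs_of(fit$par[1], exp(fit$par[2])), grid)
}

# Per-stratum covariate category probabilities from the targets plus shared
# prevalences.
stratum_covariate_probs <- function(targets_row, shared) {
  p35 <- targets_row$age35_pct / 100
  p_age <- c((1 - p35) * shared$age_under35_split, p35 * shared$age35_split)
  p_ad <- targets_row$adequate_pct / 100
  p_kess <- c(p_ad, (1 - p_ad) * shared$kessner_rest_split)
  list(age = setNames(p_age, age_levels),
       parity = setNames(shared$parity, parity_levels),
       kessner = setNames(p_kess, kessner_levels),
       male = shared$male,
       smoking = targets_row$smoking_pct / 100,
       drinking = targets_row$drinking_pct / 100,
       conditions = shared$conditions)
}

# Exact enumeration of the covariate design distribution for one stratum:
# every (age, parity, kessner, sex, tobacco, alcohol, medical-risk) cell with
# its probability and its covariate linear predictor under `beta`. The
# medical-risk dichotomy is Bernoulli with prevalence 1 - prod(1 - p_c).
covariate_cells <- function(cov, beta) {
  p_med <- 1 - prod(1 - cov$conditions)
  cells <- expand.grid(age = seq_along(age_levels),
                       parity = seq_along(parity_levels),
                       kessner = seq_along(kessner_levels),
                       male = 0:1, tobacco = 0:1, alcohol = 0:1, med = 0:1)
  w <- cov$age[cells$age] * cov$parity[cells$parity] *
    cov$kessner[cells$kessner] *
    ifelse(cells$male == 1, cov$male, 1 - cov$male) *
    ifelse(cells$tobacco == 1, cov$smoking, 1 - cov$smoking) *
    ifelse(cells$alcohol == 1, cov$drinking, 1 - cov$drinking) *
    ifelse(cells$med == 1, p_med, 1 - p_med)
  X <- t(mapply(function(a, p, k, m, t, al, md)
    design_row(age_levels[a], parity_levels[p], kessner_levels[k],
               sex_levels[m + 1], t, al, md),
    cells$age, cells$parity, cells$kessner, cells$male,
    cells$tobacco, cells$alcohol, cells$med))
  list(weight = unname(w), lin = drop(X %*% beta))
}

# Solve the stratum intercept so the covariate- and education-averaged PTB
# probability hits the printed marginal rate; one-dimensional root find.
calibrate_intercept <- function(target_p, edu_probs, alpha, knots, cells) {
  s <- drop(rq_terms(0:17, knots) %*% alpha)
  G <- outer(s, cells$lin, "+")
  W <- outer(as.numeric(edu_probs), cells$weight)
  marginal <- function(d) sum(W * expit(d + G)) - target_p
  uniroot(marginal, c(-12, 6), tol = 1e-10)$root
}

validate_generator_params <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  st <- params$strata
  if (any(st$size < 0)) stop("stratum sizes must be >= 0", call. = FALSE)
  bad_sum <- abs(rowSums(params$edu_probs) - 1) > 1e-6
  if (any(bad_sum)) stop("education probability vectors must sum to 1", call. = FALSE)
  if (any(params$edu_probs < -1e-12)) stop("education probabilities must be >= 0", call. = FALSE)
  if (ncol(params$edu_probs) != 18L)
    stop("education probabilities must be supported on 0..17", call. = FALSE)
  for (i in seq_len(nrow(st))) {
    cov <- params$cov[[i]]
    for (nm in c("age", "parity", "kessner")) {
      if (abs(sum(cov[[nm]]) - 1) > 1e-6 || any(cov[[nm]] < -1e-12))
        stop(sprintf("stratum %d: %s probabilities invalid", i, nm), call. = FALSE)
    }
    pr <- c(cov$male, cov$smoking, cov$drinking, cov$conditions)
    if (any(pr < 0 | pr > 1))
      stop(sprintf("stratum %d: prevalence outside [0,1]", i), call. = FALSE)
  }
  rates <- c(params$missingness, params$contamination)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]", call. = FALSE)
  invisible(params)
}

#' Construct synthetic-registry generator parameters
#'
#' Low-level constructor; most users want [make_table1_preset()], which fills
#' every field from the published descriptive table. All probability vectors
#' are validated.
#'
#' @param strata data.frame with columns `ethnicity`, `nativity`, `size`,
#'   `ptb_target` (marginal PTB probability), `intercept` (true log-odds),
#'   and `a1`, `a2`, `a3` (true spline coefficients on the uncentred basis).
#' @param edu_probs numeric matrix (strata x 18) of education probabilities
#'   over integer years 0--17.
#' @param cov list (one element per stratum) of covariate category
#'   probabilities as produced internally; see `make_table1_preset`.
#' @param beta named true covariate log-odds effects for the full design.
#' @param knots spline knots of the generating dose-response.
#' @param missingness named per-field missingness rates (fields `education`,
#'   `nativity`, `ethnicity`, `birthweight`, `kessner`, `tobacco`, `alcohol`,
#'   `parity`); missingness is completely at random.
#' @param contamination named rates of extra ineligible records appended to
#'   the table (`non_hispanic`, `under20`, `plural`), as fractions of the
#'   total configured stratum size.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(strata, edu_probs, cov, beta,
                             knots = default_knots,
                             missingness = NULL, contamination = NULL) {
  miss0 <- setNames(numeric(8), c("education", "nativity", "ethnicity",
                                  "birthweight", "kessner", "tobacco",
                                  "alcohol", "parity"))
  cont0 <- setNames(numeric(3), c("non_hispanic", "under20", "plural"))
  if (!is.null(missingness)) miss0[names(missingness)] <- missingness
  if (!is.null(contamination)) cont0[names(contamination)] <- contamination
  params <- structure(list(strata = strata, edu_probs = edu_probs, cov = cov,
                           beta = beta, knots = check_knots(knots),
                           missingness = miss0, contamination = cont0),
                      class = "generator_params")
  validate_generator_params(params)
}

#' Generator preset calibrated to the published descriptive table
#'
#' Builds generator parameters whose stratum sizes equal the published
#' population counts, whose education distributions are discretised truncated
#' normals moment-matched to the published means/SDs, whose covariate
#' prevalences match the published rates (with unreported splits fixed at
#' typical natality-file values), and whose intercepts are solved by root
#' finding so each stratum's marginal (covariate-averaged) PTB probability
#' equals the published preterm percentage. True spline coefficients default
#' to a steep protective education gradient for native-born strata (and
#' island-born Puerto Ricans) and a flat gradient elsewhere.
#'
#' @param scale multiply all stratum sizes by this factor (rounded); use for
#'   scaled-down simulation studies.
#' @param alpha optional 14 x 3 matrix of true spline coefficients
#'   (rows in stratum order US-born/Foreign-born within each subgroup).
#' @param missingness,contamination see [generator_params()]; defaults are
#'   zero missingness inside strata and 2% contamination of each kind, so
#'   that exclusion filters act only on records that do not belong to the
#'   analysis strata and descriptive statistics after filtering reproduce the
#'   configured sizes exactly.
#' @return a `generator_params` object.
#' @export
make_table1_preset <- function(scale = 1, alpha = NULL,
                               missingness = NULL,
                               contamination = c(non_hispanic = 0.02,
                                                 under20 = 0.02,
                                                 plural = 0.02)) {
  targets <- stratum_targets()
  shared <- default_shared_prevalences()
  beta <- default_covariate_effects()
  alpha <- alpha %||% default_spline_truth()
  n <- nrow(targets)
  edu_probs <- t(vapply(seq_len(n), function(i)
    education_distribution(targets$edu_mean[i], targets$edu_sd[i]),
    numeric(18)))
  cov <- lapply(seq_len(n), function(i)
    stratum_covariate_probs(targets[i, ], shared))
  intercept <- vapply(seq_len(n), function(i) {
    cells <- covariate_cells(cov[[i]], beta)
    calibrate_intercept(targets$ptb_pct[i] / 100, edu_probs[i, ],
                        alpha[i, ], default_knots, cells)
  }, numeric(1))
  strata <- data.frame(ethnicity = targets$ethnicity,
                       nativity = targets$nativity,
                       size = as.integer(round(targets$size * scale)),
                       ptb_target = targets$ptb_pct / 100,
                       edu_mean = targets$edu_mean, edu_sd = targets$edu_sd,
                       intercept = intercept,
                       a1 = alpha[, 1], a2 = alpha[, 2], a3 = alpha[, 3])
  generator_params(strata, edu_probs, cov, beta,
                   missingness = missingness, contamination = contamination)
}

#' Missingness rates implied by the published cohort accounting
#'
#' Field-level completely-at-random missingness rates derived from the
#' published exclusion counts (birthweight 81, nativity 5,962, ethnic
#' ancestry 9,416, education 15,254 out of 365,139 births) and the reported
#' 11.4% missing prenatal care, with smoking/drinking and parity missingness
#' at the reported sub-1.2% level.
#'
#' @return named numeric vector usable as the `missingness` argument of
#'   [generator_params()] or [make_table1_preset()].
#' @export
paper_missingness_rates <- function() {
  c(education = 15254 / 365139, nativity = 5962 / 365139,
    ethnicity = 9416 / 365139, birthweight = 81 / 365139,
    kessner = 0.114, tobacco = 0.005, alcohol = 0.005, parity = 0.012)
}
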