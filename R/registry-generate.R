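# Drawing synthetic registry tables and evaluating the generating truth.

draw_stratum_records <- function(params, i, n) {
  st <- params$strata[i, ]
  cov <- params$cov[[i]]
  edu <- sample(0:17, n, replace = TRUE, prob = params$edu_probs[i, ])
  age_cat <- sample(seq_along(age_levels), n, replace = TRUE, prob = cov$age)
  age_lo <- c(20, 25, 30, 35, 40)[age_cat]
  age_hi <- c(24, 29, 34, 39, 45)[age_cat]
  age <- age_lo + floor(runif(n) * (age_hi - age_lo + 1))
  parity_cat <- sample(seq_along(parity_levels), n, replace = TRUE,
                       prob = cov$parity)
  parity <- integer(n)
  parity[parity_cat == 2L] <- sample(1:4, sum(parity_cat == 2L), replace = TRUE)
  parity[parity_cat == 3L] <- sample(5:8, sum(parity_cat == 3L), replace = TRUE)
  kess <- kessner_levels[sample(seq_along(kessner_levels), n, replace = TRUE,
                                prob = cov$kessner)]
  male <- rbinom(n, 1, cov$male)
  tobacco <- rbinom(n, 1, cov$smoking)
  alcohol <- rbinom(n, 1, cov$drinking)
  conds <- vapply(cov$conditions, function(p) rbinom(n, 1, p),
                  integer(n))
  if (n == 1L) conds <- matrix(conds, nrow = 1,
                               dimnames = list(NULL, condition_names))
  med <- as.integer(rowSums(conds) > 0)
  X <- cbind((age_cat == 2) * 1, (age_cat == 3) * 1, (age_cat == 4) * 1,
             (age_cat == 5) * 1,
             (parity_cat == 1) * 1, (parity_cat == 3) * 1,
             (kess == kessner_levels[2]) * 1, (kess == kessner_levels[3]) * 1,
             male, tobacco, alcohol, med)
  eta <- st$intercept +
    drop(rq_terms(edu, params$knots) %*% c(st$a1, st$a2, st$a3)) +
    drop(X %*% unname(params$beta))
  preterm <- rbinom(n, 1, expit(eta))
  out <- data.frame(ethnicity = st$ethnicity, nativity = st$nativity,
                    education = edu, mother_age = age, plurality = 1L,
                    parity = parity, kessner = kess,
                    infant_sex = sex_levels[male + 1L],
                    tobacco = tobacco, alcohol = alcohol,
                    preterm = preterm, birthweight_missing = 0L,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(conds))
}

#' Generate a synthetic birth-registry table
#'
#' Draws one row per birth from the generating model in `params`: education
#' from the stratum's discrete distribution, covariates from their
#' prevalences, and the preterm outcome Bernoulli with probability
#' `expit(intercept + alpha . q(education) + beta . covariates)`.
#' Contamination records (non-Hispanic, under-20, non-singleton) are appended
#' at the configured rates, then per-field missingness is injected completely
#' at random. The result is fully reproducible given `(params, seed)` and the
#' caller's RNG stream is left untouched.
#'
#' @param params a `generator_params` object.
#' @param seed integer seed.
#' @return a `data.frame`, one row per birth, with columns `ethnicity`,
#'   `nativity`, `education`, `mother_age`, `plurality`, `parity`, `kessner`,
#'   `infant_sex`, `tobacco`, `alcohol`, `preterm`, `birthweight_missing`,
#'   and one 0/1 column per medical-risk condition. Missing values are `NA`
#'   (empty fields on disk).
#' @export
generate_registry <- function(params, seed) {
  validate_generator_params(params)
  with_seed(seed, {
    sizes <- params$strata$size
    parts <- lapply(which(sizes > 0), function(i)
      draw_stratum_records(params, i, sizes[i]))
    tab <- do.call(rbind, parts)
    total <- sum(sizes)
    n_cont <- round(params$contamination * total)
    if (sum(n_cont) > 0 && total > 0) {
      host <- sample(which(sizes > 0), sum(n_cont), replace = TRUE,
                     prob = sizes[sizes > 0])
      extra <- do.call(rbind, lapply(seq_along(host), function(r)
        draw_stratum_records(params, host[r], 1L)))
      kind <- rep(names(n_cont), n_cont)
      extra$ethnicity[kind == "non_hispanic"] <- "Non-Hispanic"
      n20 <- sum(kind == "under20")
      if (n20) extra$mother_age[kind == "under20"] <-
          sample(15:19, n20, replace = TRUE)
      extra$plurality[kind == "plural"] <- 2L
      tab <- rbind(tab, extra)
    }
    miss <- params$missingness
    field_of <- c(education = "education", nativity = "nativity",
                  ethnicity = "ethnicity", kessner = "kessner",
                  tobacco = "tobacco", alcohol = "alcohol", parity = "parity")
    for (nm in names(field_of)) {
      if (miss[[nm]] > 0) {
        hit <- runif(nrow(tab)) < miss[[nm]]
        tab[[field_of[[nm]]]][hit] <- NA
      }
    }
    if (miss[["birthweight"]] > 0)
      tab$birthweight_missing <- as.integer(runif(nrow(tab)) < miss[["birthweight"]])
    tab <- tab[sample(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

stratum_index <- function(params, ethnicity, nativity) {
  i <- which(params$strata$ethnicity == ethnicity &
               params$strata$nativity == nativity)
  if (length(i) != 1L)
    stop(sprintf("no stratum for ethnicity '%s', nativity '%s'",
                 ethnicity, nativity), call. = FALSE)
  i
}

#' Exact generating risk of preterm birth
#'
#' Evaluates the ground-truth probability used by [generate_registry()] for a
#' given stratum, education, and covariate pattern. This is the oracle that
#' fitted risk surfaces are checked against in parameter-recovery studies.
#'
#' @param params a `generator_params` object.
#' @param ethnicity,nativity stratum labels.
#' @param education years of education (vectorised, each within 0--17).
#' @param pattern a [reference_pattern()]; default is the lowest-risk pattern.
#' @return probabilities, one per education value.
#' @export
true_risk <- function(params, ethnicity, nativity, education, pattern = NULL) {
  i <- stratum_index(params, ethnicity, nativity)
  if (any(education < 0 | education > 17))
    stop("education must lie in 0..17", call. = FALSE)
  st <- params$strata[i, ]
  lin <- sum(unname(params$beta) * pattern_design(pattern, "full"))
  expit(st$intercept +
          evaluate_curve(c(st$a1, st$a2, st$a3), c(0, 0, 0), education,
                         params$knots) + lin)
}

#' Generating risk marginalised over the non-age covariates
#'
#' The oracle matching an age-adjusted fit's reference risk: age is held at
#' a fixed category (default the 20-24 reference) while the remaining
#' covariates are averaged over their exact stratum distribution. An
#' age-adjusted model omits those covariates, so its fitted risk at the age
#' reference targets this marginal quantity, not the all-lowest-risk
#' pattern of [true_risk()].
#'
#' @inheritParams true_risk
#' @param age age category at which the risk is evaluated.
#' @return probabilities, one per education value.
#' @export
true_age_adjusted_risk <- function(params, ethnicity, nativity, education,
                                   age = "20-24") {
  i <- stratum_index(params, ethnicity, nativity)
  if (any(education < 0 | education > 17))
    stop("education must lie in 0..17", call. = FALSE)
  st <- params$strata[i, ]
  cov <- params$cov[[i]]
  cov$age <- setNames((age_levels == match.arg(age, age_levels)) * 1,
                      age_levels)
  cells <- covariate_cells(cov, params$beta)
  s <- evaluate_curve(c(st$a1, st$a2, st$a3), c(0, 0, 0), education,
                      params$knots)
  vapply(s, function(sx)
    sum(cells$weight * expit(st$intercept + sx + cells$lin)), numeric(1))
}

#' Marginal (covariate- and education-averaged) generating risk
#'
#' The stratum-level PTB probability implied by the generator, averaging the
#' generating risk over the stratum's education distribution and the exact
#' covariate design distribution. For a calibrated preset this equals the
#' published preterm percentage by construction.
#'
#' @inheritParams true_risk
#' @return a single probability.
#' @export
marginal_true_risk <- function(params, ethnicity, nativity) {
  i <- stratum_index(params, ethnicity, nativity)
  st <- params$strata[i, ]
  cells <- covariate_cells(params$cov[[i]], params$beta)
  s <- drop(rq_terms(0:17, params$knots) %*% c(st$a1, st$a2, st$a3))
  W <- outer(as.numeric(params$edu_probs[i, ]), cells$weight)
  sum(W * expit(st$intercept + outer(s, cells$lin, "+")))
}

#' Read/write registry tables and generator parameters
#'
#' Registry tables are plain CSV with missing values as empty fields;
#' generator parameters round-trip through YAML.
#'
#' @param table a registry `data.frame`.
#' @param path file path.
#' @name registry_io
NULL

#' @rdname registry_io
#' @export
write_registry <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname registry_io
#' @export
read_registry <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}

#' @rdname registry_io
#' @param params a `generator_params` object.
#' @export
write_generator_params <- function(params, path) {
  obj <- list(strata = as.list(params$strata),
              edu_probs = apply(params$edu_probs, 1, as.numeric,
                                simplify = FALSE),
              cov = params$cov, beta = as.list(params$beta),
              knots = params$knots,
              missingness = as.list(params$missingness),
              contamination = as.list(params$contamination))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname registry_io
#' @export
read_generator_params <- function(path) {
  obj <- yaml::read_yaml(path)
  cov <- lapply(obj$cov, function(cv)
    list(age = setNames(as.numeric(cv$age), age_levels),
         parity = setNames(as.numeric(cv$parity), parity_levels),
         kessner = setNames(as.numeric(cv$kessner), kessner_levels),
         male = cv$male, smoking = cv$smoking, drinking = cv$drinking,
         conditions = setNames(as.numeric(cv$conditions), condition_names)))
  generator_params(strata = as.data.frame(obj$strata,
                                          stringsAsFactors = FALSE),
                   edu_probs = do.call(rbind, lapply(obj$edu_probs, as.numeric)),
                   cov = cov,
                   beta = setNames(as.numeric(obj$beta), names(obj$beta)),
                   knots = as.numeric(obj$knots),
                   missingness = unlist(obj$missingness),
                   contamination = unlist(obj$contamination))
}
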