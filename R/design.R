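# Shared covariate design definition.
#
# One place defines the model's covariate design columns, their reference
# levels, and the mapping from categorical levels to indicator columns; the
# generator, the recoder, the calibration enumeration, and the reference
# pattern used for risk surfaces all go through it. Reference levels are the
# lowest-risk pattern (mother 20-24, 1-4 previous live births, adequate
# prenatal care, female infant, no tobacco/alcohol, none of the medical-risk
# conditions), so a fitted intercept is directly the reference log-odds.

age_levels     <- c("20-24", "25-29", "30-34", "35-39", "40+")
parity_levels  <- c("0", "1-4", "5+")
kessner_levels <- c("adequate", "intermediate", "inadequate")
sex_levels     <- c("female", "male")

condition_names <- c("anemia", "hypertension", "diabetes", "uterine_bleeding",
                     "preeclampsia", "eclampsia", "placenta_previa",
                     "placental_abruption")

design_cols_full <- c("age25_29", "age30_34", "age35_39", "age40p",
                      "parity0", "parity5p",
                      "kessner_intermediate", "kessner_inadequate",
                      "male", "tobacco", "alcohol", "medical_risk")
design_cols_age <- design_cols_full[1:4]

#' Design column names for an adjustment mode
#'
#' @param mode `"age"` (maternal-age categories only) or `"full"` (all
#'   covariates).
#' @return character vector of indicator column names.
#' @export
design_columns <- function(mode = c("age", "full")) {
  mode <- match.arg(mode)
  if (mode == "age") design_cols_age else design_cols_full
}

# Indicator row for one covariate pattern given as levels.
design_row <- function(age = "20-24", parity = "1-4", kessner = "adequate",
                       sex = "female", tobacco = 0L, alcohol = 0L,
                       medical_risk = 0L) {
  age <- match.arg(age, age_levels)
  parity <- match.arg(parity, parity_levels)
  kessner <- match.arg(kessner, kessner_levels)
  sex <- match.arg(sex, sex_levels)
  setNames(c(age == age_levels[2], age == age_levels[3],
             age == age_levels[4], age == age_levels[5],
             parity == parity_levels[1], parity == parity_levels[3],
             kessner == kessner_levels[2], kessner == kessner_levels[3],
             sex == "male", tobacco > 0, alcohol > 0, medical_risk > 0) * 1,
           design_cols_full)
}

#' Reference covariate pattern
#'
#' The covariate levels at which adjusted absolute risks are evaluated.
#' Defaults to the lowest-risk pattern; individual levels can be overridden.
#'
#' @param age,parity,kessner,sex categorical levels.
#' @param tobacco,alcohol,medical_risk 0/1 flags.
#' @return an object of class `reference_pattern` (named list of levels with
#'   the corresponding design indicator row as attribute `design`).
#' @export
reference_pattern <- function(age = "20-24", parity = "1-4",
                              kessner = "adequate", sex = "female",
                              tobacco = 0L, alcohol = 0L, medical_risk = 0L) {
  lv <- list(age = age, parity = parity, kessner = kessner, sex = sex,
             tobacco = tobacco, alcohol = alcohol, medical_risk = medical_risk)
  structure(lv, design = design_row(age, parity, kessner, sex, tobacco,
                                    alcohol, medical_risk),
            class = "reference_pattern")
}

pattern_design <- function(pattern, mode = "full") {
  if (is.null(pattern)) pattern <- reference_pattern()
  if (!inherits(pattern, "reference_pattern"))
    stop("`pattern` must be created by reference_pattern()", call. = FALSE)
  attr(pattern, "design")[design_columns(mode)]
}
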