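# Cohort construction: inclusion/exclusion accounting, covariate recoding,
# and stratum-level descriptive summaries.
#
# Exclusion rules are applied in a fixed, documented order (non-singleton,
# under-20, non-Hispanic, missing birthweight, missing nativity, missing
# ethnic ancestry, missing education, then — in fully-adjusted mode — missing
# any adjustment covariate). The source data report only counts, not an
# order; when a record fails several rules it is attributed to the first
# applicable one, so the ledger depends on this order.

registry_required_cols <- function() c("ethnicity", "nativity", "education",
                            "mother_age", "plurality", "parity", "kessner",
                            "infant_sex", "tobacco", "alcohol", "preterm",
                            "birthweight_missing", condition_names)

exclusion_rules <- function(mode) {
  rules <- list(
    non_singleton      = function(d) !is.na(d$plurality) & d$plurality > 1,
    under_20           = function(d) !is.na(d$mother_age) & d$mother_age < 20,
    non_hispanic       = function(d) !is.na(d$ethnicity) &
      !(d$ethnicity %in% hispanic_subgroups),
    missing_birthweight = function(d) d$birthweight_missing %in% 1,
    missing_nativity   = function(d) is.na(d$nativity),
    missing_ethnicity  = function(d) is.na(d$ethnicity),
    missing_education  = function(d) is.na(d$education))
  if (mode == "full")
    rules$missing_covariate <- function(d)
      is.na(d$kessner) | is.na(d$infant_sex) | is.na(d$parity) |
      is.na(d$tobacco) | is.na(d$alcohol) | is.na(d$mother_age) |
      Reduce(`|`, lapply(condition_names, function(cn) is.na(d[[cn]])))
  rules
}

#' Apply cohort inclusion/exclusion rules
#'
#' Filters a registry table down to the analysis cohort of singleton births
#' to Hispanic/Latina women aged 20 or older with complete outcome-relevant
#' fields, recording how many records each rule removes. Records failing
#' several rules count against the first applicable rule only, so the
#' ledger's removals always sum to input minus output.
#'
#' @param registry a registry `data.frame` (see [generate_registry()]).
#' @param mode `"age"` for the age-adjusted cohort or `"full"` to also drop
#'   records missing any adjustment covariate.
#' @return list with `cohort` (the retained rows) and `ledger`, a
#'   `data.frame` of class `exclusion_ledger` with columns `rule`, `removed`,
#'   `remaining` and attributes `input`, `output`, `mode`.
#' @export
apply_exclusions <- function(registry, mode = c("age", "full")) {
  mode <- match.arg(mode)
  stopifnot_cols(registry, registry_required_cols(), "registry")
  rules <- exclusion_rules(mode)
  keep <- rep(TRUE, nrow(registry))
  removed <- integer(length(rules))
  remaining <- integer(length(rules))
  for (r in seq_along(rules)) {
    hit <- keep & rules[[r]](registry)
    removed[r] <- sum(hit)
    keep <- keep & !hit
    remaining[r] <- sum(keep)
  }
  ledger <- structure(
    data.frame(rule = names(rules), removed = removed, remaining = remaining,
               stringsAsFactors = FALSE),
    input = nrow(registry), output = sum(keep), mode = mode,
    class = c("exclusion_ledger", "data.frame"))
  cohort <- registry[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger (%s-adjusted cohort)\n", attr(x, "mode")))
  cat(sprintf("  input records: %d\n", attr(x, "input")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("  retained: %d (%.1f%%)\n", attr(x, "output"),
              100 * attr(x, "output") / max(attr(x, "input"), 1)))
  invisible(x)
}

#' Percentage of records removed by a ledger's rules
#'
#' @param ledger an `exclusion_ledger`.
#' @param rules rule names to include; defaults to all rules in the ledger.
#' @return removals among the selected rules as a percentage of the ledger's
#'   input count.
#' @export
exclusion_percent <- function(ledger, rules = ledger$rule) {
  100 * sum(ledger$removed[ledger$rule %in% rules]) / attr(ledger, "input")
}

#' The published cohort accounting as an exclusion ledger
#'
#' Reconstructs the source study's reported accounting: 990,597 singleton
#' births to women aged 20+, restriction to the 365,139 Hispanic/Latina
#' births, then a cumulative 26,550 records missing birthweight, nativity,
#' ethnic ancestry, or education. The reported field-level missingness
#' counts (81, 5,962, 9,416, 15,254) sum to 26,713 — more than the
#' cumulative exclusion because records can miss several fields — so they
#' are attached as attribute `field_counts` rather than stacked as ledger
#' rows. `exclusion_percent()` over the `missing_any` rule reproduces the
#' reported cumulative exclusion of 2.7%.
#'
#' @return an `exclusion_ledger`.
#' @export
published_cohort_ledger <- function() {
  removed <- c(non_hispanic = 990597L - 365139L, missing_any = 26550L)
  remaining <- 990597L - cumsum(removed)
  structure(data.frame(rule = names(removed), removed = unname(removed),
                       remaining = unname(remaining),
                       stringsAsFactors = FALSE),
            input = 990597L, output = unname(remaining[length(remaining)]),
            mode = "age",
            field_counts = c(missing_birthweight = 81L,
                             missing_nativity = 5962L,
                             missing_ethnicity = 9416L,
                             missing_education = 15254L),
            class = c("exclusion_ledger", "data.frame"))
}

#' @rdname registry_io
#' @param ledger an `exclusion_ledger`.
#' @export
write_ledger <- function(ledger, path) {
  write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}

#' Recode a filtered cohort into the model frame
#'
#' Maps raw registry fields to the analysis design: education capped at 17
#' completed years; maternal age to categories 20-24 / 25-29 / 30-34 / 35-39
#' / 40+; previous live births to 0 / 1-4 / 5+; prenatal-care adequacy kept
#' as the three Kessner levels; the medical-risk dichotomy set when any of
#' the eight recorded conditions is present; and indicator design columns
#' built against the lowest-risk reference levels (see [reference_pattern()]).
#'
#' @param cohort a filtered registry (no missing model fields; run
#'   [apply_exclusions()] first).
#' @return a `data.frame` (the model frame) with columns `preterm`,
#'   `ethnicity`, `nativity`, `j`, `k`, `education`, the categorical
#'   recodings, and one column per design indicator. Attribute
#'   `design_cols` lists the indicator columns.
#' @export
recode_cohort <- function(cohort) {
  stopifnot_cols(cohort, registry_required_cols(), "cohort")
  if (any(cohort$mother_age < 20, na.rm = TRUE))
    stop("cohort contains mothers under 20; apply_exclusions() must run first",
         call. = FALSE)
  need <- c("education", "nativity", "ethnicity", "mother_age", "parity",
            "kessner", "infant_sex", "tobacco", "alcohol")
  if (anyNA(cohort[need]) || anyNA(cohort[condition_names]))
    stop("cohort contains missing model fields; apply_exclusions() must run first",
         call. = FALSE)
  edu <- pmin(as.integer(cohort$education), 17L)
  age_cat <- cut(cohort$mother_age, c(20, 25, 30, 35, 40, Inf),
                 labels = age_levels, right = FALSE)
  parity_cat <- cut(cohort$parity, c(-Inf, 0, 4, Inf), labels = parity_levels)
  kess <- factor(cohort$kessner, levels = kessner_levels)
  med <- as.integer(rowSums(cohort[condition_names]) > 0)
  male <- as.integer(cohort$infant_sex == "male")
  frame <- data.frame(
    preterm = as.integer(cohort$preterm),
    ethnicity = factor(cohort$ethnicity, levels = hispanic_subgroups),
    nativity = factor(cohort$nativity, levels = nativity_classes),
    education = edu, age_cat = age_cat, parity_cat = parity_cat,
    kessner = kess, male = male,
    tobacco = as.integer(cohort$tobacco > 0),
    alcohol = as.integer(cohort$alcohol > 0),
    medical_risk = med)
  frame$j <- as.integer(frame$ethnicity)
  frame$k <- as.integer(frame$nativity) - 1L  # 0 = US-born, 1 = foreign-born
  frame$age25_29 <- (age_cat == age_levels[2]) * 1L
  frame$age30_34 <- (age_cat == age_levels[3]) * 1L
  frame$age35_39 <- (age_cat == age_levels[4]) * 1L
  frame$age40p   <- (age_cat == age_levels[5]) * 1L
  frame$parity0  <- (parity_cat == parity_levels[1]) * 1L
  frame$parity5p <- (parity_cat == parity_levels[3]) * 1L
  frame$kessner_intermediate <- (kess == kessner_levels[2]) * 1L
  frame$kessner_inadequate   <- (kess == kessner_levels[3]) * 1L
  structure(frame, design_cols = design_cols_full)
}

weighted_pct <- function(pct, n) sum(pct * n) / sum(n)

#' Stratum-level descriptive statistics
#'
#' Per (subgroup, nativity) stratum: record count, nativity percentage
#' within the subgroup, PTB percentage, education mean and SD, and covariate
#' prevalences. Aggregate "All Hispanic/Latino" rows (one per nativity class)
#' are population-weighted combinations of the subgroup rows.
#'
#' @param cohort a filtered registry.
#' @return data.frame, one row per stratum plus two aggregate rows; empty
#'   strata keep `n = 0` with rate columns `NA`.
#' @export
describe_cohort <- function(cohort) {
  stopifnot_cols(cohort, registry_required_cols(), "cohort")
  grid <- expand.grid(ethnicity = hispanic_subgroups,
                      nativity = nativity_classes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    d <- cohort[cohort$ethnicity %in% grid$ethnicity[r] &
                  cohort$nativity %in% grid$nativity[r], , drop = FALSE]
    n <- nrow(d)
    if (n == 0L)
      return(data.frame(ethnicity = grid$ethnicity[r],
                        nativity = grid$nativity[r], n = 0L,
                        nativity_pct = NA_real_, ptb_pct = NA_real_,
                        edu_mean = NA_real_, edu_sd = NA_real_,
                        age35_pct = NA_real_, adequate_pct = NA_real_,
                        smoking_pct = NA_real_, drinking_pct = NA_real_))
    data.frame(ethnicity = grid$ethnicity[r], nativity = grid$nativity[r],
               n = n, nativity_pct = NA_real_,
               ptb_pct = 100 * mean(d$preterm, na.rm = TRUE),
               edu_mean = mean(d$education, na.rm = TRUE),
               edu_sd = sd(d$education, na.rm = TRUE),
               age35_pct = 100 * mean(d$mother_age >= 35, na.rm = TRUE),
               adequate_pct = 100 * mean(d$kessner == "adequate", na.rm = TRUE),
               smoking_pct = 100 * mean(d$tobacco, na.rm = TRUE),
               drinking_pct = 100 * mean(d$alcohol, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  for (eth in hispanic_subgroups) {
    idx <- tab$ethnicity == eth
    tot <- sum(tab$n[idx])
    if (tot > 0) tab$nativity_pct[idx] <- 100 * tab$n[idx] / tot
  }
  agg <- aggregate_descriptives(tab)
  rbind(agg, tab)
}

#' Population-weighted aggregate of subgroup descriptive rows
#'
#' Combines subgroup rows into "All Hispanic/Latino" rows per nativity class,
#' weighting every percentage and mean by the subgroup population counts.
#'
#' @param tab a descriptive table with one row per (subgroup, nativity).
#' @return data.frame with one aggregate row per nativity class.
#' @export
aggregate_descriptives <- function(tab) {
  tab <- tab[tab$ethnicity %in% hispanic_subgroups & tab$n > 0, , drop = FALSE]
  agg <- lapply(nativity_classes, function(nat) {
    d <- tab[tab$nativity == nat, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(ethnicity = "All Hispanic/Latino", nativity = nat,
               n = sum(d$n), nativity_pct = NA_real_,
               ptb_pct = weighted_pct(d$ptb_pct, d$n),
               edu_mean = weighted_pct(d$edu_mean, d$n),
               edu_sd = NA_real_,
               age35_pct = weighted_pct(d$age35_pct, d$n),
               adequate_pct = weighted_pct(d$adequate_pct, d$n),
               smoking_pct = weighted_pct(d$smoking_pct, d$n),
               drinking_pct = weighted_pct(d$drinking_pct, d$n))
  })
  agg <- do.call(rbind, agg)
  tot <- sum(agg$n)
  if (!is.null(agg) && tot > 0) agg$nativity_pct <- 100 * agg$n / tot
  agg
}
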