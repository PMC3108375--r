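# Posterior deliverables: absolute-risk surfaces on the ethnicity x nativity
# x education grid, native-minus-foreign risk differences, and the
# age-adjusted versus fully-adjusted comparison. Every summary is computed
# draw by draw and aggregated afterwards; summarising the parameters first
# and transforming would bias every nonlinear functional.

risk_draw_array <- function(draws, pattern, grid) {
  eth <- draws$ethnicities
  nat <- draws$nativities
  xdes <- pattern_design(pattern, draws$spec$adjustment)
  beta_mat <- par_matrix(draws, grep("^beta\\[", draws$pars, value = TRUE))
  lin <- drop(beta_mat %*% xdes)
  delta_mat <- par_matrix(draws, grep("^delta\\[", draws$pars, value = TRUE))
  alpha_pars <- grep("^alpha", draws$pars, value = TRUE)
  alpha_mat <- par_matrix(draws, alpha_pars)  # columns g within j within k
  qg <- sweep(rq_terms(grid, draws$knots), 2, draws$offsets)
  nd <- nrow(delta_mat)
  out <- array(NA_real_, c(nd, 7, 2, length(grid)),
               dimnames = list(NULL, eth, nat, grid))
  for (s in 1:14) {
    k <- (s - 1L) %/% 7L + 1L
    j <- (s - 1L) %% 7L + 1L
    acols <- alpha_mat[, (3 * (s - 1) + 1):(3 * s), drop = FALSE]
    for (gi in seq_along(grid)) {
      eta <- delta_mat[, s] + drop(acols %*% qg[gi, ]) + lin
      out[, j, k, gi] <- expit(eta)
    }
  }
  out
}

summ_draws <- function(v) {
  qs <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(mean = mean(v), median = qs[2], lower95 = qs[1], upper95 = qs[3])
}

#' Posterior absolute-risk surface
#'
#' For every retained draw and every (ethnic group, nativity class,
#' education year) grid point, computes the absolute PTB probability at the
#' supplied covariate pattern, then summarises across draws (posterior mean,
#' median, central 95% interval). Native-born entries below the reporting
#' floor (8 years by default) are flagged `below_floor`: such attainments
#' are too rare among US-born mothers to support estimation, and flagged
#' rows are suppressed at plotting, not at estimation.
#'
#' @param draws a `ptb_draws` object.
#' @param pattern a [reference_pattern()]; default is the lowest-risk
#'   pattern (for an age-adjusted fit only the age level matters).
#' @param grid education years to evaluate (default 0--17).
#' @param native_floor education level below which native-born estimates are
#'   flagged.
#' @param keep_draws keep the per-draw risk array as attribute
#'   `risk_draws` (needed by [risk_difference_surface()]).
#' @return data.frame of class `risk_surface` with columns `ethnicity`,
#'   `nativity`, `education`, `mean`, `median`, `lower95`, `upper95`,
#'   `below_floor`.
#' @export
risk_surface <- function(draws, pattern = NULL, grid = 0:17,
                         native_floor = 8, keep_draws = TRUE) {
  stopifnot(inherits(draws, "ptb_draws"))
  if (any(grid < 0 | grid > 17)) stop("grid must lie within 0..17")
  arr <- risk_draw_array(draws, pattern, grid)
  stats <- t(apply(expand.grid(gi = seq_along(grid), k = 1:2, j = 1:7)[, 3:1],
                   1, function(r) summ_draws(arr[, r[1], r[2], r[3]])))
  ord <- expand.grid(gi = seq_along(grid), k = 1:2, j = 1:7)
  out <- data.frame(ethnicity = draws$ethnicities[ord$j],
                    nativity = draws$nativities[ord$k],
                    education = grid[ord$gi], stats,
                    stringsAsFactors = FALSE)
  out$below_floor <- out$nativity == draws$nativities[1] &
    out$education < native_floor
  out <- out[order(match(out$ethnicity, draws$ethnicities),
                   match(out$nativity, draws$nativities), out$education), ]
  rownames(out) <- NULL
  structure(out, class = c("risk_surface", "data.frame"),
            risk_draws = if (keep_draws) arr else NULL,
            pattern = pattern, grid = grid,
            adjustment = draws$spec$adjustment)
}

#' Posterior risk-difference surface (native minus foreign born)
#'
#' The risk difference is formed within each retained draw —
#' `RD = risk(US-born) - risk(foreign-born)` at the same education — and
#' only then summarised, so the interval reflects the joint posterior. The
#' grid starts at 8 years, the effective minimum education for native-born
#' mothers.
#'
#' @param surface a `risk_surface` computed with `keep_draws = TRUE`.
#' @param grid education years (subset of the surface grid, default 8--17).
#' @return data.frame of class `rd_surface` with per (ethnicity, education)
#'   posterior mean, median and 95% interval of the RD.
#' @export
risk_difference_surface <- function(surface, grid = 8:17) {
  arr <- attr(surface, "risk_draws")
  if (is.null(arr))
    stop("surface was computed with keep_draws = FALSE; per-draw risks are required",
         call. = FALSE)
  sgrid <- as.numeric(dimnames(arr)[[4]])
  if (!all(grid %in% sgrid)) stop("grid must be within the surface grid")
  gi <- match(grid, sgrid)
  eth <- dimnames(arr)[[2]]
  rows <- list()
  for (j in seq_along(eth)) for (g in seq_along(gi)) {
    rd <- arr[, j, 1, gi[g]] - arr[, j, 2, gi[g]]
    rows[[length(rows) + 1L]] <- data.frame(
      ethnicity = eth[j], education = grid[g], t(summ_draws(rd)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out[order(match(out$ethnicity, eth), out$education), ],
            class = c("rd_surface", "data.frame"),
            adjustment = attr(surface, "adjustment"))
}

#' Compare age-adjusted and fully-adjusted risk differences
#'
#' Pairs the two RD summaries on a common (ethnicity, education) grid and
#' reports their difference, mirroring the check that extensive covariate
#' adjustment changes the nativity contrasts little.
#'
#' @param rd_age,rd_full `rd_surface` objects on the same grid.
#' @return data.frame with the two posterior means and their difference per
#'   (ethnicity, education).
#' @export
compare_adjustments <- function(rd_age, rd_full) {
  key <- c("ethnicity", "education")
  if (!identical(rd_age[key], rd_full[key]))
    stop("risk-difference surfaces are on different grids", call. = FALSE)
  data.frame(rd_age[key],
             rd_age = rd_age$mean, rd_full = rd_full$mean,
             difference = rd_full$mean - rd_age$mean)
}

#' @rdname registry_io
#' @param surface a `risk_surface` or `rd_surface`.
#' @export
write_surface <- function(surface, path) {
  write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}
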