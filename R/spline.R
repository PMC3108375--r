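# Restricted quadratic spline basis for years of completed education.
#
# The dose-response in education is modelled with three coefficients on the
# basis
#   q1(x) = x
#   q2(x) = (x - k1)+^2 - (x - k3)+^2
#   q3(x) = (x - k2)+^2 - (x - k3)+^2
# with interior knots k1 < k2 < k3 (default 8, 11, 13 years). Subtracting the
# outer-knot term cancels the quadratic growth above k3, so the curve is
# quadratic on [k1, k3], exactly linear below k1 and above k3, and
# continuously differentiable everywhere. Columns are centred at the fitting
# sample's means for sampler stability; the offsets are carried so risks can
# be evaluated at any education value on the same scale.

default_knots <- c(8, 11, 13)

check_knots <- function(knots) {
  if (!is.numeric(knots) || length(knots) != 3L || anyNA(knots))
    stop("knots must be three numeric values", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing", call. = FALSE)
  if (knots[1] < 0 || knots[3] > 17)
    stop("knots must lie within the education range [0, 17]", call. = FALSE)
  as.numeric(knots)
}

pos2 <- function(x) pmax(x, 0)^2

rq_terms <- function(x, knots) {
  cbind(q1 = x,
        q2 = pos2(x - knots[1]) - pos2(x - knots[3]),
        q3 = pos2(x - knots[2]) - pos2(x - knots[3]))
}

#' Build the restricted quadratic spline basis
#'
#' Evaluates the three restricted quadratic spline columns at the supplied
#' education values. The returned basis is uncentred (`offsets = c(0, 0, 0)`);
#' use [center_basis()] to centre it at a fitting sample.
#'
#' @param x numeric education values (years, within 0--17).
#' @param knots three strictly increasing interior knots (years); default
#'   `c(8, 11, 13)`.
#' @return an object of class `spline_basis`: list with `Q` (n x 3 matrix of
#'   basis columns, possibly centred), `knots`, `offsets`, and the evaluation
#'   points `x`.
#' @examples
#' b <- build_basis(0:17)
#' b$Q[b$x == 13, ]  # (13, 25, 4)
#' @export
build_basis <- function(x, knots = default_knots) {
  knots <- check_knots(knots)
  if (!is.numeric(x) || anyNA(x)) stop("education values must be numeric and non-missing")
  if (any(x < 0 | x > 17)) stop("education values must lie in [0, 17]")
  structure(list(Q = rq_terms(x, knots), knots = knots,
                 offsets = c(0, 0, 0), x = as.numeric(x)),
            class = "spline_basis")
}

#' Centre a spline basis at a sample of education values
#'
#' Subtracts the sample mean of each basis column. Centring only shifts the
#' intercept of the linear predictor; fitted probabilities are unchanged, but
#' the sampler mixes better because intercept and spline coefficients are far
#' less correlated.
#'
#' @param basis a `spline_basis` from [build_basis()].
#' @param sample education values defining the centring sample; defaults to
#'   the basis's own evaluation points.
#' @return the basis with centred `Q` and the centring `offsets` recorded.
#' @export
center_basis <- function(basis, sample = NULL) {
  stopifnot(inherits(basis, "spline_basis"))
  sample <- sample %||% basis$x
  if (!length(sample)) stop("centring sample must be non-empty")
  off <- colMeans(rq_terms(sample, basis$knots))
  Q <- rq_terms(basis$x, basis$knots)
  basis$Q <- sweep(Q, 2, off)
  basis$offsets <- unname(off)
  basis
}

#' Evaluate the education dose-response contribution
#'
#' Computes `alpha . (q(x) - offsets)`, the log-odds contribution of
#' education at `x` for spline coefficients `alpha` under the centring
#' `offsets` used at fitting time.
#'
#' @param alpha numeric length-3 spline coefficients.
#' @param offsets numeric length-3 centring offsets (0 for an uncentred fit),
#'   or a `spline_basis` whose offsets and knots are used.
#' @param x education values to evaluate at.
#' @param knots knots (ignored when `offsets` is a `spline_basis`).
#' @return numeric vector of log-odds contributions, one per `x`.
#' @export
evaluate_curve <- function(alpha, offsets, x, knots = default_knots) {
  if (inherits(offsets, "spline_basis")) {
    knots <- offsets$knots
    offsets <- offsets$offsets
  }
  stopifnot(length(alpha) == 3L, length(offsets) == 3L)
  knots <- check_knots(knots)
  drop(sweep(rq_terms(x, knots), 2, offsets) %*% alpha)
}

#' Tabulate the spline basis over the education grid
#'
#' Convenience export of the (uncentred) basis on integer years 0--17, for
#' inspection or comparison against other implementations.
#'
#' @inheritParams build_basis
#' @return data.frame with columns `education`, `q1`, `q2`, `q3`.
#' @export
spline_basis_table <- function(knots = default_knots) {
  knots <- check_knots(knots)
  data.frame(education = 0:17, rq_terms(0:17, knots))
}
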