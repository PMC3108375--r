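# Small shared helpers.

#' Inverse-logit with overflow guard
#'
#' Logistic transform of a linear predictor; the argument is clipped to
#' +/- 30 log-odds first. Beyond that range the probability is within 1e-13
#' of 0 or 1, so clipping avoids overflow without measurable bias.
#'
#' @param x numeric vector of log-odds.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) plogis(pmin(pmax(x, -30), 30))

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
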