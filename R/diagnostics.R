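# MCMC convergence diagnostics: split-chain potential scale reduction and
# effective sample size, plus trace exports for the monitored parameters.

split_rhat <- function(mat) {
  # mat: iterations x chains; each chain split in half
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for posterior draws
#'
#' Per monitored parameter: posterior mean and SD, split-chain potential
#' scale reduction (R-hat; each chain is split in half, so a single chain
#' still yields a value when it has enough draws, but R-hat is reported as
#' `NA` for fewer than two chains as between-chain mixing cannot be
#' assessed), and effective sample size (via [coda::effectiveSize()], summed
#' across chains).
#'
#' @param draws a `ptb_draws` object.
#' @param pars parameter names to report; defaults to all.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `rhat`, `ess`.
#' @export
diagnostics <- function(draws, pars = NULL) {
  pars <- pars %||% draws$pars
  i <- match(pars, draws$pars)
  if (anyNA(i)) stop("unknown parameter name(s)", call. = FALSE)
  nchain <- dim(draws$draws)[2]
  out <- lapply(i, function(ix) {
    mat <- draws$draws[, , ix, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
    mcl <- coda::as.mcmc.list(lapply(seq_len(ncol(mat)), function(ch)
      coda::mcmc(mat[, ch])))
    data.frame(parameter = draws$pars[ix],
               mean = mean(mat), sd = sd(as.numeric(mat)),
               rhat = if (nchain >= 2L) split_rhat(mat) else NA_real_,
               ess = sum(coda::effectiveSize(mcl)))
  })
  do.call(rbind, out)
}

#' Trace plot of monitored parameters
#'
#' One panel per parameter, one line per chain, in the style used to assess
#' mixing visually (spline terms, an intercept, and a precision are the
#' typical choices).
#'
#' @param draws a `ptb_draws` object.
#' @param pars parameter names (default: the first spline coefficient,
#'   intercept, and precision of the first stratum).
#' @return a ggplot object.
#' @export
trace_plot <- function(draws, pars = NULL) {
  pars <- pars %||% draws$pars[c(grep("^alpha1", draws$pars)[1],
                                 grep("^delta", draws$pars)[1],
                                 grep("^tau0", draws$pars)[1])]
  long <- draws_long(draws)
  long <- long[long$parameter %in% pars, , drop = FALSE]
  long$parameter <- factor(long$parameter, levels = pars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
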