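# End-to-end pipeline: simulate (optional) -> filter -> recode -> fit ->
# summarise -> export, with stage-level logging, file-based interfaces
# between stages, and a machine-readable run manifest.

#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: either `registry` (path to an
#' existing registry CSV) or `preset` (generator parameters to simulate
#' from; a `generator_params` object or a YAML path).
#'
#' @param output_dir directory for all run artifacts.
#' @param registry optional path to a registry CSV.
#' @param preset optional `generator_params` or YAML path.
#' @param mode `"age"`, `"full"`, or `"both"`.
#' @param spec a `ptb_model_spec` (its `adjustment` field is set per mode).
#' @param config an `mcmc_config`.
#' @param seed global seed; seeds simulation, and offsets the MCMC seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir, registry = NULL, preset = NULL,
                       mode = c("age", "full", "both"),
                       spec = model_spec(), config = mcmc_config(),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(registry) == is.null(preset))
    stop("supply exactly one of `registry` (a CSV path) or `preset`",
         call. = FALSE)
  if (!is.null(registry) && !file.exists(registry))
    stop(sprintf("registry file '%s' does not exist", registry), call. = FALSE)
  structure(list(output_dir = output_dir, registry = registry,
                 preset = preset, mode = mode, spec = spec, config = config,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
  invisible(NULL)
}

pipeline_modes <- function(mode) if (mode == "both") c("age", "full") else mode

#' Run the full analysis pipeline
#'
#' Executes simulate (when a preset is configured), filter, recode, fit,
#' summarise, and export, writing every artifact under the configured output
#' directory: the registry (if simulated), exclusion ledger(s), retained
#' draws, convergence diagnostics, risk and risk-difference surfaces, the
#' figure set, and `manifest.json` recording the seed, configuration, and
#' MD5 checksum of every artifact.
#'
#' @param config a `run_config`.
#' @param quiet suppress stage logging.
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  add <- function(path) artifacts <<- c(artifacts, path)

  if (!is.null(config$preset)) {
    params <- config$preset
    if (is.character(params)) params <- read_generator_params(params)
    registry <- generate_registry(params, config$seed)
    stage_log(quiet, "simulate: %d records", nrow(registry))
    add(write_registry(registry, file.path(out, "registry.csv")))
  } else {
    registry <- read_registry(config$registry)
    stage_log(quiet, "load: %d records from %s", nrow(registry),
              config$registry)
  }

  surfaces <- list()
  manifest_fits <- list()
  for (mode in pipeline_modes(config$mode)) {
    filt <- apply_exclusions(registry, mode)
    stage_log(quiet, "filter[%s]: %d in, %d kept", mode,
              attr(filt$ledger, "input"), attr(filt$ledger, "output"))
    add(write_ledger(filt$ledger, file.path(out, sprintf("ledger_%s.csv", mode))))
    frame <- recode_cohort(filt$cohort)
    spec <- config$spec
    spec$adjustment <- mode
    draws <- sample_posterior(frame, spec = spec, config = config$config)
    stage_log(quiet, "fit[%s]: %d kept draws x %d chains", mode,
              draws$iterations_kept, config$config$chains)
    add(draws_long(draws, file.path(out, sprintf("draws_%s.csv", mode))))
    diag <- diagnostics(draws)
    add_path <- file.path(out, sprintf("diagnostics_%s.csv", mode))
    write.csv(diag, add_path, row.names = FALSE)
    add(add_path)
    bad <- diag$rhat[is.finite(diag$rhat)] > 1.1
    if (any(bad))
      warning(sprintf("%d parameter(s) with split R-hat > 1.1 in %s fit",
                      sum(bad), mode), call. = FALSE)
    surf <- risk_surface(draws)
    add(write_surface(surf, file.path(out, sprintf("risk_surface_%s.csv", mode))))
    rd <- risk_difference_surface(surf)
    add(write_surface(rd, file.path(out, sprintf("rd_surface_%s.csv", mode))))
    surfaces[[paste0("risk_", mode)]] <- surf
    surfaces[[paste0("rd_", mode)]] <- rd
    manifest_fits[[mode]] <- list(max_rhat = max(diag$rhat, na.rm = TRUE),
                                  records = nrow(frame))
    tp <- trace_plot(draws)
    f <- file.path(out, sprintf("traces_%s.png", mode))
    save_png(tp, f, width = 8, height = 6)
    add(f)
  }
  if (config$mode == "both") {
    cmp <- compare_adjustments(surfaces$rd_age, surfaces$rd_full)
    f <- file.path(out, "rd_adjustment_comparison.csv")
    write.csv(cmp, f, row.names = FALSE)
    add(f)
  }
  figs <- export_figures(surfaces, file.path(out, "figures"))
  artifacts <- c(artifacts, figs)
  stage_log(quiet, "export: %d figure files", length(figs))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ptbhier")),
    seed = config$seed, mode = config$mode,
    mcmc = unclass(config$config),
    spec = unclass(config$spec)[c("knots", "mu_var", "tau_shape", "tau_rate",
                                  "beta_var", "tau_structure")],
    fits = manifest_fits,
    artifacts = as.list(setNames(unname(tools::md5sum(artifacts)),
                                 basename(artifacts))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Staged pipeline commands
#'
#' File-to-file stages matching the pipeline: each runs standalone on the
#' previous stage's outputs, so any two stages communicate only through
#' documented CSV/YAML/JSON formats. These back the command-line interface
#' in `inst/scripts/ptbhier-pipeline.R`.
#'
#' @param params_path YAML of generator parameters (or `NULL` for the
#'   calibrated descriptive-table preset).
#' @param registry_path registry CSV path.
#' @param out output file or directory path.
#' @param mode `"age"` or `"full"`.
#' @param seed integer seed.
#' @param frame_path,draws_dir,surface_dir intermediate file locations.
#' @param spec,config model and MCMC settings.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
pipeline_simulate <- function(out, params_path = NULL, seed = 1L) {
  params <- if (is.null(params_path)) make_table1_preset()
  else read_generator_params(params_path)
  write_registry(generate_registry(params, seed), out)
}

#' @rdname pipeline_stages
#' @export
pipeline_filter <- function(registry_path, out, mode = "age") {
  registry <- read_registry(registry_path)
  filt <- apply_exclusions(registry, mode)
  write_registry(filt$cohort, out)
  write_ledger(filt$ledger,
               file.path(dirname(out), sprintf("ledger_%s.csv", mode)))
  invisible(filt$ledger)
}

#' @rdname pipeline_stages
#' @export
pipeline_fit <- function(registry_path, out, mode = "age",
                         spec = model_spec(), config = mcmc_config()) {
  cohort <- read_registry(registry_path)
  frame <- recode_cohort(cohort)
  spec$adjustment <- mode
  draws <- sample_posterior(frame, spec = spec, config = config)
  draws_long(draws, out)
  write.csv(diagnostics(draws),
            file.path(dirname(out), sprintf("diagnostics_%s.csv", mode)),
            row.names = FALSE)
  invisible(draws)
}

#' @rdname pipeline_stages
#' @export
pipeline_report <- function(ledger) {
  if (is.character(ledger)) {
    df <- read.csv(ledger, stringsAsFactors = FALSE)
    input <- df$remaining[1] + df$removed[1]
    for (r in seq_len(nrow(df) - 1))
      if (df$remaining[r + 1] + df$removed[r + 1] != df$remaining[r])
        stop("ledger rows are not conservative", call. = FALSE)
    ledger <- structure(df, input = input,
                        output = df$remaining[nrow(df)], mode = "age",
                        class = c("exclusion_ledger", "data.frame"))
  }
  missing_rules <- grep("^missing", ledger$rule, value = TRUE)
  pct <- exclusion_percent(ledger, missing_rules)
  cat(sprintf(
    "cumulative exclusion for missing fields: n = %s of %s (%.1f%%)\n",
    format(sum(ledger$removed[ledger$rule %in% missing_rules]), big.mark = ","),
    format(attr(ledger, "input"), big.mark = ","), pct))
  invisible(pct)
}
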