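# Figure export: composite risk and risk-difference figures plus per-group
# interval panels.

surface_plot_data <- function(surface, drop_floor = TRUE) {
  d <- as.data.frame(surface)
  if (drop_floor && "below_floor" %in% names(d)) d <- d[!d$below_floor, ]
  d
}

risk_panel <- function(d, title) {
  ggplot2::ggplot(d, ggplot2::aes(x = education, y = mean,
                                  colour = ethnicity)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = title, x = "years of completed education",
                  y = "P(preterm birth)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

group_risk_panel <- function(d, group, title) {
  ggplot2::ggplot(d[d$ethnicity == group, ],
                  ggplot2::aes(x = education, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower95, ymax = upper95,
                                      fill = nativity), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(colour = nativity)) +
    ggplot2::labs(title = paste(group, "-", title),
                  x = "years of completed education", y = "P(preterm birth)") +
    ggplot2::theme_minimal()
}

group_rd_panel <- function(d, group, title) {
  ggplot2::ggplot(d[d$ethnicity == group, ],
                  ggplot2::aes(x = education, y = mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower95, ymax = upper95),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste(group, "-", title),
                  x = "years of completed education",
                  y = "risk difference (native - foreign born)") +
    ggplot2::theme_minimal()
}

save_png <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 150)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Export the figure set for fitted surfaces
#'
#' Writes the composite absolute-risk figure (one panel per nativity class
#' and adjustment mode), the composite risk-difference figure (one panel per
#' adjustment mode), and per-group interval panels: for each adjustment mode
#' one risk plot and one RD plot per ethnic group. With both modes supplied
#' that is 2 composite figures and 7 x 2 x 2 = 28 per-group panels. Output
#' is deterministic given the surfaces.
#'
#' @param surfaces named list with elements among `risk_age`, `risk_full`
#'   (`risk_surface` objects) and `rd_age`, `rd_full` (`rd_surface`
#'   objects); at least one risk surface is required.
#' @param destination directory (created if needed).
#' @return character vector of the files written.
#' @export
export_figures <- function(surfaces, destination) {
  risk_keys <- intersect(c("risk_age", "risk_full"), names(surfaces))
  rd_keys <- intersect(c("rd_age", "rd_full"), names(surfaces))
  if (!length(risk_keys))
    stop("no risk surfaces supplied; nothing to export", call. = FALSE)
  for (kk in c(risk_keys, rd_keys))
    if (!nrow(surfaces[[kk]]))
      stop(sprintf("surface '%s' is empty", kk), call. = FALSE)
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  mode_label <- c(risk_age = "age-adjusted", risk_full = "fully adjusted",
                  rd_age = "age-adjusted", rd_full = "fully adjusted")
  panels <- list()
  for (kk in risk_keys) {
    d <- surface_plot_data(surfaces[[kk]])
    for (nat in unique(d$nativity))
      panels[[length(panels) + 1L]] <-
        risk_panel(d[d$nativity == nat, ], paste(nat, mode_label[kk], sep = ", "))
  }
  f <- file.path(destination, "risk_panels.png")
  save_png(patchwork::wrap_plots(panels, ncol = 2), f,
           width = 10, height = 4 * ceiling(length(panels) / 2))
  files <- c(files, f)
  if (length(rd_keys)) {
    rdp <- lapply(rd_keys, function(kk) {
      d <- as.data.frame(surfaces[[kk]])
      ggplot2::ggplot(d, ggplot2::aes(x = education, y = mean,
                                      colour = ethnicity)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::geom_line() +
        ggplot2::labs(title = mode_label[kk],
                      x = "years of completed education",
                      y = "risk difference (native - foreign born)",
                      colour = NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(legend.position = "bottom")
    })
    f <- file.path(destination, "rd_panels.png")
    save_png(patchwork::wrap_plots(rdp, ncol = 2), f, width = 10, height = 4.5)
    files <- c(files, f)
  }
  slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  for (kk in risk_keys) {
    d <- surface_plot_data(surfaces[[kk]])
    for (g in unique(d$ethnicity)) {
      f <- file.path(destination, sprintf("risk_%s_%s.png",
                                          sub("risk_", "", kk), slug(g)))
      save_png(group_risk_panel(d, g, mode_label[kk]), f)
      files <- c(files, f)
    }
  }
  for (kk in rd_keys) {
    d <- as.data.frame(surfaces[[kk]])
    for (g in unique(d$ethnicity)) {
      f <- file.path(destination, sprintf("rd_%s_%s.png",
                                          sub("rd_", "", kk), slug(g)))
      save_png(group_rd_panel(d, g, mode_label[kk]), f)
      files <- c(files, f)
    }
  }
  files
}
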