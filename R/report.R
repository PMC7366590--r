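#' Render the validation report
#'
#' Writes the standard tables and figures for a completed validation run to
#' `out_dir`: CSV tables for the three aggregation modes, the band
#' fractions, the summary tests and the cap scenarios, plus figures — mean
#' and median error heatmaps over `(t_pred, t_data)`, the median error vs
#' `t_data` plot with IQR bars and the fitted regression line, and a
#' histogram of `ln_ratio` with its normal overlay.
#'
#' @param cells `validation_cells` from [rolling_validate()] or
#'   [dual_tmax_run()] (cap attributes required for the scenario table; it
#'   is skipped with a message when absent, e.g. for merged cells).
#' @param out_dir output directory (created if needed).
#' @param fig_format `"png"` or `"svg"`.
#' @return invisibly, the paths written.
#' @export
render_report <- function(cells, out_dir, fig_format = c("png", "svg")) {
  fig_format <- match.arg(fig_format)
  if (!nrow(as.data.frame(cells)))
    stop("no validation cells: nothing to report", call. = FALSE)
  samples <- error_samples(cells)
  if (!nrow(samples))
    stop("no cell has observed BI: nothing to report", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  by_cell <- aggregate_errors(samples, "per_tpred_tdata")
  by_tdata <- aggregate_errors(samples, "per_tdata")
  wr(by_cell, "errors_per_tpred_tdata.csv")
  wr(by_tdata, "errors_per_tdata.csv")
  wr(aggregate_errors(samples, "none"), "errors_unaggregated.csv")
  wr(band_fractions(samples), "band_fractions.csv")
  tests <- summary_tests(samples)
  wr(data.frame(
    statistic = c("mean_ln_ratio", "ci_low", "ci_high", "t_test_p",
                  "prob_underprediction", "binom_ci_low", "binom_ci_high",
                  "binom_p", "regression_slope", "regression_se",
                  "regression_p", "n_samples"),
    value = c(tests$t_test$mean, tests$t_test$ci, tests$t_test$p,
              tests$binomial$prob_underprediction, tests$binomial$ci,
              tests$binomial$p, tests$regression$slope, tests$regression$se,
              tests$regression$p, tests$t_test$n)), "summary_tests.csv")
  if (!is.null(attr(cells, "min_cap")) && !is.null(attr(cells, "max_cap"))) {
    wr(scenario_caps(cells), "cap_scenarios.csv")
  } else message("cells carry no cap attributes; scenario table skipped")

  dev <- if (fig_format == "png")
    function(p) grDevices::png(p, width = 1400, height = 1000, res = 150)
  else function(p) grDevices::svg(p, width = 9, height = 6.5)
  fig <- function(name, plot) {
    p <- file.path(out_dir, paste0(name, ".", fig_format))
    dev(p); print(plot); grDevices::dev.off()
    paths <<- c(paths, p)
  }

  fig("heatmap_mean_error", ggplot2::ggplot(by_cell,
      ggplot2::aes(x = .data$t_data, y = .data$t_pred, fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean error", trans = "log10") +
    ggplot2::labs(x = "t_data (months of own data)",
                  y = "t_pred (predicted month)",
                  title = "Mean error ratio per (t_pred, t_data)") +
    ggplot2::theme_minimal())
  fig("heatmap_median_error", ggplot2::ggplot(by_cell,
      ggplot2::aes(x = .data$t_data, y = .data$t_pred, fill = .data$median)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "median error", trans = "log10") +
    ggplot2::labs(x = "t_data (months of own data)",
                  y = "t_pred (predicted month)",
                  title = "Median error ratio per (t_pred, t_data)") +
    ggplot2::theme_minimal())
  fig("error_vs_tdata", ggplot2::ggplot(by_tdata,
      ggplot2::aes(x = .data$t_data, y = .data$median)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                           width = 0.3, color = "grey55") +
    ggplot2::geom_point(color = "darkorange") +
    ggplot2::geom_smooth(
      data = samples,
      ggplot2::aes(x = .data$t_data, y = .data$error_ratio),
      method = "lm", formula = y ~ x, se = FALSE, color = "steelblue") +
    ggplot2::coord_cartesian(
      ylim = c(0, stats::quantile(samples$error_ratio, 0.99))) +
    ggplot2::labs(x = "t_data (months of own data)",
                  y = "error ratio",
                  title = "Median error ratio by t_data (bars: IQR; line: OLS on samples)") +
    ggplot2::theme_minimal())
  fig("ln_ratio_histogram", ggplot2::ggplot(samples,
      ggplot2::aes(x = .data$ln_ratio)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 50, fill = "steelblue", color = "white") +
    ggplot2::stat_function(
      fun = stats::dnorm,
      args = list(mean = mean(samples$ln_ratio),
                  sd = stats::sd(samples$ln_ratio)),
      color = "darkorange", linewidth = 1) +
    ggplot2::labs(x = "ln(observed / predicted)", y = "density",
                  title = "Distribution of signed log errors") +
    ggplot2::theme_minimal())
  invisible(paths)
}
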