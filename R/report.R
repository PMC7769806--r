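round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Lorenz-curve plot for one year
#'
#' Draws the Lorenz curves of several resources against one allocation base
#' for a single year, with the diagonal as the perfect-equality reference.
#'
#' @inheritParams gini_table
#' @param year Year to plot.
#' @param base `"population"` or `"area"`.
#' @return A ggplot object.
#' @export
lorenz_plot <- function(panel, year, resources = panel_inputs(panel),
                        base = c("population", "area")) {
  base <- match.arg(base)
  curves <- dplyr::bind_rows(lapply(resources, function(r) {
    pts <- lorenz_points(make_shares(panel, year, r, base))
    pts$resource <- r
    pts
  }))
  ggplot2::ggplot(curves, ggplot2::aes(.data$cum_base, .data$cum_resource,
                                       colour = .data$resource)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste0("Cumulative share of ", base),
      y = "Cumulative share of resource",
      title = paste0("Lorenz curves, ", year, " (by ", base, ")")) +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline and write report tables
#'
#' One reproducible entry point over the whole package: equity tables
#' (densities, Gini, Theil decompositions), the DEA slack table for a
#' chosen year, and the Malmquist summaries, each written as a UTF-8 CSV
#' into `out_dir`. Numeric rounding is applied only here, at the report
#' layer; all computation upstream is full precision. Given the same panel
#' (or synthetic spec with the same seed) and configuration, outputs are
#' byte-identical across runs.
#'
#' @param panel A [resource_panel()], or `NULL` to generate one.
#' @param spec A [panel_spec()] used when `panel` is `NULL` (exactly one of
#'   the two must be supplied).
#' @param out_dir Output directory (created if needed).
#' @param analyses Subset of `c("equity", "dea", "malmquist")`.
#' @param bases Allocation bases for the equity tables.
#' @param dea_year Year for the DEA slack table (default: last panel year).
#' @param rts Returns-to-scale assumption for the DEA radial stage.
#' @param equity_digits,dea_digits Report rounding (4 and 3 by default).
#' @param lorenz_plots Also write one Lorenz plot per base for `dea_year`
#'   (PNG, requires a functioning graphics device).
#'
#' @return Invisibly, a named character vector of the files written. A
#'   `manifest.yaml` recording the configuration, the solver backend and
#'   its tolerances, and the package version is always written.
#' @export
run_report <- function(panel = NULL, spec = NULL, out_dir,
                       analyses = c("equity", "dea", "malmquist"),
                       bases = c("population", "area"),
                       dea_year = NULL, rts = c("VRS", "CRS"),
                       equity_digits = 4, dea_digits = 3,
                       lorenz_plots = FALSE) {
  if (is.null(panel) == is.null(spec)) {
    stop("supply exactly one of `panel` or `spec`", call. = FALSE)
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  rts <- match.arg(rts)
  if (is.null(panel)) panel <- gen_panel(spec)
  stopifnot(inherits(panel, "resource_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dea_year)) dea_year <- max(panel$year)

  files <- character(0)
  emit <- function(df, name, digits) {
    path <- file.path(out_dir, name)
    readr::write_csv(round_df(df, digits), path, progress = FALSE)
    files[[name]] <<- path
    message("wrote ", path)
    path
  }

  if ("equity" %in% analyses) {
    emit(density_table(panel), "density.csv", equity_digits)
    emit(gini_table(panel, bases = bases), "gini.csv", equity_digits)
    for (b in bases) {
      emit(theil_table(panel, base = b), paste0("theil_", b, ".csv"),
           equity_digits)
    }
    if (lorenz_plots) {
      for (b in bases) {
        f <- file.path(out_dir, paste0("lorenz_", dea_year, "_", b, ".png"))
        ggplot2::ggsave(f, lorenz_plot(panel, dea_year, base = b),
                        width = 5, height = 5, dpi = 150)
        files[[basename(f)]] <- f
      }
    }
  }

  if ("dea" %in% analyses) {
    eff <- dea_efficiency(panel, dea_year, rts = rts)
    eff$lambda <- NULL
    emit(eff, paste0("dea_slacks_", dea_year, ".csv"), dea_digits)
  }

  if ("malmquist" %in% analyses) {
    mq <- malmquist(panel)
    smry <- malmquist_summary(mq, digits = dea_digits)
    emit(mq, "malmquist_components.csv", dea_digits)
    emit(smry$by_period, "malmquist_by_year.csv", dea_digits)
    emit(smry$by_dmu, "malmquist_by_dmu.csv", dea_digits)
    emit(smry$frequency, "malmquist_frequency.csv", dea_digits)
  }

  manifest <- list(
    package = "equidea",
    version = as.character(utils::packageVersion("equidea")),
    analyses = analyses, bases = bases, dea_year = dea_year, rts = rts,
    equity_digits = equity_digits, dea_digits = dea_digits,
    synthetic = !is.null(spec),
    seed = if (!is.null(spec)) spec$seed else NA,
    solver = list(backend = "boot::simplex", pivot_eps = 1e-10,
                  rts_tol = 1e-6),
    n_dmus = length(unique(panel$dmu)),
    years = as.character(sort(unique(panel$year)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  files[["manifest.yaml"]] <- file.path(out_dir, "manifest.yaml")
  invisible(files)
}
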