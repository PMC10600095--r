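#' Read a flow-specification CSV
#'
#' Expected columns: `scenario_id`, `source`, `target`, `quantity`
#' (green tonnes/yr).
#'
#' @param path CSV file.
#' @return A validated `flow_table`.
#' @export
read_flow_csv <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE)
  build_scenario_flows(sp)
}

#' Write a scenario result to a directory
#'
#' Writes `results_<scenario>.csv` (year, component, scope, value_tco2e),
#' `summary_<scenario>.json` (net and cumulative series plus the constant
#' credits) and, if a flow table is supplied, a Sankey JSON.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if needed).
#' @param flow_table Optional `flow_table` for the Sankey export.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, flow_table = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- result$config$scenario_id
  readr::write_csv(result$table,
                   file.path(dir, paste0("results_", sid, ".csv")))
  jsonlite::write_json(
    list(config = unclass(result$config),
         credits = result$credits,
         annual = as.data.frame(result$annual)),
    file.path(dir, paste0("summary_", sid, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(flow_table)) {
    sankey_json(flow_table, file.path(dir, paste0("sankey_", sid, ".json")))
  }
  invisible(dir)
}

#' Plot annual or cumulative net GWP trajectories
#'
#' @param results Named list of `scenario_result`s (e.g. from
#'   [run_all_scenarios()]).
#' @param what One of `"net_s13"`, `"net_s14"`, `"cumulative_s14"`.
#' @return A ggplot object; values are shown in Mt CO2e.
#' @export
plot_trajectories <- function(results, what = c("net_s14", "net_s13",
                                                "cumulative_s14")) {
  what <- match.arg(what)
  df <- purrr::imap(results, function(r, id) {
    dplyr::mutate(r$annual, scenario = id)
  }) |> purrr::list_rbind()
  lab <- c(net_s13 = "annual net Scope 1-3",
           net_s14 = "annual net Scope 1-4",
           cumulative_s14 = "cumulative net Scope 1-4")[[what]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year,
                                   y = .data[[what]] / 1e6,
                                   colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = paste(lab, "(Mt CO2e)"),
                  colour = "scenario") +
    ggplot2::theme_minimal()
}
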