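#' Validate an emission-factor inventory
#'
#' An inventory holds per-process, per-scope CO2e factors. Several rows may
#' share a `process_id` and scope (e.g. the resin burden of panel mills is
#' kept as its own Scope 3 row, tagged `decarb_sector = "resins"`, so the
#' resin share stays inspectable); they are summed at evaluation time.
#'
#' @param df Data frame with columns `process_id`, `scope` (1, 2 or 3),
#'   `value_kgco2e` (>= 0, per declared unit), `unit` (one of
#'   `"green tonne"`, `"m3 product"`, `"tonne product"`, `"MJ delivered"`,
#'   `"tkm"`) and `decarb_sector`.
#' @return The validated inventory as a tibble.
#' @export
emission_inventory <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("process_id", "scope", "value_kgco2e", "unit", "decarb_sector")
  stopifnot(all(need %in% names(df)))
  if (!all(df$scope %in% 1:3)) {
    stop("inventory scope must be 1, 2 or 3", call. = FALSE)
  }
  if (any(df$value_kgco2e < 0)) {
    stop("emission factors must be non-negative", call. = FALSE)
  }
  ok_units <- c("green tonne", "m3 product", "tonne product", "MJ delivered", "tkm")
  if (!all(df$unit %in% ok_units)) {
    stop("unknown factor unit(s): ",
         paste(setdiff(unique(df$unit), ok_units), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Validate a decarbonisation schedule
#'
#' A schedule is a step function per sector: the multiplier applied to that
#' sector's emission factors is 1 before the first step year and thereafter
#' the value of the most recent step. Multipliers must be in `[0, 1]` and
#' non-increasing in year (industry does not re-carbonise).
#'
#' @param df Data frame with columns `sector`, `step_year`, `multiplier`.
#' @return The validated schedule as a tibble, ordered by sector and year.
#' @export
decarb_schedule <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("sector", "step_year", "multiplier") %in% names(df)))
  if (any(df$multiplier < 0 | df$multiplier > 1)) {
    stop("multipliers must lie in [0, 1]", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$sector, .data$step_year)
  bad <- df |>
    dplyr::group_by(.data$sector) |>
    dplyr::summarise(ok = !is.unsorted(rev(.data$multiplier)), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("multiplier must be non-increasing in year for sector(s): ",
         paste(bad$sector, collapse = ", "), call. = FALSE)
  }
  df
}

#' Decarbonisation multiplier for a sector-year
#'
#' @param sector Sector tag present in the schedule.
#' @param year Calendar year (vectorised).
#' @param schedule A [decarb_schedule()] table.
#' @return Numeric multiplier(s) in `[0, 1]`; 1 before the first step.
#' @export
#' @examples
#' sch <- decarb_schedule(data.frame(
#'   sector = "electricity", step_year = c(2030, 2040, 2050),
#'   multiplier = c(0.6, 0.3, 0)
#' ))
#' decarb_multiplier("electricity", c(2025, 2035, 2045), sch)
decarb_multiplier <- function(sector, year, schedule) {
  rows <- schedule[schedule$sector == sector, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("unknown decarbonisation sector: ", sector, call. = FALSE)
  }
  rows <- rows[order(rows$step_year), , drop = FALSE]
  vapply(year, function(y) {
    past <- rows$step_year <= y
    if (!any(past)) 1 else rows$multiplier[[max(which(past))]]
  }, numeric(1))
}

# sum of factor * multiplier for one process node and scope, kg CO2e per unit
scoped_factor <- function(inv, process_id, year, schedule,
                          required_unit = "green tonne") {
  rows <- inv[inv$process_id == process_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("missing emission factor for process: ", process_id, call. = FALSE)
  }
  off <- rows$unit != required_unit
  if (any(off)) {
    stop(sprintf("unit mismatch for process '%s': factor unit '%s', flows in '%s'",
                 process_id, rows$unit[off][[1]], required_unit), call. = FALSE)
  }
  rows$mult <- vapply(rows$decarb_sector, decarb_multiplier, numeric(1),
                      year = year, schedule = schedule)
  rows
}

#' Scope 1-3 process emissions of a flow table for one year
#'
#' For every process node the throughput (green tonnes/yr, see
#' [process_throughput()]) is multiplied by each matching inventory factor
#' and that factor's decarbonisation multiplier for `year`. Results are
#' reported per value-chain component and scope, in tonnes CO2e/yr.
#'
#' @param table A `flow_table`.
#' @param inv An [emission_inventory()].
#' @param year Calendar year.
#' @param schedule A [decarb_schedule()].
#' @return Tibble with columns `year`, `component`, `scope` (character
#'   `"1"`, `"2"`, `"3"`), `value_tco2e`.
#' @export
component_process_emissions <- function(table, inv, year, schedule) {
  thr <- process_throughput(table)
  thr <- thr[thr$throughput > 0, , drop = FALSE]
  if (nrow(thr) == 0) {
    return(tibble::tibble(year = integer(), component = character(),
                          scope = character(), value_tco2e = numeric()))
  }
  rows <- purrr::map2(thr$process_id, thr$throughput, function(p, q) {
    f <- scoped_factor(inv, p, year, schedule)
    tibble::tibble(
      process_id = p,
      scope = as.character(f$scope),
      value_tco2e = q * f$value_kgco2e * f$mult / 1000
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(thr[, c("process_id", "component")], by = "process_id")
  rows |>
    dplyr::group_by(.data$component, .data$scope) |>
    dplyr::summarise(value_tco2e = sum(.data$value_tco2e), .groups = "drop") |>
    dplyr::mutate(year = as.integer(year)) |>
    dplyr::select("year", "component", "scope", "value_tco2e")
}

#' Emissions from import-volume changes versus business-as-usual
#'
#' Embodied emissions of business-as-usual imports are set to zero by the
#' consequential convention; only the *change* in import volumes carries
#' emissions. Each delta (green-tonne-equivalent product units/yr) is
#' multiplied by a per-category processing factor (equal to the domestic
#' chain burden per unit product) plus a transport factor, each under its
#' own decarbonisation sector. Negative deltas (imports falling) yield
#' negative emissions.
#'
#' Inventory rows are looked up as `import_processing_<category>` and
#' `import_transport_<category>`.
#'
#' @param deltas Output of [derive_import_deltas()].
#' @param inv An [emission_inventory()].
#' @param year Calendar year.
#' @param schedule A [decarb_schedule()].
#' @return Tibble with columns `year`, `component`
#'   (`"change_in_import_emissions"`), `scope` (`"4"`), `value_tco2e`.
#' @export
import_delta_emissions <- function(deltas, inv, year, schedule) {
  active <- deltas[deltas$import_delta != 0, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(active))) {
    cat_i <- active$category[[i]]
    d <- active$import_delta[[i]]
    for (kind in c("import_processing_", "import_transport_")) {
      f <- scoped_factor(inv, paste0(kind, cat_i), year, schedule)
      total <- total + d * sum(f$value_kgco2e * f$mult) / 1000
    }
  }
  tibble::tibble(year = as.integer(year),
                 component = "change_in_import_emissions",
                 scope = "4", value_tco2e = total)
}
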