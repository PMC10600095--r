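#' Scenario run configuration
#'
#' Bundles the run settings for [run_scenario()]. The study runs from
#' `start_year` to `end_year`; before `implementation_year` the
#' business-as-usual wood flow applies, from it onward the scenario flow
#' applies. Study year 1 is the year after `start_year`, so the delayed
#' implementations "year 5" and "year 10" map to 2027 and 2032 by
#' default.
#'
#' @param scenario_id One of `"bau"`, `"cascading"`, `"circular"`,
#'   `"cascading_circular"` (any id present in the input bundle).
#' @param start_year,end_year Study period bounds (defaults 2022, 2050).
#' @param implementation_year Calendar year the scenario flow replaces
#'   business-as-usual; must lie in `[start_year, end_year]`.
#' @param harvest Annual harvest, green tonnes/yr.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario_id, start_year = 2022, end_year = 2050,
                            implementation_year = 2027, harvest = 9.5e6) {
  if (!(start_year <= implementation_year && implementation_year <= end_year)) {
    stop("need start_year <= implementation_year <= end_year", call. = FALSE)
  }
  structure(list(scenario_id = scenario_id, start_year = start_year,
                 end_year = end_year,
                 implementation_year = implementation_year,
                 harvest = harvest),
            class = "scenario_config")
}

# per-category production carbon inflow (t C/yr) of a flow table,
# excluding nothing: fuelwood is included and handled by its zero
# half-life (immediate release)
production_carbon <- function(table, convention) {
  po <- product_output(table)
  tibble::tibble(category = po$category,
                 inflow_tc = green_tonnes_to_carbon(po$production, convention))
}

#' Run one wood-use scenario over the study period
#'
#' Assembles, per year, the Scope 1-3 process emissions of the active flow
#' table, the import-change emissions of the deltas versus
#' business-as-usual, the annualised HWP storage-change credit, the
#' avoided-harvest credit driven by recycled-MDF production, and the fuel
#' and construction substitution credits. For the `bau` scenario the
#' HWP-change, import-change and avoided-harvest entries are zero by
#' construction (the consequential baseline convention).
#'
#' Substitution credits are computed on total consumption, which is held
#' constant across scenarios by import rebalancing, except woodfuel whose
#' net consumption falls in circular scenarios.
#'
#' @param config A [scenario_config()].
#' @param inputs An input bundle, see [make_paper_like_fixture()].
#' @return A `scenario_result`: list with `table` (tibble `year`,
#'   `component`, `scope`, `value_tco2e`), `annual` (tibble `year`,
#'   `net_s13`, `net_s14`, `cumulative_s14`), `deltas`, `credits`
#'   (the constant annual credit values) and `config`.
#'
#'   `scope` is `"1"`, `"2"`, `"3"` for process emissions, `"4"` for
#'   avoided emissions (substitution, reduced harvest, import change) and
#'   `"storage"` for the domestic HWP stock change, which is a biogenic
#'   flux inside the value-chain boundary: `net_s13` sums scopes 1-3 plus
#'   storage, and `net_s14 = net_s13 +` the Scope 4 components, exactly.
#'   `cumulative_s14` accrues from the year after `start_year` on a
#'   baseline of zero (a 28-step accumulation for the default period).
#' @export
#' @examples
#' fx <- make_paper_like_fixture()
#' res <- run_scenario(scenario_config("bau"), fx)
#' head(res$annual)
run_scenario <- function(config, inputs) {
  sid <- config$scenario_id
  if (!sid %in% names(inputs$flows)) {
    stop("scenario '", sid, "' not present in inputs", call. = FALSE)
  }
  years <- config$start_year:config$end_year
  impl <- config$implementation_year
  bau_t <- scale_to_harvest(inputs$flows$bau, config$harvest)
  scen_t <- scale_to_harvest(inputs$flows[[sid]], config$harvest)
  conv <- inputs$convention
  active <- function(y) if (y < impl) bau_t else scen_t

  # ---- Scope 1-3 process emissions -------------------------------------
  rows <- purrr::map(years, function(y) {
    component_process_emissions(active(y), inputs$inventory, y,
                                inputs$schedule)
  }) |> purrr::list_rbind()

  # ---- import deltas and their emissions -------------------------------
  deltas <- derive_import_deltas(scen_t, bau_t,
                                 woodfuel_replacement =
                                   inputs$woodfuel_replacement)
  imp_rows <- purrr::map(years, function(y) {
    if (y < impl) {
      tibble::tibble(year = as.integer(y),
                     component = "change_in_import_emissions",
                     scope = "4", value_tco2e = 0)
    } else {
      import_delta_emissions(deltas, inputs$inventory, y, inputs$schedule)
    }
  }) |> purrr::list_rbind()

  # ---- HWP storage-change credit ---------------------------------------
  window <- inputs$hwp_window %||% 50
  pool_years <- config$start_year:(impl + window)
  prod_of <- function(tab) production_carbon(tab, conv)
  prod_series <- function(path_table) {
    purrr::map(pool_years, function(y) {
      dplyr::mutate(prod_of(path_table(y)), year = as.integer(y), .before = 1)
    }) |> purrr::list_rbind()
  }
  scen_path <- function(y) active(min(y, config$end_year))
  bau_path <- function(y) bau_t
  hwp_credit <- storage_change_credit(
    stock_series(prod_series(scen_path), inputs$half_lives),
    stock_series(prod_series(bau_path), inputs$half_lives),
    window = window, co2_per_c = conv$co2_per_c
  )
  hwp_rows <- tibble::tibble(
    year = as.integer(years),
    component = "change_in_uk_hwp_c_storage",
    scope = "storage",
    value_tco2e = dplyr::if_else(years >= impl, hwp_credit, 0)
  )

  # ---- avoided-harvest credit (recycled-MDF scenarios) -----------------
  scen_prod <- product_output(scen_t)
  rmdf_gt <- scen_prod$production[scen_prod$category == "recycled_mdf"]
  rmdf_gt <- if (length(rmdf_gt) == 0) 0 else rmdf_gt
  avoided <- avoided_harvest_credit(
    recycled_mdf_volume = rmdf_gt / conv$gt_per_m3_product,
    convention = conv, estate = inputs$estate,
    study_years = inputs$study_window %||% 28
  )
  forest_rows <- tibble::tibble(
    year = as.integer(years),
    component = "avoided_reduced_harvest",
    scope = "4",
    value_tco2e = dplyr::if_else(years >= impl, avoided$credit_tco2e, 0)
  )

  # ---- substitution credits --------------------------------------------
  bau_prod <- product_output(bau_t)
  bau_of <- function(cat) bau_prod$production[bau_prod$category == cat]
  fuel_cons_delta <- deltas$consumption_delta[deltas$category == "woodfuel"]
  fuel_cons_delta <- if (length(fuel_cons_delta) == 0) 0 else fuel_cons_delta
  subst_rows <- purrr::map(years, function(y) {
    fuel_gt <- bau_of("woodfuel") + if (y >= impl) fuel_cons_delta else 0
    fuel <- fuel_substitution_credit(fuel_gt, inputs$substitution, y,
                                     inputs$schedule)
    constr <- construction_substitution_credit(
      green_tonnes_to_20mc(bau_of("carcassing"), conv),
      inputs$substitution, y, inputs$schedule
    )
    tibble::tibble(year = as.integer(y),
                   component = "avoided_product_substitution",
                   scope = "4", value_tco2e = fuel + constr)
  }) |> purrr::list_rbind()

  table <- dplyr::bind_rows(rows, imp_rows, hwp_rows, forest_rows, subst_rows) |>
    dplyr::arrange(.data$year, .data$component, .data$scope)

  annual <- table |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      net_s13 = sum(.data$value_tco2e[.data$scope %in% c("1", "2", "3",
                                                         "storage")]),
      scope4 = sum(.data$value_tco2e[.data$scope == "4"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      net_s14 = .data$net_s13 + .data$scope4,
      cumulative_s14 = cumsum(dplyr::if_else(.data$year == config$start_year,
                                             0, .data$net_s14))
    ) |>
    dplyr::select("year", "net_s13", "net_s14", "cumulative_s14")

  structure(list(table = table, annual = annual, deltas = deltas,
                 credits = list(hwp_storage = hwp_credit,
                                avoided_harvest = avoided$credit_tco2e,
                                harvest_reduction_gt =
                                  avoided$harvest_reduction_gt),
                 config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  last <- x$annual[nrow(x$annual), ]
  cat(sprintf("<scenario_result> '%s' %d-%d (implemented %d)\n",
              cfg$scenario_id, cfg$start_year, cfg$end_year,
              cfg$implementation_year))
  cat(sprintf("  net Scope 1-3 %d: %.4g t CO2e/yr\n", last$year, last$net_s13))
  cat(sprintf("  net Scope 1-4 %d: %.4g t CO2e/yr\n", last$year, last$net_s14))
  cat(sprintf("  cumulative net Scope 1-4 by %d: %.4g t CO2e\n",
              last$year, last$cumulative_s14))
  invisible(x)
}

#' Compare two scenario results
#'
#' Percentage comparisons matching the phrasing used for headline results:
#' * `s13_pct_lower`: how much lower scenario `b`'s net Scope 1-3 is than
#'   `a`'s at `year`, `(S13_a - S13_b) / S13_a * 100`.
#' * `s14_pct_larger_reduction`: how much larger `b`'s net Scope 1-4
#'   reduction is than `a`'s at `year`,
#'   `(|net14_b| - |net14_a|) / |net14_a| * 100`; both nets must be
#'   negative (reductions).
#' * `cumulative_pct_larger`: the same ratio on cumulative net Scope 1-4
#'   at the final year.
#'
#' @param a,b `scenario_result`s on the same year axis (`a` is the
#'   reference).
#' @param metric One of the three metric names above.
#' @param year Calendar year (ignored for the cumulative metric).
#' @return A percentage.
#' @export
compare_scenarios <- function(a, b,
                              metric = c("s13_pct_lower",
                                         "s14_pct_larger_reduction",
                                         "cumulative_pct_larger"),
                              year = NULL) {
  metric <- match.arg(metric)
  if (!identical(a$annual$year, b$annual$year)) {
    stop("results are not on the same year axis", call. = FALSE)
  }
  get_at <- function(res, col, y) {
    v <- res$annual[[col]][res$annual$year == y]
    if (length(v) == 0) stop("year ", y, " not in results", call. = FALSE)
    v
  }
  if (metric == "s13_pct_lower") {
    if (is.null(year)) stop("year is required for s13_pct_lower", call. = FALSE)
    ref <- get_at(a, "net_s13", year)
    if (ref == 0) stop("reference net Scope 1-3 is zero; comparison undefined",
                       call. = FALSE)
    return((ref - get_at(b, "net_s13", year)) / ref * 100)
  }
  col <- if (metric == "s14_pct_larger_reduction") "net_s14" else "cumulative_s14"
  y <- if (metric == "s14_pct_larger_reduction") {
    if (is.null(year)) stop("year is required for s14_pct_larger_reduction",
                            call. = FALSE)
    year
  } else {
    max(a$annual$year)
  }
  va <- get_at(a, col, y)
  vb <- get_at(b, col, y)
  if (va >= 0) {
    stop("reference net is not a reduction (>= 0); comparison undefined",
         call. = FALSE)
  }
  (abs(vb) - abs(va)) / abs(va) * 100
}

#' Combine a scenario with an afforestation programme
#'
#' No interaction is modelled between the value-chain scenarios and new
#' planting (the programme's forests are additional and unharvested over
#' the period), so the combined cumulative impact is the exact sum of the
#' two cumulative series.
#'
#' @param result A `scenario_result`.
#' @param afforestation Output of [afforestation_series()] covering the
#'   result's years.
#' @return Tibble `year`, `scenario_cumulative`,
#'   `afforestation_cumulative`, `combined_cumulative` (t CO2e).
#' @export
combine_afforestation <- function(result, afforestation) {
  joined <- dplyr::left_join(result$annual,
                             afforestation[, c("year", "cumulative_tco2e")],
                             by = "year") |>
    dplyr::mutate(cumulative_tco2e = dplyr::if_else(
      is.na(.data$cumulative_tco2e), 0, .data$cumulative_tco2e))
  tibble::tibble(
    year = joined$year,
    scenario_cumulative = joined$cumulative_s14,
    afforestation_cumulative = joined$cumulative_tco2e,
    combined_cumulative = joined$cumulative_s14 + joined$cumulative_tco2e
  )
}

#' Run every scenario in an input bundle
#'
#' @param inputs An input bundle.
#' @param implementation_year Shared implementation year.
#' @param ... Passed to [scenario_config()].
#' @return Named list of `scenario_result`s.
#' @export
run_all_scenarios <- function(inputs, implementation_year = 2027, ...) {
  purrr::imap(inputs$flows, function(fl, id) {
    run_scenario(scenario_config(id,
                                 implementation_year = implementation_year,
                                 harvest = inputs$harvest, ...),
                 inputs)
  })
}
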