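#' Carbon and mass conventions
#'
#' Conversion constants used to move between green tonnes of wood, dry
#' mass, carbon and CO2. Freshly harvested softwood is roughly half water
#' by mass, and dry wood is roughly half carbon; both fractions are
#' configurable assumptions.
#'
#' @param moisture_green Water fraction of green mass, in (0, 1).
#' @param carbon_dry Carbon fraction of dry mass, in (0, 1).
#' @param tc_per_m3 Tonnes of carbon per m3 of standing stem volume
#'   (basic density x carbon fraction x biomass expansion factor),
#'   used by the forest-carbon layer.
#' @param gt_per_m3_product Green-tonne-equivalent virgin wood per m3 of
#'   panel product, used to convert recycled-MDF volume to displaced
#'   harvest.
#' @return A `carbon_convention` list (also carrying `co2_per_c = 44/12`,
#'   which is fixed stoichiometry).
#' @export
carbon_convention <- function(moisture_green = 0.5, carbon_dry = 0.5,
                              tc_per_m3 = 0.28, gt_per_m3_product = 1.4) {
  stopifnot(moisture_green > 0, moisture_green < 1,
            carbon_dry > 0, carbon_dry < 1,
            tc_per_m3 > 0, gt_per_m3_product > 0)
  structure(
    list(moisture_green = moisture_green, carbon_dry = carbon_dry,
         co2_per_c = CO2_PER_C, tc_per_m3 = tc_per_m3,
         gt_per_m3_product = gt_per_m3_product),
    class = "carbon_convention"
  )
}

#' Convert green tonnes of wood to tonnes of carbon
#'
#' @param gt Green tonnes.
#' @param convention A [carbon_convention()].
#' @return Tonnes of carbon.
#' @export
green_tonnes_to_carbon <- function(gt, convention = carbon_convention()) {
  gt * (1 - convention$moisture_green) * convention$carbon_dry
}

#' One annual step of a first-order HWP carbon pool
#'
#' The simple-decay (IPCC Tier-1) recurrence with decay constant
#' `k = ln(2) / half_life`:
#' `next = exp(-k) * stock + (1 - exp(-k)) / k * inflow`.
#' The release is the exact mass balance `stock + inflow - next`, so
#' carbon is conserved to machine precision. A non-positive half-life
#' denotes immediate release (fuelwood): the whole inflow is emitted in
#' the same year.
#'
#' @param stock Current stock, t C (>= 0).
#' @param inflow Inflow during the year, t C/yr (>= 0).
#' @param half_life Product half-life, years.
#' @return List with `stock` (next year's stock, t C) and `release`
#'   (t C emitted during the year).
#' @export
#' @examples
#' pool_step(stock = 100, inflow = 10, half_life = 35)
pool_step <- function(stock, inflow, half_life) {
  if (stock < 0 || inflow < 0) {
    stop("stock and inflow must be non-negative", call. = FALSE)
  }
  if (half_life <= 0) {
    return(list(stock = stock, release = inflow))
  }
  k <- log(2) / half_life
  # -expm1(-k) = 1 - exp(-k), accurate for very long half-lives
  nxt <- exp(-k) * stock + (-expm1(-k)) / k * inflow
  list(stock = nxt, release = stock + inflow - nxt)
}

#' Evolve HWP carbon pools for a production series
#'
#' Runs one first-order pool per category over the year axis of
#' `production` and returns per-year, per-category stocks and releases.
#' Pools start empty: stocks are increments relative to the start of the
#' series, which is the quantity the storage-change credit differences
#' out. Imported products and landfill are outside the accounting
#' boundary and never enter these pools.
#'
#' @param production Tibble with columns `year`, `category`, `inflow_tc`
#'   (t C/yr, >= 0). Years must be consecutive; missing category-years
#'   count as zero inflow.
#' @param half_lives Tibble with columns `category`, `half_life_years`.
#'   Every category in `production` must be present.
#' @return Tibble with columns `year`, `category`, `stock_tc` (end-of-year
#'   stock), `release_tc`.
#' @export
stock_series <- function(production, half_lives) {
  production <- tibble::as_tibble(production)
  stopifnot(all(c("year", "category", "inflow_tc") %in% names(production)))
  cats <- unique(production$category)
  missing_hl <- setdiff(cats, half_lives$category)
  if (length(missing_hl) > 0) {
    stop("no half-life for category(ies): ",
         paste(missing_hl, collapse = ", "), call. = FALSE)
  }
  years <- sort(unique(production$year))
  if (length(years) == 0) {
    return(tibble::tibble(year = integer(), category = character(),
                          stock_tc = numeric(), release_tc = numeric()))
  }
  years <- seq(min(years), max(years))
  grid <- tidyr::expand_grid(year = years, category = cats) |>
    dplyr::left_join(production, by = c("year", "category")) |>
    dplyr::mutate(inflow_tc = dplyr::if_else(is.na(.data$inflow_tc), 0,
                                             .data$inflow_tc))
  out <- purrr::map(cats, function(cat_i) {
    hl <- half_lives$half_life_years[half_lives$category == cat_i][[1]]
    inf <- grid$inflow_tc[grid$category == cat_i]
    stock <- numeric(length(years))
    release <- numeric(length(years))
    s <- 0
    for (t in seq_along(years)) {
      step <- pool_step(s, inf[[t]], hl)
      stock[[t]] <- step$stock
      release[[t]] <- step$release
      s <- step$stock
    }
    tibble::tibble(year = years, category = cat_i,
                   stock_tc = stock, release_tc = release)
  }) |>
    purrr::list_rbind()
  out
}

#' Total HWP stock per year
#'
#' @param series Output of [stock_series()].
#' @return Tibble `year`, `stock_tc`, `release_tc` summed over categories.
#' @export
total_stock <- function(series) {
  series |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(stock_tc = sum(.data$stock_tc),
                     release_tc = sum(.data$release_tc), .groups = "drop")
}

#' Annualised HWP storage-change credit versus business-as-usual
#'
#' The credit is the annualised average gain in the domestic HWP carbon
#' stock caused by the change in domestic production: the stock-gain
#' trajectory (scenario minus BAU) is averaged over the `window` years
#' following the first year of divergence, annualised by dividing by the
#' window length, and converted to CO2e. Gains are reported negative
#' (removals). Comparing BAU with itself gives exactly zero, the BAU
#' convention.
#'
#' @param scenario_series,bau_series Outputs of [stock_series()] on the
#'   same year axis, which must extend at least `window` years past the
#'   first divergence.
#' @param window Averaging window in years (default 50).
#' @param co2_per_c Mass conversion, default 44/12.
#' @return Constant annual credit in t CO2e/yr (<= 0 for storage gains).
#' @export
storage_change_credit <- function(scenario_series, bau_series, window = 50,
                                  co2_per_c = CO2_PER_C) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  ts <- total_stock(scenario_series)
  tb <- total_stock(bau_series)
  if (!identical(ts$year, tb$year)) {
    stop("series must share the same year axis", call. = FALSE)
  }
  gain <- ts$stock_tc - tb$stock_tc
  first <- which(abs(gain) > 0)[1]
  if (is.na(first)) return(0)
  idx <- first:(first + window - 1)
  if (max(idx) > length(gain)) {
    stop(sprintf("series too short: need %d years after divergence, have %d",
                 window, length(gain) - first + 1), call. = FALSE)
  }
  -mean(gain[idx]) * co2_per_c / window
}
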