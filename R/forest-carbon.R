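#' Parametric yield curve for a given yield class
#'
#' Cumulative standing volume against age follows a Chapman-Richards
#' sigmoid `V(a) = vmax * (1 - exp(-k a))^p`. `vmax` is not free: it is
#' scaled so that the curve's maximum mean annual increment (MAI, the
#' culmination of `V(a)/a`) equals the requested yield class, the
#' productivity index used in UK forestry. The default shape parameters
#' put MAI culmination near age 45-50, typical of upland conifer crops.
#'
#' @param yield_class Maximum MAI, m3/ha/yr (> 0).
#' @param species Label carried in the output.
#' @param k,p Chapman-Richards shape parameters.
#' @param max_age Last tabulated age; volume is flat beyond it.
#' @return A `yield_curve`: list with `species`, `yield_class`, `points`
#'   (tibble `age`, `volume_m3_ha`, monotone non-decreasing from 0).
#' @export
#' @examples
#' yc <- yield_curve(16)
#' volume_at(yc, 50)
yield_curve <- function(yield_class, species = "sitka_spruce",
                        k = 0.035, p = 2.5, max_age = 150) {
  stopifnot(yield_class > 0, k > 0, p > 0, max_age > 1)
  ages <- 0:max_age
  shape <- (1 - exp(-k * ages))^p
  mai_shape <- shape[-1] / ages[-1]
  vmax <- yield_class / max(mai_shape)
  structure(
    list(species = species, yield_class = yield_class,
         points = tibble::tibble(age = ages, volume_m3_ha = vmax * shape)),
    class = "yield_curve"
  )
}

#' Build a yield curve from tabulated points
#'
#' @param points Data frame with columns `age`, `volume_m3_ha`;
#'   volume must be 0 at age 0 and non-decreasing.
#' @param species,yield_class Metadata labels.
#' @return A `yield_curve`.
#' @export
yield_curve_from_points <- function(points, species = "custom",
                                    yield_class = NA_real_) {
  points <- tibble::as_tibble(points)[, c("age", "volume_m3_ha")]
  points <- dplyr::arrange(points, .data$age)
  if (nrow(points) == 0) stop("empty yield curve", call. = FALSE)
  if (points$age[[1]] != 0 || points$volume_m3_ha[[1]] != 0) {
    points <- dplyr::bind_rows(tibble::tibble(age = 0, volume_m3_ha = 0), points)
  }
  if (is.unsorted(points$volume_m3_ha)) {
    stop("yield curve volume must be non-decreasing in age", call. = FALSE)
  }
  structure(list(species = species, yield_class = yield_class, points = points),
            class = "yield_curve")
}

#' Standing volume at a given age
#'
#' Linear interpolation between tabulated points, flat beyond the last
#' point (old stands hold their volume; senescence is not modelled).
#'
#' @param curve A `yield_curve`.
#' @param age Stand age(s), years.
#' @return Volume(s), m3/ha.
#' @export
volume_at <- function(curve, age) {
  stats::approx(curve$points$age, curve$points$volume_m3_ha, xout = age,
                rule = 2)$y
}

#' Area-weighted mean yield class of a species mixture
#'
#' @param components Data frame (or list coercible to one) with columns
#'   `fraction` and `yield_class`; fractions must sum to 1.
#' @return The weighted mean yield class, m3/ha/yr.
#' @export
#' @examples
#' weighted_mean_yield_class(data.frame(
#'   fraction = c(0.5, 0.5), yield_class = c(24, 6)
#' ))
weighted_mean_yield_class <- function(components) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("fraction", "yield_class") %in% names(components)))
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    stop("mix fractions must sum to 1", call. = FALSE)
  }
  sum(components$fraction * components$yield_class)
}

# one-pool soil / dead-organic-matter dynamics, same conservative
# first-order recurrence as the HWP pools
soil_step <- function(stock, input, half_life) {
  k <- log(2) / half_life
  exp(-k) * stock + (1 - exp(-k)) / k * input
}

#' Annual carbon trajectory of one stand cohort
#'
#' Biomass carbon is standing volume times a volume-to-carbon product
#' (`convention$tc_per_m3`). The stand is clearfelled whenever its age
#' reaches `rotation` (volume resets to zero) and replanted at once. Soil
#' and dead organic matter form a single first-order pool fed by a
#' constant turnover fraction of standing biomass plus harvest residues
#' left on site at clearfell.
#'
#' @param area Stand area, ha (> 0).
#' @param plant_year Planting (age-0) calendar year.
#' @param rotation Clearfell age, years; `Inf` for no harvest.
#' @param curve A `yield_curve`.
#' @param years Integer vector of calendar years to report.
#' @param convention A [carbon_convention()].
#' @param soil Named list: `half_life` (years), `turnover` (fraction of
#'   biomass C entering the pool per year), `residue_frac` (fraction of
#'   felled biomass C left as residue), `initial` (t C at the first year).
#' @return Tibble `year`, `age`, `biomass_tc`, `soil_tc`, `total_tc`,
#'   `harvested_tc` (biomass removed that year, t C).
#' @export
stand_trajectory <- function(area, plant_year, rotation, curve, years,
                             convention = carbon_convention(),
                             soil = list(half_life = 30, turnover = 0.015,
                                         residue_frac = 0.3, initial = 0)) {
  if (area <= 0) stop("area must be positive", call. = FALSE)
  years <- sort(as.integer(years))
  n <- length(years)
  age <- biomass <- soil_c <- harvested <- numeric(n)
  s <- soil$initial
  for (i in seq_len(n)) {
    a <- years[[i]] - plant_year
    a <- if (a < 0) NA_real_ else if (is.finite(rotation)) a %% rotation else a
    age[[i]] <- a
    b <- if (is.na(a)) 0 else area * volume_at(curve, a) * convention$tc_per_m3
    felled <- 0
    if (!is.na(a) && is.finite(rotation) && a == 0 && years[[i]] > plant_year) {
      # the stand stood at rotation age during the preceding instant
      felled <- area * volume_at(curve, rotation) * convention$tc_per_m3
    }
    input <- soil$turnover * b + soil$residue_frac * felled
    s <- soil_step(s, input, soil$half_life)
    biomass[[i]] <- b
    soil_c[[i]] <- s
    harvested[[i]] <- felled * (1 - soil$residue_frac)
  }
  tibble::tibble(year = years, age = age, biomass_tc = biomass,
                 soil_tc = soil_c, total_tc = biomass + soil_c,
                 harvested_tc = harvested)
}

#' Mean standing biomass carbon of a fully regulated estate (closed form)
#'
#' A regulated (normal) forest holds equal area in every age class
#' `0 .. rotation - 1`, so its standing biomass carbon is the age-class
#' average of the yield curve times the total area. Used as the
#' independent check on the cohort simulation.
#'
#' @param area Total estate area, ha.
#' @param rotation Rotation, years.
#' @param curve A `yield_curve`.
#' @param convention A [carbon_convention()].
#' @return Standing biomass carbon, t C.
#' @export
regulated_mean_stock <- function(area, rotation, curve,
                                 convention = carbon_convention()) {
  ages <- 0:(rotation - 1)
  mean(volume_at(curve, ages)) * area * convention$tc_per_m3
}

#' Estate carbon trajectory under a rotation change
#'
#' Simulates an estate as an age-class area vector, starting fully
#' regulated on `rotation_from`. From the first simulated year the target
#' rotation becomes `rotation_to`: stands are clearfelled (and replanted)
#' only once they reach the new rotation age, so extending the rotation
#' pauses harvesting while the oldest classes grow on, raising the mean
#' standing stock toward the new regulated equilibrium. Soil carbon uses
#' the same one-pool model as [stand_trajectory()], initialised at the
#' baseline steady state.
#'
#' @param area Estate area, ha.
#' @param rotation_from,rotation_to Initial and target rotations, years.
#' @param curve A `yield_curve`.
#' @param n_years Number of annual steps to simulate.
#' @param convention A [carbon_convention()].
#' @param soil Soil parameters as in [stand_trajectory()] (element
#'   `initial` is ignored; the baseline steady state is used).
#' @return Tibble `step` (1-based year index), `biomass_tc`, `soil_tc`,
#'   `total_tc`, `harvest_m3` (volume felled that year).
#' @export
estate_trajectory <- function(area, rotation_from, rotation_to, curve, n_years,
                              convention = carbon_convention(),
                              soil = list(half_life = 30, turnover = 0.015,
                                          residue_frac = 0.3)) {
  if (rotation_to < rotation_from) {
    stop("extended rotation must not be shorter than the baseline",
         call. = FALSE)
  }
  max_age <- rotation_to + n_years + 1
  areas <- numeric(max_age + 1)              # index = age + 1
  areas[1:rotation_from] <- area / rotation_from
  tc <- convention$tc_per_m3
  vol <- volume_at(curve, 0:max_age)
  # baseline steady state for the soil pool
  base_biomass <- regulated_mean_stock(area, rotation_from, curve, convention)
  base_residue <- soil$residue_frac * (area / rotation_from) *
    volume_at(curve, rotation_from) * tc
  k_s <- log(2) / soil$half_life
  s <- (soil$turnover * base_biomass + base_residue) / k_s
  biomass <- soil_c <- harvest <- numeric(n_years)
  for (t in seq_len(n_years)) {
    # grow one year
    areas <- c(0, areas[-length(areas)])
    # clearfell every class at or beyond the target rotation
    ripe <- which(seq_along(areas) - 1 >= rotation_to)
    felled_area <- sum(areas[ripe])
    felled_vol <- sum(areas[ripe] * vol[ripe])
    areas[ripe] <- 0
    areas[1] <- areas[1] + felled_area
    b <- sum(areas * vol) * tc
    input <- soil$turnover * b + soil$residue_frac * felled_vol * tc
    s <- soil_step(s, input, soil$half_life)
    biomass[[t]] <- b
    soil_c[[t]] <- s
    harvest[[t]] <- felled_vol
  }
  tibble::tibble(step = seq_len(n_years), biomass_tc = biomass,
                 soil_tc = soil_c, total_tc = biomass + soil_c,
                 harvest_m3 = harvest)
}

#' Avoided-harvest credit from recycled MDF
#'
#' Recycling MDF displaces virgin wood demand, allowing harvest rotations
#' to lengthen and forests to hold more carbon. Following the study
#' design, any positive recycled volume shifts a reference estate
#' (default: 710,000 ha of commercial spruce, the scale of the UK
#' commercial conifer resource) from a 50-year to a 54-year rotation; the
#' credit is the annualised average estate carbon gain (biomass + soil)
#' over the study window, converted to CO2e and reported negative. The
#' implied long-run harvest reduction is also returned so users can map
#' recycled volume to rotation change themselves.
#'
#' @param recycled_mdf_volume Recycled-MDF production, m3/yr (>= 0).
#'   Zero gives a zero credit; the rotation shift is fixed, not scaled.
#' @param convention A [carbon_convention()] (`gt_per_m3_product` converts
#'   the recycled volume to green-tonne-equivalent displaced harvest).
#' @param estate List: `area` (ha), `rotation_baseline`,
#'   `rotation_extended` (years), `curve` (a `yield_curve`), optional
#'   `soil` parameters, `green_t_per_m3` (green tonnes per m3 of standing
#'   volume, for the harvest-reduction report).
#' @param study_years Averaging window, years (default 28).
#' @return List: `credit_tco2e` (constant annual credit, <= 0),
#'   `harvest_reduction_gt` (implied long-run reduction, green t/yr),
#'   `displaced_harvest_gt` (the recycled volume as green-tonne-equivalent
#'   virgin wood), `gain_series` (per-step estate carbon gain, t C).
#' @export
avoided_harvest_credit <- function(recycled_mdf_volume,
                                   convention = carbon_convention(),
                                   estate = default_estate(),
                                   study_years = 28) {
  if (recycled_mdf_volume < 0) {
    stop("recycled volume must be non-negative", call. = FALSE)
  }
  if (estate$rotation_extended < estate$rotation_baseline) {
    stop("extended rotation must not be shorter than the baseline",
         call. = FALSE)
  }
  if (recycled_mdf_volume == 0) {
    return(list(credit_tco2e = 0, harvest_reduction_gt = 0,
                displaced_harvest_gt = 0,
                gain_series = rep(0, study_years)))
  }
  soil <- estate$soil %||% list(half_life = 30, turnover = 0.015,
                                residue_frac = 0.3)
  base <- estate_trajectory(estate$area, estate$rotation_baseline,
                            estate$rotation_baseline, estate$curve,
                            study_years, convention, soil)
  ext <- estate_trajectory(estate$area, estate$rotation_baseline,
                           estate$rotation_extended, estate$curve,
                           study_years, convention, soil)
  gain <- ext$total_tc - base$total_tc
  credit <- -mean(gain) * convention$co2_per_c / study_years
  gpm <- estate$green_t_per_m3 %||% 1
  harv_red <- (estate$area / estate$rotation_baseline *
                 volume_at(estate$curve, estate$rotation_baseline) -
               estate$area / estate$rotation_extended *
                 volume_at(estate$curve, estate$rotation_extended)) * gpm
  list(credit_tco2e = credit,
       harvest_reduction_gt = harv_red,
       displaced_harvest_gt = recycled_mdf_volume * convention$gt_per_m3_product,
       gain_series = gain)
}

#' Default reference estate for the avoided-harvest credit
#'
#' @param yield_class Yield class of the reference spruce estate.
#' @return Estate parameter list, see [avoided_harvest_credit()].
#' @export
default_estate <- function(yield_class = 16) {
  list(area = 710000, rotation_baseline = 50, rotation_extended = 54,
       curve = yield_curve(yield_class),
       soil = list(half_life = 30, turnover = 0.015, residue_frac = 0.3),
       green_t_per_m3 = 1.0)
}

#' Afforestation programme definition
#'
#' @param planting_rate ha planted per year.
#' @param start_year,end_year First and last planting years (inclusive).
#' @param mix Data frame with columns `fraction` (summing to 1) and
#'   `yield_class` for each composition component.
#' @return An `afforestation_programme` list.
#' @export
afforestation_programme <- function(planting_rate = 20000,
                                    start_year = 2023, end_year = 2050,
                                    mix = default_afforestation_mix()) {
  if (start_year > end_year) stop("start_year must be <= end_year", call. = FALSE)
  mix <- tibble::as_tibble(mix)
  if (nrow(mix) == 0) stop("mix must have at least one component", call. = FALSE)
  if (abs(sum(mix$fraction) - 1) > 1e-9) {
    stop("mix fractions must sum to 1", call. = FALSE)
  }
  structure(list(planting_rate = planting_rate, start_year = start_year,
                 end_year = end_year, mix = mix),
            class = "afforestation_programme")
}

#' Default planting mix: half pure commercial spruce, half an even
#' conifer:broadleaf mixture
#'
#' The mixed component's aggregate yield class is the area-weighted mean
#' of its species yield classes ([weighted_mean_yield_class()]).
#'
#' @return Tibble `fraction`, `yield_class`, `label`.
#' @export
default_afforestation_mix <- function() {
  mixed <- weighted_mean_yield_class(tibble::tibble(
    # conifer half: sitka, douglas fir, corsican pine; broadleaf half:
    # birch, rowan, oak
    fraction = rep(1 / 6, 6),
    yield_class = c(16, 14, 12, 6, 4, 6)
  ))
  tibble::tibble(
    fraction = c(0.5, 0.5),
    yield_class = c(16, mixed),
    label = c("commercial_conifer", "conifer_broadleaf_mix")
  )
}

#' Net sequestration series of an afforestation programme
#'
#' One cohort per planting year per mix component, no harvest within the
#' reported horizon (commercial felling starts beyond it). Annual net
#' sequestration is the year-on-year increase in total (biomass + soil)
#' carbon, reported as negative CO2e; the cumulative series is its
#' running sum.
#'
#' @param prog An [afforestation_programme()].
#' @param years Calendar years to report.
#' @param curves Optional list of `yield_curve`s, one per mix row;
#'   defaults to [yield_curve()] at each component's yield class.
#' @param convention A [carbon_convention()].
#' @param soil Soil parameters as in [stand_trajectory()].
#' @return Tibble `year`, `stock_tc`, `sequestration_tco2e` (<= 0),
#'   `cumulative_tco2e`.
#' @export
afforestation_series <- function(prog, years = prog$start_year:2050,
                                 curves = NULL,
                                 convention = carbon_convention(),
                                 soil = list(half_life = 30, turnover = 0.015,
                                             residue_frac = 0.3, initial = 0)) {
  years <- sort(as.integer(years))
  if (is.null(curves)) {
    curves <- purrr::map(prog$mix$yield_class, yield_curve)
  }
  stock <- rep(0, length(years))
  if (prog$planting_rate > 0) {
    for (i in seq_len(nrow(prog$mix))) {
      area <- prog$planting_rate * prog$mix$fraction[[i]]
      for (py in prog$start_year:prog$end_year) {
        tr <- stand_trajectory(area, py, Inf, curves[[i]], years,
                               convention, soil)
        stock <- stock + tr$total_tc
      }
    }
  }
  seq_t <- -diff(c(0, stock)) * convention$co2_per_c
  tibble::tibble(year = years, stock_tc = stock,
                 sequestration_tco2e = seq_t,
                 cumulative_tco2e = cumsum(seq_t))
}
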