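#' Node registry for the wood-flow network
#'
#' Every flow network is defined over a fixed set of named nodes. Each node
#' has a role: `source` nodes inject wood into the system (the forest gate
#' and waste-wood recovery), `process` nodes transform it (mills and the
#' woodfuel chain), `product` nodes are terminal harvested-wood-product
#' (HWP) sinks carrying exactly one HWP category, and `loss` nodes receive
#' explicitly declared processing losses.
#'
#' @return A tibble with columns `node`, `role`, `category` (HWP category
#'   for product nodes, otherwise `NA`) and `component` (the value-chain
#'   emission component a process node reports under, otherwise `NA`).
#' @export
#' @examples
#' wood_flow_nodes()
wood_flow_nodes <- function() {
  tibble::tribble(
    ~node,                  ~role,     ~category,            ~component,
    "forest_gate",          "source",  NA,                   "uk_forestry_operations",
    "waste_wood_recovered", "source",  NA,                   NA,
    "waste_mdf_recovered",  "source",  NA,                   NA,
    "sawmill",              "process", NA,                   "uk_sawmilling",
    "particleboard_mill",   "process", NA,                   "uk_wood_panel_production",
    "mdf_mill",             "process", NA,                   "uk_wood_panel_production",
    "recycled_mdf_mill",    "process", NA,                   "uk_wood_panel_production",
    "woodfuel_chain",       "process", NA,                   "uk_woodfuel_production",
    "carcassing",           "product", "carcassing",         NA,
    "fencing",              "product", "fencing",            NA,
    "fence_poles",          "product", "fence_poles",        NA,
    "packaging_pallets",    "product", "packaging_pallets",  NA,
    "particleboard",        "product", "particleboard",      NA,
    "mdf",                  "product", "mdf",                NA,
    "recycled_mdf",         "product", "recycled_mdf",       NA,
    "woodfuel",             "product", "woodfuel",           NA,
    "other",                "product", "other",              NA,
    "loss_sawmill",         "loss",    NA,                   NA,
    "loss_panel",           "loss",    NA,                   NA
  )
}

#' HWP categories
#'
#' @return Character vector of the nine harvested-wood-product categories.
#' @export
hwp_categories <- function() {
  c("carcassing", "fencing", "fence_poles", "packaging_pallets",
    "particleboard", "mdf", "recycled_mdf", "woodfuel", "other")
}

# relative tolerance for node balance; pure arithmetic, only rounding expected
BALANCE_RTOL <- 1e-6

#' Build and validate a scenario wood-flow table
#'
#' Constructs a `flow_table` from a declarative flow specification: one row
#' per directed flow, quantities in green tonnes per year. The table is
#' validated for unknown nodes, negative quantities and mass balance at
#' every intermediate (process) node, where inflow must equal outflow
#' (losses are explicit flows into loss nodes, so the balance is exact up
#' to a relative tolerance of `1e-6` times the harvest total).
#'
#' @param spec Data frame with columns `source`, `target`, `quantity`
#'   (green tonnes/yr, non-negative) and optionally `scenario_id`.
#' @param scenario_id Scenario identifier; defaults to the one found in
#'   `spec` or `"unnamed"`.
#' @param nodes Node registry, see [wood_flow_nodes()].
#' @return A `flow_table`: a tibble of flows with attributes
#'   `scenario_id` and `harvest_total` (total outflow of the forest gate).
#' @export
#' @examples
#' spec <- data.frame(
#'   source = c("forest_gate", "sawmill"),
#'   target = c("sawmill", "carcassing"),
#'   quantity = c(100, 100)
#' )
#' build_scenario_flows(spec, scenario_id = "bau")
build_scenario_flows <- function(spec, scenario_id = NULL, nodes = wood_flow_nodes()) {
  spec <- tibble::as_tibble(spec)
  if (is.null(scenario_id)) {
    scenario_id <- if ("scenario_id" %in% names(spec) && nrow(spec) > 0) {
      as.character(spec$scenario_id[[1]])
    } else {
      "unnamed"
    }
  }
  if (nrow(spec) == 0) {
    tab <- tibble::tibble(source = character(), target = character(),
                          quantity = numeric())
    return(new_flow_table(tab, scenario_id, harvest_total = 0, nodes = nodes))
  }
  stopifnot(all(c("source", "target", "quantity") %in% names(spec)))
  used <- unique(c(spec$source, spec$target))
  unknown <- setdiff(used, nodes$node)
  if (length(unknown) > 0) {
    stop("unknown node name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(spec$quantity)) || any(spec$quantity < 0)) {
    bad <- spec[!is.finite(spec$quantity) | spec$quantity < 0, ]
    stop("negative or non-finite flow quantity on edge ",
         bad$source[[1]], " -> ", bad$target[[1]], call. = FALSE)
  }
  tab <- dplyr::select(spec, "source", "target", "quantity")
  harvest_total <- sum(tab$quantity[tab$source == "forest_gate"])
  ft <- new_flow_table(tab, scenario_id, harvest_total, nodes)
  bal <- node_balance(ft)
  bad <- dplyr::filter(bal, .data$flagged)
  if (nrow(bad) > 0) {
    stop("unbalanced node(s) beyond tolerance: ",
         paste(sprintf("%s (residual %.6g)", bad$node, bad$residual),
               collapse = ", "),
         call. = FALSE)
  }
  ft
}

new_flow_table <- function(tab, scenario_id, harvest_total, nodes = wood_flow_nodes()) {
  out <- tibble::as_tibble(tab)
  attr(out, "scenario_id") <- scenario_id
  attr(out, "harvest_total") <- harvest_total
  attr(out, "nodes") <- nodes
  class(out) <- c("flow_table", class(out))
  out
}

#' @export
print.flow_table <- function(x, ...) {
  cat(sprintf("<flow_table> scenario '%s', harvest %.6g green t/yr, %d flows\n",
              flow_scenario_id(x), flow_harvest_total(x), nrow(x)))
  NextMethod()
}

#' Accessors for flow-table metadata
#'
#' @param table A `flow_table`.
#' @return `flow_scenario_id()` the scenario identifier;
#'   `flow_harvest_total()` the forest-gate outflow in green tonnes/yr.
#' @export
flow_scenario_id <- function(table) attr(table, "scenario_id")

#' @rdname flow_scenario_id
#' @export
flow_harvest_total <- function(table) attr(table, "harvest_total")

flow_nodes <- function(table) {
  nd <- attr(table, "nodes")
  if (is.null(nd)) wood_flow_nodes() else nd
}

#' Per-node mass-balance report
#'
#' Computes, for every node appearing in the table, total inflow, total
#' outflow and (for intermediate process nodes) the residual
#' `inflow - outflow`. Residuals whose magnitude exceeds
#' `tol * harvest_total` are flagged. Source, product and loss nodes are
#' reported with `NA` residuals since they are not required to balance.
#'
#' @param table A `flow_table` (or plain data frame of flows).
#' @param tol Relative tolerance (default `1e-6`).
#' @return Tibble with columns `node`, `role`, `inflow`, `outflow`,
#'   `residual`, `flagged`.
#' @export
node_balance <- function(table, tol = BALANCE_RTOL) {
  nodes <- flow_nodes(table)
  if (nrow(table) == 0) {
    return(tibble::tibble(node = character(), role = character(),
                          inflow = numeric(), outflow = numeric(),
                          residual = numeric(), flagged = logical()))
  }
  inflow <- stats::aggregate(quantity ~ target, data = table, sum)
  outflow <- stats::aggregate(quantity ~ source, data = table, sum)
  all_nodes <- unique(c(table$source, table$target))
  rep <- tibble::tibble(node = all_nodes) |>
    dplyr::left_join(nodes[, c("node", "role")], by = "node") |>
    dplyr::left_join(stats::setNames(inflow, c("node", "inflow")), by = "node") |>
    dplyr::left_join(stats::setNames(outflow, c("node", "outflow")), by = "node") |>
    dplyr::mutate(
      inflow = dplyr::if_else(is.na(.data$inflow), 0, .data$inflow),
      outflow = dplyr::if_else(is.na(.data$outflow), 0, .data$outflow),
      residual = dplyr::if_else(.data$role == "process",
                                .data$inflow - .data$outflow, NA_real_)
    )
  ht <- flow_harvest_total(table)
  scale <- if (is.null(ht) || !is.finite(ht) || ht <= 0) {
    max(rep$inflow, rep$outflow, 1)
  } else {
    ht
  }
  rep$flagged <- !is.na(rep$residual) & abs(rep$residual) > tol * scale
  rep
}

#' Rescale a flow table to a target harvest
#'
#' Multiplies every flow by `harvest / harvest_total`, preserving all node
#' balances exactly (the operation is linear).
#'
#' @param table A balanced `flow_table`.
#' @param harvest Target forest-gate output in green tonnes/yr (> 0).
#' @return A `flow_table` whose forest-gate outflow equals `harvest`.
#' @export
#' @examples
#' ft <- build_scenario_flows(data.frame(
#'   source = "forest_gate", target = "carcassing", quantity = 100
#' ))
#' flow_harvest_total(scale_to_harvest(ft, 9.5e6))
scale_to_harvest <- function(table, harvest) {
  if (!is.numeric(harvest) || length(harvest) != 1 || !is.finite(harvest) ||
      harvest <= 0) {
    stop("harvest must be a single positive number", call. = FALSE)
  }
  ht <- flow_harvest_total(table)
  if (is.null(ht) || ht <= 0) {
    stop("flow table has no positive harvest_total to scale from", call. = FALSE)
  }
  out <- table
  out$quantity <- out$quantity * (harvest / ht)
  attr(out, "harvest_total") <- harvest
  out
}

#' UK production per HWP category
#'
#' Production of each category is the total inflow into its terminal
#' product node, in green tonnes/yr. Categories with no flows are reported
#' as zero so that scenario comparisons are always complete.
#'
#' @param table A `flow_table`.
#' @return Tibble with columns `category`, `production` (green tonnes/yr).
#' @export
product_output <- function(table) {
  nodes <- flow_nodes(table)
  prod_nodes <- nodes[nodes$role == "product", c("node", "category")]
  got <- if (nrow(table) == 0) {
    tibble::tibble(node = character(), production = numeric())
  } else {
    stats::setNames(stats::aggregate(quantity ~ target, data = table, sum),
                    c("node", "production")) |>
      tibble::as_tibble()
  }
  prod_nodes |>
    dplyr::left_join(got, by = "node") |>
    dplyr::mutate(production = dplyr::if_else(is.na(.data$production), 0,
                                              .data$production)) |>
    dplyr::select("category", "production")
}

#' Throughput of each process node
#'
#' Process throughput is the quantity the emission factors multiply: total
#' inflow for mills and the woodfuel chain, total outflow (the harvest)
#' for the forest gate.
#'
#' @param table A `flow_table`.
#' @return Tibble with columns `process_id`, `component`, `throughput`
#'   (green tonnes/yr).
#' @export
process_throughput <- function(table) {
  nodes <- flow_nodes(table)
  proc <- nodes[!is.na(nodes$component), c("node", "component")]
  thr <- purrr::map_dbl(proc$node, function(n) {
    if (n == "forest_gate") {
      sum(table$quantity[table$source == n])
    } else {
      sum(table$quantity[table$target == n])
    }
  })
  tibble::tibble(process_id = proc$node, component = proc$component,
                 throughput = thr)
}

#' Import-volume deltas versus business-as-usual
#'
#' Under the consequential convention, total (domestic + imported) supply
#' of every product category is held constant across scenarios: imports
#' adjust to mirror changes in domestic production. The exception is
#' woodfuel, where only a configurable fraction of any domestic production
#' shortfall is replaced by imported woodfuel, so circular scenarios show
#' a real net reduction in woodfuel consumption (recycled waste MDF no
#' longer burned is only partly replaced).
#'
#' Recycled MDF is a drop-in substitute for virgin MDF, so the two are
#' compared as one consumption group (configurable via `groups`).
#'
#' @param scenario,bau `flow_table`s scaled to the same harvest.
#' @param woodfuel_replacement Fraction in `[0, 1]` of the woodfuel
#'   production shortfall replaced by imports (default 0.4).
#' @param groups Named character vector mapping category -> consumption
#'   group; defaults to identity with `recycled_mdf` grouped under `mdf`.
#' @return Tibble with columns `category` (consumption group),
#'   `uk_delta` (scenario - BAU domestic production, green t/yr),
#'   `import_delta` (signed import change, green-tonne-equivalent/yr) and
#'   `consumption_delta` (net change in total supply; zero except
#'   woodfuel).
#' @export
derive_import_deltas <- function(scenario, bau, woodfuel_replacement = 0.4,
                                 groups = NULL) {
  hs <- flow_harvest_total(scenario)
  hb <- flow_harvest_total(bau)
  if (!isTRUE(all.equal(hs, hb, tolerance = 1e-9))) {
    stop(sprintf("mismatched harvest totals: %.6g vs %.6g", hs, hb),
         call. = FALSE)
  }
  if (woodfuel_replacement < 0 || woodfuel_replacement > 1) {
    stop("woodfuel_replacement must be in [0, 1]", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- stats::setNames(hwp_categories(), hwp_categories())
    groups[["recycled_mdf"]] <- "mdf"
  }
  grp <- function(p) {
    p$group <- unname(groups[p$category])
    stats::aggregate(production ~ group, data = p, sum)
  }
  ps <- grp(product_output(scenario))
  pb <- grp(product_output(bau))
  m <- merge(pb, ps, by = "group", suffixes = c("_bau", "_scen"), all = TRUE)
  m[is.na(m)] <- 0
  uk_delta <- m$production_scen - m$production_bau
  import_delta <- -uk_delta
  fuel <- m$group == "woodfuel"
  import_delta[fuel] <- -uk_delta[fuel] * woodfuel_replacement
  tibble::tibble(
    category = m$group,
    uk_delta = uk_delta,
    import_delta = import_delta,
    consumption_delta = uk_delta + import_delta
  ) |>
    dplyr::arrange(.data$category)
}

#' Export a flow table as Sankey-style JSON
#'
#' Writes `{"scenario_id": ..., "nodes": [...], "links": [{source, target,
#' value}, ...]}` with links indexed into the node list, the layout most
#' Sankey plotting libraries expect.
#'
#' @param table A `flow_table`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
sankey_json <- function(table, path = NULL) {
  nodes <- unique(c(table$source, table$target))
  links <- list(
    source = match(table$source, nodes) - 1L,
    target = match(table$target, nodes) - 1L,
    value = table$quantity
  )
  obj <- list(
    scenario_id = flow_scenario_id(table),
    nodes = lapply(nodes, function(n) list(name = n)),
    links = purrr::pmap(links, function(source, target, value) {
      list(source = source, target = target, value = value)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
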