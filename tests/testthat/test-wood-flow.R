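test_that("scenario flow tables are built, scaled and mass-balanced", {
  fx <- fx_bundle()

  # the normalised BAU table ships a 100-unit harvest
  expect_equal(flow_harvest_total(fx$flows$bau), 100)
  expect_equal(sum(fx$flows$bau$quantity[fx$flows$bau$source == "forest_gate"]),
               100)

  # empty spec: empty table, vacuously balanced
  empty <- build_scenario_flows(data.frame(source = character(),
                                           target = character(),
                                           quantity = numeric()))
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(node_balance(empty)), 0)

  # scaling to the national harvest and back is linear, flow by flow
  big <- scale_to_harvest(fx$flows$bau, 9.5e6)
  expect_equal(flow_harvest_total(big), 9.5e6)
  expect_equal(big$quantity / fx$flows$bau$quantity,
               rep(9.5e4, nrow(big)))
  expect_equal(scale_to_harvest(big, flow_harvest_total(big))$quantity,
               big$quantity)

  # balance report on a balanced table: all process residuals zero
  bal <- node_balance(fx$flows$circular)
  expect_true(all(abs(bal$residual[bal$role == "process"]) < 1e-9))
  expect_false(any(bal$flagged))

  # BAU cascades recovered waste wood into particleboard and energy
  bau <- fx$flows$bau
  expect_true(any(bau$source == "waste_wood_recovered" &
                    bau$target == "particleboard_mill" & bau$quantity > 0))
  expect_true(any(bau$source == "waste_wood_recovered" &
                    bau$target == "woodfuel_chain" & bau$quantity > 0))
})

test_that("flow validation rejects malformed specifications", {
  expect_error(build_scenario_flows(data.frame(
    source = "forest_gate", target = "space_elevator", quantity = 1
  )), "unknown node")
  expect_error(build_scenario_flows(data.frame(
    source = "forest_gate", target = "sawmill", quantity = -5
  )), "negative")
  # unbalanced process node is named in the error
  expect_error(build_scenario_flows(data.frame(
    source = c("forest_gate", "sawmill"),
    target = c("sawmill", "carcassing"),
    quantity = c(100, 60)
  )), "sawmill")
  expect_error(scale_to_harvest(build_scenario_flows(tiny_flow_spec()), -1),
               "positive")
})

test_that("deleting one internal flow flags exactly the two touched nodes", {
  fx <- fx_bundle()
  fl <- tibble::as_tibble(fx$flows$bau)
  drop <- which(fl$source == "sawmill" & fl$target == "mdf_mill")
  broken <- circwood:::new_flow_table(fl[-drop, ], "broken", 100)
  bal <- node_balance(broken)
  expect_setequal(bal$node[bal$flagged], c("sawmill", "mdf_mill"))
})

test_that("random balanced instances conserve mass at every node (oracle)", {
  for (seed in 1:10) {
    b <- random_instance(list(seed = seed))
    for (ft in b$flows) {
      res <- brute_node_residuals(ft)
      expect_true(all(abs(res) < 1e-6 * flow_harvest_total(ft)))
      expect_true(all(ft$quantity >= 0))
    }
  }
})

test_that("import deltas close the supply balance for non-fuel products", {
  fx <- fx_bundle()
  bau <- fx$flows$bau

  # self-comparison: everything zero
  self <- derive_import_deltas(bau, bau)
  expect_true(all(self$import_delta == 0))
  expect_true(all(self$consumption_delta == 0))

  for (id in c("cascading", "circular", "cascading_circular")) {
    d <- derive_import_deltas(fx$flows[[id]], bau, woodfuel_replacement = 0.4)
    nf <- d[d$category != "woodfuel", ]
    # constant total supply: UK change + import change = 0
    expect_equal(nf$consumption_delta, rep(0, nrow(nf)))
    # brute-force conservation: scenario production + imports = BAU production
    po_b <- product_output(bau)
    po_s <- product_output(fx$flows[[id]])
    po_b$category[po_b$category == "recycled_mdf"] <- "mdf"
    po_s$category[po_s$category == "recycled_mdf"] <- "mdf"
    for (ct in setdiff(unique(nf$category), "woodfuel")) {
      supply_b <- sum(po_b$production[po_b$category == ct])
      supply_s <- sum(po_s$production[po_s$category == ct]) +
        d$import_delta[d$category == ct]
      expect_equal(supply_s, supply_b)
    }
  }

  # cascading raises carcassing production by 10 units: imports fall by 10
  d <- derive_import_deltas(fx$flows$cascading, bau)
  expect_equal(d$uk_delta[d$category == "carcassing"], 10)
  expect_equal(d$import_delta[d$category == "carcassing"], -10)

  # circular scenarios: a real net reduction in woodfuel consumption
  for (id in c("circular", "cascading_circular")) {
    d <- derive_import_deltas(fx$flows[[id]], bau, woodfuel_replacement = 0.4)
    expect_lt(d$consumption_delta[d$category == "woodfuel"], 0)
    expect_gt(d$import_delta[d$category == "woodfuel"], 0)
  }

  expect_error(derive_import_deltas(scale_to_harvest(bau, 200), bau),
               "mismatched harvest")
})

test_that("circular scenarios cut virgin panel feedstock and add recycling", {
  fx <- fx_bundle()
  virgin_mdf <- function(ft) {
    sum(ft$quantity[ft$source == "forest_gate" & ft$target == "mdf_mill"])
  }
  rmdf_edge <- function(ft) {
    sum(ft$quantity[ft$source == "waste_mdf_recovered" &
                      ft$target == "recycled_mdf_mill"])
  }
  for (id in c("circular", "cascading_circular")) {
    expect_lt(virgin_mdf(fx$flows[[id]]), virgin_mdf(fx$flows$bau))
    expect_gt(rmdf_edge(fx$flows[[id]]), 0)
  }
  # spared material is diverted to sawmilling
  to_saw <- function(ft) {
    sum(ft$quantity[ft$source == "forest_gate" & ft$target == "sawmill"])
  }
  expect_gt(to_saw(fx$flows$circular), to_saw(fx$flows$bau))
})

test_that("sankey export round-trips nodes and link values", {
  ft <- build_scenario_flows(tiny_flow_spec(), scenario_id = "bau")
  js <- jsonlite::fromJSON(sankey_json(ft), simplifyVector = FALSE)
  expect_equal(js$scenario_id, "bau")
  expect_equal(length(js$nodes), 3)
  expect_equal(vapply(js$links, function(l) l$value, numeric(1)),
               c(100, 100))
})
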