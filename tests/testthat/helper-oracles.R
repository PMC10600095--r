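# Independent brute-force oracles. These deliberately avoid the package's
# own aggregation code paths: plain loops over rows.

# per-node inflow/outflow residuals by explicit summation
brute_node_residuals <- function(flows) {
  procs <- c("sawmill", "particleboard_mill", "mdf_mill",
             "recycled_mdf_mill", "woodfuel_chain")
  res <- numeric(0)
  for (p in procs) {
    if (!p %in% c(flows$source, flows$target)) next
    inflow <- 0
    outflow <- 0
    for (i in seq_len(nrow(flows))) {
      if (flows$target[i] == p) inflow <- inflow + flows$quantity[i]
      if (flows$source[i] == p) outflow <- outflow + flows$quantity[i]
    }
    res[p] <- inflow - outflow
  }
  res
}

# first-order pool by explicit yearly iteration
brute_pool <- function(inflows, half_life) {
  k <- log(2) / half_life
  s <- 0
  stocks <- numeric(length(inflows))
  releases <- numeric(length(inflows))
  for (t in seq_along(inflows)) {
    nxt <- exp(-k) * s + (-expm1(-k)) / k * inflows[t]
    releases[t] <- s + inflows[t] - nxt
    s <- nxt
    stocks[t] <- s
  }
  list(stock = stocks, release = releases)
}

# scope/component totals by looping over inventory rows and throughputs
brute_process_emissions <- function(table, inv, year, schedule) {
  thr <- process_throughput(table)
  total <- 0
  for (i in seq_len(nrow(thr))) {
    rows <- inv[inv$process_id == thr$process_id[i], ]
    for (j in seq_len(nrow(rows))) {
      m <- decarb_multiplier(rows$decarb_sector[j], year, schedule)
      total <- total + thr$throughput[i] * rows$value_kgco2e[j] * m / 1000
    }
  }
  total
}
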