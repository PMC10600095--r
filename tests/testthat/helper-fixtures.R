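# shared fixtures, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_bundle <- function() cached("fx", make_paper_like_fixture())

fx_results <- function() {
  cached("res5", run_all_scenarios(fx_bundle(), implementation_year = 2027))
}

fx_results_delayed <- function() {
  cached("res10", run_all_scenarios(fx_bundle(), implementation_year = 2032))
}

# a minimal one-step flow spec used by several unit tests
tiny_flow_spec <- function(q = 100) {
  data.frame(
    source = c("forest_gate", "sawmill"),
    target = c("sawmill", "carcassing"),
    quantity = c(q, q)
  )
}
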