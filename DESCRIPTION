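Package: circwood
Title: Dynamic Consequential Life-Cycle Assessment of Circular Wood Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic, consequential life-cycle-assessment model of a
    national forestry value chain. Four wood-use scenarios
    (business-as-usual, cascading, circular, cascading-and-circular) are
    run over 2022-2050 to produce annual and cumulative Scope 1-4
    greenhouse-gas trajectories. The model couples mass-balanced wood-flow
    networks with a process-emission engine under stepwise industrial
    decarbonisation, first-order-decay harvested-wood-product carbon
    pools, a stand/estate forest-carbon model driving avoided-harvest
    credits and an afforestation programme, and substitution credits for
    displaced fossil fuel and concrete. A deterministic synthetic input
    bundle and a seeded random-instance generator make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
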