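Package: easementsim
Title: Long-Term Cost-Effectiveness of Conservation Easements Versus Land Purchase
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic 100-year comparison of conservation easements and
    fee-simple land purchase as strategies to protect high-biodiversity
    private land. Generates synthetic cadastral parcel portfolios calibrated
    to regional price statistics, selects ensembles of reserve networks
    meeting a beta-diversity protection target (a greedy and a simulated
    annealing stand-in for Marxan), applies a transaction- and
    recurring-cost schedule for easements, simulates annual dispute events
    (pre-emptive enforcement with monetary cost, damage enforcement with
    biodiversity loss) drawn from a bounded power-law cost profile, and
    summarises cost, biodiversity loss and relative cost-effectiveness
    across scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
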