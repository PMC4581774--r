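# purchase and easement trajectories, the full experiment

test_that("purchase trajectory is flat at assessed value plus trust fraction", {
  net <- uniform_network(25, value = 2e5)
  tr <- simulate_purchase(net, scenario_config(years = 40))
  expect_equal(tr$cumulative_cost, rep(1.15 * 25 * 2e5, 41))
  expect_equal(tr$protected_beta, rep(net$total_beta, 41))
  expect_equal(nrow(tr$events), 0)
  tr0 <- simulate_purchase(net, scenario_config(years = 40, trust_fraction = 0))
  expect_equal(tr0$cumulative_cost[1], net$total_assessed_value)
})

test_that("zero-dispute easement cost follows the closed form exactly", {
  net <- uniform_network(30, area = 2.5)
  cfg <- scenario_config(years = 100)
  tr <- simulate_easement(net, cfg, dispute_rate = 0, seed = 1)
  setup <- sum(easement_setup_cost(net$parcels$area_acres))
  expect_equal(tr$cumulative_cost, setup + (0:100) * 909.6 * 30)
  expect_equal(tr$protected_beta, rep(net$total_beta, 101))
  expect_equal(nrow(tr$events), 0)
})

test_that("degenerate rates: one PE event per easement per year, no loss", {
  net <- uniform_network(12)
  cfg <- scenario_config(years = 10, pe_probability = 1)
  tr <- simulate_easement(net, cfg, dispute_rate = 1, seed = 2)
  expect_equal(nrow(tr$events), 12 * 10)
  expect_true(all(tr$events$kind == "PE"))
  expect_equal(tr$protected_beta, rep(net$total_beta, 11))
  # all-DE twin: no dispute costs, beta strictly decreasing
  cfg_de <- scenario_config(years = 10, pe_probability = 0)
  tr_de <- simulate_easement(net, cfg_de, dispute_rate = 1, seed = 2)
  expect_true(all(tr_de$events$kind == "DE"))
  expect_true(all(tr_de$events$cost == 0))
  expect_true(all(diff(tr_de$protected_beta) < 0))
})

test_that("every emitted event respects the PE/DE invariants", {
  net <- uniform_network(100)
  cfg <- scenario_config(years = 50)
  tr <- simulate_easement(net, cfg, dispute_rate = 0.1, seed = 3)
  ev <- tr$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$loss_fraction[ev$kind == "PE"] == 0))
  expect_true(all(ev$cost[ev$kind == "DE"] == 0))
  expect_true(all(ev$cost[ev$kind == "PE"] >= 1000 &
                    ev$cost[ev$kind == "PE"] <= 400000))
  expect_true(all(ev$loss_fraction >= 0 & ev$loss_fraction <= 1))
})

test_that("trajectories are monotone: cost up, biodiversity down", {
  net <- uniform_network(60)
  for (seed in 1:5) {
    tr <- simulate_easement(net, scenario_config(years = 60),
                            dispute_rate = 0.05, seed = seed)
    expect_true(all(diff(tr$cumulative_cost) >= 0))
    expect_true(all(diff(tr$protected_beta) <= 0))
    expect_equal(tr$protected_beta[1], net$total_beta)
  }
})

test_that("dispute counts match the binomial expectation", {
  net <- uniform_network(1000)
  cfg <- scenario_config(years = 100)
  counts <- vapply(1:50, function(s) {
    nrow(simulate_easement(net, cfg, dispute_rate = 0.028, seed = s)$events)
  }, numeric(1))
  n_trials <- 1000 * 100
  expected <- n_trials * 0.028
  se <- sqrt(n_trials * 0.028 * (1 - 0.028) / 50)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("small-rate mean loss matches the analytic linearization", {
  net <- uniform_network(300)
  rate <- 0.002
  years <- 50
  cfg <- scenario_config(years = years, pe_probability = 0.5,
                         loss_jitter_sd = 0.05)
  loss <- vapply(1:40, function(s) {
    tr <- simulate_easement(net, cfg, dispute_rate = rate, seed = 1000 + s)
    1 - tr$protected_beta[years + 1] / tr$protected_beta[1]
  }, numeric(1))
  m <- oracle_mean_loss(0.05)
  analytic <- years * rate * (1 - cfg$pe_probability) * m
  se <- sd(loss) / sqrt(length(loss))
  expect_lt(abs(mean(loss) - analytic), 3 * se)
})

test_that("run_experiment is reproducible and ordered across rates", {
  cfg <- scenario_config(
    n_solutions = 4, years = 60, seed = 21,
    dispute_rates = c(0, 0.0028, 0.028, 0.1),
    portfolio = portfolio_params(n_parcels = 1500, seed = 21))
  r1 <- run_experiment(config = cfg)
  r2 <- run_experiment(config = cfg)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(r1$summary, r2$summary)

  fin <- r1$summary[r1$summary$year == 60, ]
  ease <- fin[fin$scenario != "purchase", ]
  ease <- ease[order(as.numeric(sub("easement_rate_", "", ease$scenario))), ]
  expect_true(all(diff(ease$cost_mean) > 0))          # cost grows with rate
  expect_true(all(diff(ease$beta_fraction_mean) < 0)) # loss grows with rate
  # degenerate ensemble: one solution, no disputes -> min = mean = max
  one <- run_experiment(config = scenario_config(
    n_solutions = 1, years = 10, dispute_rates = 0, seed = 2,
    portfolio = portfolio_params(n_parcels = 400, seed = 2)))
  expect_equal(one$summary$cost_min, one$summary$cost_mean)
  expect_equal(one$summary$cost_max, one$summary$cost_mean)
})

test_that("config validation rejects out-of-range fields", {
  expect_error(scenario_config(dispute_rates = -0.1),
               class = "easementsim_config_error")
  expect_error(scenario_config(years = 0), class = "easementsim_config_error")
  expect_error(scenario_config(pe_probability = 1.5),
               class = "easementsim_config_error")
  expect_error(scenario_config(solution_jitter = 1),
               class = "easementsim_config_error")
})
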