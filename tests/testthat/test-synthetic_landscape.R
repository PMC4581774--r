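# portfolio generation, calibration, and the Marxan stand-in selectors

test_that("generate_portfolio honours size, validity and determinism", {
  one <- generate_portfolio(portfolio_params(n_parcels = 1, seed = 5))
  expect_equal(nrow(one), 1L)
  expect_true(one$area_acres > 0 && one$assessed_value > 0 &&
                one$beta_score >= 0)
  a <- generate_portfolio(portfolio_params(n_parcels = 500, seed = 7))
  b <- generate_portfolio(portfolio_params(n_parcels = 500, seed = 7))
  expect_identical(a, b)
  expect_false(identical(
    a, generate_portfolio(portfolio_params(n_parcels = 500, seed = 8))))
  expect_error(portfolio_params(n_parcels = 0),
               class = "easementsim_config_error")
  expect_error(portfolio_params(price_log_sd = NaN),
               class = "easementsim_config_error")
})

test_that("default portfolio is calibrated to the regional statistics", {
  p <- generate_portfolio(portfolio_params(n_parcels = 10000, seed = 1))
  ppa <- p$assessed_value / p$area_acres
  expect_gte(mean(ppa < 1e5), 0.05)
  expect_lte(mean(ppa < 1e5), 0.11)
  expect_lt(abs(mean(ppa) - 2.1e6) / 2.1e6, 0.25)
  expect_true(all(p$area_acres >= 0.01 & p$area_acres <= 5830))
  # negative rank coupling between price/acre and beta score
  expect_lt(cor(ppa, p$beta_score, method = "spearman"), -0.2)
})

test_that("price_lognormal_params solves the stated constraints exactly", {
  par <- price_lognormal_params(2.1e6, 0.08, 1e5)
  expect_equal(exp(par[["meanlog"]] + par[["sdlog"]]^2 / 2), 2.1e6)
  expect_equal(plnorm(1e5, par[["meanlog"]], par[["sdlog"]]), 0.08)
})

test_that("greedy selection follows the ratio order and meets the target", {
  pf <- toy_portfolio()  # ratios 10, 5, 10/3; total beta 30
  # target 1/3: parcel A1 alone reaches beta 10 = target exactly
  expect_equal(select_network_greedy(pf, 1 / 3)$parcel_ids, "A1")
  # target 0.34: 10.2 beta needed, so the two best-ratio parcels
  expect_equal(select_network_greedy(pf, 0.34)$parcel_ids, c("A1", "A2"))
  # target 1: everything
  all_net <- select_network_greedy(pf, 1)
  expect_setequal(all_net$parcel_ids, pf$parcel_id)
  # totals are conserved sums over members
  expect_equal(all_net$total_beta, sum(pf$beta_score))
  expect_equal(all_net$total_assessed_value, sum(pf$assessed_value))
  expect_equal(all_net$total_area_acres, sum(pf$area_acres))
  expect_error(select_network_greedy(pf[0, ], 0.2),
               class = "easementsim_input_error")
})

test_that("greedy ties break on smaller parcel id", {
  pf <- data.frame(parcel_id = c("B2", "B1"), area_acres = c(1, 1),
                   assessed_value = c(5, 5), beta_score = c(2, 2))
  expect_equal(select_network_greedy(pf, 0.5)$parcel_ids, "B1")
})

test_that("greedy and annealed selections meet the target and bound the optimum", {
  for (seed in 1:5) {
    pf <- random_portfolio(12, seed)
    target <- 0.4
    opt <- enumerate_optimum_cost(pf, target)
    tgt_beta <- target * sum(pf$beta_score)
    g <- select_network_greedy(pf, target)
    expect_gte(g$total_beta, tgt_beta)
    expect_gte(g$total_assessed_value, opt - 1e-9)
    a <- select_network_annealed(pf, target, n_iter = 4000, seed = seed)
    expect_gte(a$total_beta, tgt_beta)
    expect_gte(a$total_assessed_value, opt - 1e-9)
    expect_lte(a$total_assessed_value, g$total_assessed_value + 1e-9)
  }
})

test_that("annealed solutions stay within 20% of the exhaustive optimum", {
  worst <- 0
  for (seed in 1:20) {
    pf <- random_portfolio(12, 100 + seed)
    opt <- enumerate_optimum_cost(pf, 0.4)
    a <- select_network_annealed(pf, 0.4, n_iter = 4000, seed = seed)
    worst <- max(worst, a$total_assessed_value / opt)
  }
  expect_lte(worst, 1.2)
})

test_that("annealed selection is deterministic for a fixed seed", {
  pf <- random_portfolio(12, 3)
  a1 <- select_network_annealed(pf, 0.4, seed = 42)
  a2 <- select_network_annealed(pf, 0.4, seed = 42)
  expect_identical(a1, a2)
  # target 1 with any large penalty keeps every parcel
  expect_setequal(select_network_annealed(pf, 1, seed = 1)$parcel_ids,
                  pf$parcel_id)
})

test_that("solution ensembles meet the target on true beta and reproduce", {
  pf <- generate_portfolio(portfolio_params(n_parcels = 2000, seed = 9))
  nets <- generate_solution_set(pf, n_solutions = 10, target_fraction = 0.2,
                                jitter = 0.05, seed = 4)
  expect_length(nets, 10)
  tgt <- 0.2 * sum(pf$beta_score)
  for (nw in nets) expect_gte(nw$total_beta, tgt - 1e-9)
  expect_gt(length(unique(vapply(nets, function(nw)
    paste(nw$parcel_ids, collapse = ","), character(1)))), 1)
  # jitter 0: degenerate ensemble, all identical
  same <- generate_solution_set(pf, 5, 0.2, jitter = 0, seed = 4)
  for (nw in same[-1]) expect_identical(nw$parcel_ids, same[[1]]$parcel_ids)
  # fixed seed reproducibility
  nets2 <- generate_solution_set(pf, 10, 0.2, 0.05, seed = 4)
  expect_identical(lapply(nets, `[`, c("parcel_ids", "total_beta")),
                   lapply(nets2, `[`, c("parcel_ids", "total_beta")))
  expect_error(generate_solution_set(pf, 5, 0.2, jitter = 1),
               class = "easementsim_config_error")
})

test_that("portfolio CSV round-trips through the documented contract", {
  pf <- random_portfolio(20, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_portfolio_csv(pf, path)
  header <- readLines(path, n = 1)
  expect_match(header, "^parcel_id,area_acres,assessed_value,beta_score")
  back <- read_portfolio_csv(path)
  expect_equal(back, pf)
  expect_error(read_portfolio_csv(file.path(tempdir(), "nope.csv")),
               class = "easementsim_input_error")
})
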