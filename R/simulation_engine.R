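# 100-year trajectory simulation.
#
# Purchase scenario: all cost up front (assessed value + trust fraction);
# protected biodiversity never changes (no dispute and no protected-area
# downgrading has been reported for purchased land in the study region).
#
# Easement scenario: year 0 charges the setup cost of every easement;
# every later year charges the recurring cost per easement and each easement
# independently suffers a dispute with probability `dispute_rate` (Bernoulli
# per easement per year -- the rate counts easements affected, not events).
# A dispute is PE (adds a sampled monetary cost) or DE (multiplies the
# easement's *remaining* beta score by 1 - loss fraction; repeated DE events
# compound, so scores decay toward 0 and never go negative). Easements are
# never extinguished and keep incurring recurring costs after losses.

#' Scenario configuration
#'
#' Bundles every tunable of a full experiment. Defaults reproduce the
#' published study design: a 100-year horizon, dispute rates
#' {0, 0.028%, 0.28%, 2.8%} of easements per year, even PE/DE assignment,
#' 5% SD jitter on DE losses, a 20% beta-diversity protection target, a 15%
#' purchase trust fraction and an ensemble of 100 solutions.
#'
#' @param dispute_rates Per-easement per-year dispute probabilities to run
#'   (default `c(0, 0.00028, 0.0028, 0.028)`).
#' @param years Simulation horizon in years (default 100).
#' @param pe_probability Probability a dispute is PE rather than DE
#'   (default 0.5).
#' @param loss_jitter_sd SD of the Gaussian jitter on DE loss fractions
#'   (default 0.05 on the `[0, 1]` scale).
#' @param protection_target Fraction of total beta score to protect
#'   (default 0.20).
#' @param trust_fraction Purchase-price fraction endowed at acquisition
#'   (default 0.15).
#' @param n_solutions Ensemble size (default 100).
#' @param solution_jitter Cost jitter generating ensemble variability
#'   (default 0.05).
#' @param seed Master RNG seed.
#' @param cost_schedule An [easement_cost_schedule()].
#' @param dispute_profile A [dispute_cost_profile()].
#' @param portfolio A [portfolio_params()] used when a portfolio must be
#'   generated.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(dispute_rates = c(0, 0.00028, 0.0028, 0.028),
                            years = 100,
                            pe_probability = 0.5,
                            loss_jitter_sd = 0.05,
                            protection_target = 0.20,
                            trust_fraction = 0.15,
                            n_solutions = 100,
                            solution_jitter = 0.05,
                            seed = 1L,
                            cost_schedule = easement_cost_schedule(),
                            dispute_profile = dispute_cost_profile(),
                            portfolio = portfolio_params()) {
  if (!is.numeric(dispute_rates) || length(dispute_rates) < 1 ||
      any(dispute_rates < 0 | dispute_rates > 1)) {
    stop_config("dispute_rates must all lie in [0, 1]")
  }
  years <- assert_count(years, "years")
  assert_scalar_number(pe_probability, "pe_probability", lower = 0, upper = 1)
  assert_scalar_number(loss_jitter_sd, "loss_jitter_sd", lower = 0)
  assert_scalar_number(protection_target, "protection_target",
                       lower = 1e-12, upper = 1)
  assert_scalar_number(trust_fraction, "trust_fraction", lower = 0)
  n_solutions <- assert_count(n_solutions, "n_solutions")
  assert_scalar_number(solution_jitter, "solution_jitter", lower = 0)
  if (solution_jitter >= 1) stop_config("solution_jitter must be < 1")
  seed <- assert_count(seed, "seed", lower = 0L)
  stopifnot(inherits(cost_schedule, "easement_cost_schedule"),
            inherits(dispute_profile, "dispute_cost_profile"),
            inherits(portfolio, "portfolio_params"))
  structure(list(dispute_rates = as.numeric(dispute_rates), years = years,
                 pe_probability = pe_probability,
                 loss_jitter_sd = loss_jitter_sd,
                 protection_target = protection_target,
                 trust_fraction = trust_fraction,
                 n_solutions = n_solutions,
                 solution_jitter = solution_jitter,
                 seed = seed, cost_schedule = cost_schedule,
                 dispute_profile = dispute_profile,
                 portfolio = portfolio),
            class = "scenario_config")
}

#' Build a trajectory from raw series
#'
#' Constructs a `trajectory` object (as returned by [simulate_purchase()]
#' and [simulate_easement()]) from explicit by-year series, e.g. scenario
#' totals published elsewhere. Year 0 is the first element.
#'
#' @param cumulative_cost Non-decreasing cumulative cost series, CAD.
#' @param protected_beta Non-increasing protected beta-score series.
#' @param events Optional dispute-event `data.frame`.
#' @return A `trajectory`.
#' @export
trajectory <- function(cumulative_cost, protected_beta, events = NULL) {
  if (length(cumulative_cost) != length(protected_beta) ||
      length(cumulative_cost) < 1L) {
    stop_input("cost and beta series must have equal positive length")
  }
  if (any(diff(cumulative_cost) < 0) || any(diff(protected_beta) > 0)) {
    stop_input("cumulative_cost must be non-decreasing and protected_beta non-increasing")
  }
  new_trajectory(length(cumulative_cost) - 1L, cumulative_cost,
                 protected_beta, events %||% empty_events())
}

new_trajectory <- function(years, cumulative_cost, protected_beta, events) {
  stopifnot(length(cumulative_cost) == years + 1L,
            length(protected_beta) == years + 1L)
  structure(list(year = 0:years, cumulative_cost = cumulative_cost,
                 protected_beta = protected_beta, events = events),
            class = "trajectory")
}

empty_events <- function() {
  data.frame(year = integer(0), easement_id = character(0),
             kind = character(0), cost = numeric(0),
             loss_fraction = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate the land-purchase scenario
#'
#' The full purchase cost (assessed value plus the trust fraction) is
#' charged at year 0 and the protected beta score stays constant: purchased
#' land suffers no disputes in this model.
#'
#' @param network A `reserve_network`.
#' @param config A [scenario_config()].
#' @return A `trajectory` (years 0..T, cumulative cost, protected beta,
#'   empty event table).
#' @export
simulate_purchase <- function(network, config = scenario_config()) {
  stopifnot(inherits(network, "reserve_network"),
            inherits(config, "scenario_config"))
  total <- purchase_cost(network$total_assessed_value,
                         purchase_cost_model(config$trust_fraction))
  new_trajectory(config$years,
                 rep(total, config$years + 1L),
                 rep(network$total_beta, config$years + 1L),
                 empty_events())
}

#' Simulate an easement scenario
#'
#' Year 0 charges [easement_setup_cost()] for every member parcel. In each
#' year 1..T every easement pays the recurring cost and independently
#' disputes with probability `dispute_rate`; PE disputes add a sampled
#' monetary cost, DE disputes multiply the easement's remaining beta score
#' by one minus a sampled loss fraction. Consumes the caller's RNG stream
#' unless `seed` is given.
#'
#' @param network A `reserve_network`.
#' @param config A [scenario_config()].
#' @param dispute_rate Per-easement per-year dispute probability; defaults
#'   to the first entry of `config$dispute_rates`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A `trajectory` whose `events` table lists every dispute.
#' @export
simulate_easement <- function(network, config = scenario_config(),
                              dispute_rate = config$dispute_rates[1],
                              seed = NULL) {
  stopifnot(inherits(network, "reserve_network"),
            inherits(config, "scenario_config"))
  assert_scalar_number(dispute_rate, "dispute_rate", lower = 0, upper = 1)
  members <- network$parcels
  n <- nrow(members)
  setup <- sum(easement_setup_cost(members$area_acres, config$cost_schedule))
  recurring <- easement_recurring_annual(config$cost_schedule) * n

  years <- config$years
  cost <- numeric(years + 1L)
  beta_t <- numeric(years + 1L)
  beta <- members$beta_score
  cost[1L] <- setup
  beta_t[1L] <- sum(beta)
  ev_year <- integer(0); ev_id <- character(0); ev_kind <- character(0)
  ev_cost <- numeric(0); ev_loss <- numeric(0)

  with_seed(seed, {
    for (t in seq_len(years)) {
      yearly <- recurring
      if (dispute_rate > 0) {
        hit <- which(stats::runif(n) < dispute_rate)
        if (length(hit) > 0L) {
          kind <- assign_dispute_kind(length(hit), config$pe_probability)
          pe <- hit[kind == "PE"]; de <- hit[kind == "DE"]
          pe_cost <- sample_dispute_cost(length(pe), config$dispute_profile)
          de_loss <- sample_loss_fraction(length(de), config$dispute_profile,
                                          config$loss_jitter_sd)
          yearly <- yearly + sum(pe_cost)
          beta[de] <- pmax(0, beta[de] * (1 - de_loss))
          k <- length(hit)
          ev_year <- c(ev_year, rep.int(t, k))
          ev_id <- c(ev_id, members$parcel_id[c(pe, de)])
          ev_kind <- c(ev_kind, rep.int("PE", length(pe)),
                       rep.int("DE", length(de)))
          ev_cost <- c(ev_cost, pe_cost, numeric(length(de)))
          ev_loss <- c(ev_loss, numeric(length(pe)), de_loss)
        }
      }
      cost[t + 1L] <- cost[t] + yearly
      beta_t[t + 1L] <- sum(beta)
    }
  })
  events <- data.frame(year = ev_year, easement_id = ev_id, kind = ev_kind,
                       cost = ev_cost, loss_fraction = ev_loss,
                       stringsAsFactors = FALSE)
  new_trajectory(years, cost, beta_t, events)
}

#' Run the full scenario experiment
#'
#' Builds the solution ensemble from the portfolio, simulates the purchase
#' scenario and an easement scenario at every configured dispute rate for
#' every solution, and summarises cost, protected-beta fraction and relative
#' cost-effectiveness over the ensemble (mean, min, max by year), plus
#' final-year biodiversity loss. Bit-reproducible for a fixed config seed.
#'
#' @param portfolio Parcel `data.frame`; `NULL` generates one from
#'   `config$portfolio`.
#' @param config A [scenario_config()].
#' @return An object of class `experiment_result` with elements `config`,
#'   `networks`, `trajectories` (tidy per scenario x solution x year) and
#'   `summary` (per scenario x year ensemble statistics).
#' @export
run_experiment <- function(portfolio = NULL, config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(portfolio)) portfolio <- generate_portfolio(config$portfolio)
  check_portfolio(portfolio)

  networks <- generate_solution_set(portfolio, config$n_solutions,
                                    config$protection_target,
                                    config$solution_jitter,
                                    seed = config$seed)
  rates <- config$dispute_rates
  sim_seeds <- matrix(derive_seeds(config$seed, length(rates) * length(networks)),
                      nrow = length(rates))

  rows <- list()
  for (s in seq_along(networks)) {
    net <- networks[[s]]
    pur <- simulate_purchase(net, config)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = "purchase", dispute_rate = NA_real_, solution = s,
      year = pur$year, cumulative_cost = pur$cumulative_cost,
      protected_beta = pur$protected_beta,
      beta_fraction = pur$protected_beta / net$total_beta,
      purchase_cost = pur$cumulative_cost[1L],
      stringsAsFactors = FALSE)
    for (r in seq_along(rates)) {
      tr <- simulate_easement(net, config, rates[r], seed = sim_seeds[r, s])
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sprintf("easement_rate_%g", rates[r]),
        dispute_rate = rates[r], solution = s,
        year = tr$year, cumulative_cost = tr$cumulative_cost,
        protected_beta = tr$protected_beta,
        beta_fraction = tr$protected_beta / net$total_beta,
        purchase_cost = pur$cumulative_cost[1L],
        stringsAsFactors = FALSE)
    }
  }
  trajectories <- do.call(rbind, rows)
  # relative cost-effectiveness vs the same solution's purchase scenario:
  # (beta fraction / easement cost) / (1 / purchase cost)
  trajectories$ce_relative <- ifelse(
    trajectories$scenario == "purchase", 1,
    trajectories$beta_fraction * trajectories$purchase_cost /
      trajectories$cumulative_cost)

  keys <- list(scenario = trajectories$scenario, year = trajectories$year)
  stat_by <- function(col, f, name) {
    a <- stats::aggregate(trajectories[[col]], by = keys, FUN = f)
    names(a)[3] <- name
    a
  }
  summ <- stat_by("cumulative_cost", mean, "cost_mean")
  specs <- list(
    cost_min = list("cumulative_cost", min),
    cost_max = list("cumulative_cost", max),
    beta_fraction_mean = list("beta_fraction", mean),
    beta_fraction_min = list("beta_fraction", min),
    beta_fraction_max = list("beta_fraction", max),
    ce_mean = list("ce_relative", mean),
    ce_min = list("ce_relative", min),
    ce_max = list("ce_relative", max))
  for (nm in names(specs)) {
    summ[[nm]] <- stat_by(specs[[nm]][[1]], specs[[nm]][[2]], nm)[[nm]]
  }
  summ <- summ[order(summ$scenario, summ$year), ]
  rownames(summ) <- NULL

  structure(list(config = config, networks = networks,
                 trajectories = trajectories, summary = summ),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result: %d solutions, rates {%s}, %d years>\n",
    x$config$n_solutions,
    paste(x$config$dispute_rates, collapse = ", "), x$config$years))
  invisible(x)
}
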