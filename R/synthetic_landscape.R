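# Synthetic cadastral landscape.
#
# The study region's parcel and assessment data are private, so portfolios
# are generated synthetically and calibrated to the region's printed
# statistics: ~193,623 candidate properties (default here 20,000, a 1:10
# scale-down), mean price per acre of $2.1M with 8% of properties under
# $100,000/acre (a lognormal price distribution solved in closed form from
# those two constraints), areas lognormal with median 5 acres truncated to
# the printed protected-area size range [0.01, 5,830] acres, and a
# beta-diversity score negatively rank-correlated with price per acre
# (affordable rural parcels tend to hold high conservation value).

#' Solve lognormal price-per-acre parameters from calibration targets
#'
#' Finds `(meanlog, sdlog)` of a lognormal such that the mean equals
#' `mean_price` and the fraction below `threshold` equals `frac_below`
#' (closed-form solution of the two moment/quantile constraints).
#'
#' @param mean_price Target mean price per acre, CAD (default 2.1e6).
#' @param frac_below Target fraction of parcels below `threshold`
#'   (default 0.08).
#' @param threshold Price threshold, CAD per acre (default 1e5).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
price_lognormal_params <- function(mean_price = 2.1e6, frac_below = 0.08,
                                   threshold = 1e5) {
  assert_scalar_number(mean_price, "mean_price", lower = 1e-12)
  assert_scalar_number(frac_below, "frac_below", lower = 1e-6, upper = 0.5)
  assert_scalar_number(threshold, "threshold", lower = 1e-12)
  z <- stats::qnorm(frac_below)
  # ln(threshold) = mu + z*sigma and mu = ln(mean) - sigma^2/2
  # => sigma^2/2 - z*sigma - ln(mean/threshold) = 0 (take the positive root)
  d <- log(mean_price / threshold)
  sigma <- z + sqrt(z^2 + 2 * d)
  mu <- log(mean_price) - sigma^2 / 2
  c(meanlog = mu, sdlog = sigma)
}

#' Portfolio generation parameters
#'
#' @param n_parcels Number of parcels (default 20,000, a 1:10 scale-down of
#'   the study region's 193,623 candidate properties).
#' @param area_log_mean,area_log_sd Lognormal parameters of parcel area in
#'   acres (defaults: median 5 acres, log-SD 1.5).
#' @param area_min,area_max Truncation bounds on area, acres (defaults 0.01
#'   and 5,830, the printed protected-area size range).
#' @param price_log_mean,price_log_sd Lognormal parameters of price per acre
#'   in CAD/acre; defaults solved from the regional calibration targets via
#'   [price_lognormal_params()].
#' @param beta_log_mean,beta_log_sd Lognormal parameters of the parcel
#'   beta-diversity score (dimensionless).
#' @param price_beta_correlation Spearman rank correlation in `[-1, 0]`
#'   between price per acre and beta score (default -0.3).
#' @param seed RNG seed.
#' @return An object of class `portfolio_params`.
#' @export
portfolio_params <- function(n_parcels = 20000,
                             area_log_mean = log(5),
                             area_log_sd = 1.5,
                             area_min = 0.01,
                             area_max = 5830,
                             price_log_mean = NULL,
                             price_log_sd = NULL,
                             beta_log_mean = log(0.2),
                             beta_log_sd = 0.8,
                             price_beta_correlation = -0.3,
                             seed = 1L) {
  n_parcels <- assert_count(n_parcels, "n_parcels")
  price_defaults <- price_lognormal_params()
  price_log_mean <- price_log_mean %||% unname(price_defaults["meanlog"])
  price_log_sd <- price_log_sd %||% unname(price_defaults["sdlog"])
  assert_scalar_number(area_log_mean, "area_log_mean")
  assert_scalar_number(area_log_sd, "area_log_sd", lower = 0)
  assert_scalar_number(area_min, "area_min", lower = 1e-12)
  assert_scalar_number(area_max, "area_max", lower = area_min)
  assert_scalar_number(price_log_mean, "price_log_mean")
  assert_scalar_number(price_log_sd, "price_log_sd", lower = 0)
  assert_scalar_number(beta_log_mean, "beta_log_mean")
  assert_scalar_number(beta_log_sd, "beta_log_sd", lower = 0)
  assert_scalar_number(price_beta_correlation, "price_beta_correlation",
                       lower = -1, upper = 0)
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(list(n_parcels = n_parcels,
                 area_log_mean = area_log_mean, area_log_sd = area_log_sd,
                 area_min = area_min, area_max = area_max,
                 price_log_mean = price_log_mean, price_log_sd = price_log_sd,
                 beta_log_mean = beta_log_mean, beta_log_sd = beta_log_sd,
                 price_beta_correlation = price_beta_correlation,
                 seed = seed),
            class = "portfolio_params")
}

#' Generate a synthetic parcel portfolio
#'
#' Areas are truncated-lognormal (drawn by inverse CDF so truncation costs
#' no extra RNG draws); price per acre is lognormal; the beta score is
#' lognormal, coupled to price per acre through a Gaussian copula so that
#' their Spearman correlation equals `price_beta_correlation`. Assessed
#' value is `area_acres * price_per_acre`. Deterministic for a fixed seed.
#'
#' @param params A [portfolio_params()].
#' @return A `data.frame` with columns `parcel_id`, `area_acres`,
#'   `assessed_value`, `beta_score` (plus `price_per_acre` as an attribute
#'   column for diagnostics).
#' @export
generate_portfolio <- function(params = portfolio_params()) {
  stopifnot(inherits(params, "portfolio_params"))
  n <- params$n_parcels
  with_seed(params$seed, {
    p_lo <- stats::plnorm(params$area_min, params$area_log_mean, params$area_log_sd)
    p_hi <- stats::plnorm(params$area_max, params$area_log_mean, params$area_log_sd)
    area <- stats::qlnorm(stats::runif(n, p_lo, p_hi),
                          params$area_log_mean, params$area_log_sd)
    z_price <- stats::rnorm(n)
    price <- stats::qlnorm(stats::pnorm(z_price),
                           params$price_log_mean, params$price_log_sd)
    # Spearman rho -> Pearson correlation of the normal scores
    rho_p <- 2 * sin(pi * params$price_beta_correlation / 6)
    z_beta <- rho_p * z_price + sqrt(1 - rho_p^2) * stats::rnorm(n)
    beta <- stats::qlnorm(stats::pnorm(z_beta),
                          params$beta_log_mean, params$beta_log_sd)
    data.frame(
      parcel_id = sprintf("P%06d", seq_len(n)),
      area_acres = area,
      assessed_value = area * price,
      beta_score = beta,
      price_per_acre = price,
      stringsAsFactors = FALSE
    )
  })
}

check_portfolio <- function(portfolio) {
  req <- c("parcel_id", "area_acres", "assessed_value", "beta_score")
  if (!is.data.frame(portfolio) || !all(req %in% names(portfolio))) {
    stop_input("portfolio must be a data.frame with columns ",
               paste(req, collapse = ", "))
  }
  if (nrow(portfolio) == 0L) stop_input("portfolio is empty")
  if (anyDuplicated(portfolio$parcel_id)) stop_input("duplicate parcel ids")
  if (any(portfolio$area_acres <= 0) || any(portfolio$assessed_value <= 0) ||
      any(portfolio$beta_score < 0)) {
    stop_input("parcel invariants violated (area > 0, value > 0, beta >= 0)")
  }
  invisible(portfolio)
}

new_reserve_network <- function(portfolio, idx, solution_id = 1L) {
  members <- portfolio[idx, c("parcel_id", "area_acres", "assessed_value",
                              "beta_score")]
  rownames(members) <- NULL
  structure(list(
    solution_id = as.integer(solution_id),
    parcel_ids = members$parcel_id,
    parcels = members,
    total_beta = sum(members$beta_score),
    total_area_acres = sum(members$area_acres),
    total_assessed_value = sum(members$assessed_value)
  ), class = "reserve_network")
}

#' @export
print.reserve_network <- function(x, ...) {
  cat(sprintf(
    "<reserve_network #%d: %d parcels, %.1f acres, $%s assessed, beta %.2f>\n",
    x$solution_id, length(x$parcel_ids), x$total_area_acres,
    format(round(x$total_assessed_value), big.mark = ","), x$total_beta))
  invisible(x)
}

#' Greedy minimum-cost reserve selection
#'
#' Stand-in for the systematic reserve-design (Marxan) stage: adds parcels
#' in descending `beta_score / cost` ratio (ties broken by smaller parcel
#' id) until the cumulative beta score reaches
#' `target_fraction * total beta` of the portfolio.
#'
#' @param portfolio Parcel `data.frame` (see [generate_portfolio()]).
#' @param target_fraction Fraction of the portfolio's total beta score to
#'   protect, in `(0, 1]` (default 0.20).
#' @param cost Optional per-parcel cost vector used for ranking; defaults to
#'   `portfolio$assessed_value`. Target attainment is always evaluated on
#'   the true beta scores.
#' @param solution_id Integer id stored on the returned network.
#' @return A `reserve_network`.
#' @export
select_network_greedy <- function(portfolio, target_fraction = 0.2,
                                  cost = NULL, solution_id = 1L) {
  check_portfolio(portfolio)
  assert_scalar_number(target_fraction, "target_fraction", lower = 1e-12, upper = 1)
  cost <- cost %||% portfolio$assessed_value
  if (length(cost) != nrow(portfolio) || any(cost <= 0)) {
    stop_input("cost must be positive and match the portfolio length")
  }
  total_beta <- sum(portfolio$beta_score)
  if (total_beta <= 0) stop_input("portfolio total beta score must be > 0")
  target <- target_fraction * total_beta
  ord <- order(-portfolio$beta_score / cost, portfolio$parcel_id)
  cum_beta <- cumsum(portfolio$beta_score[ord])
  k <- which(cum_beta >= target - 1e-9)[1]
  if (is.na(k)) k <- length(ord)  # numerically unreachable only by rounding
  new_reserve_network(portfolio, ord[seq_len(k)], solution_id)
}

#' Simulated-annealing reserve selection
#'
#' Minimises `total cost + penalty_weight * max(0, target_beta - beta)` over
#' parcel subsets by single-flip Metropolis annealing with a geometric
#' cooling schedule, starting from the greedy solution. Deterministic for a
#' fixed seed. `penalty_weight` must be large enough that a target
#' shortfall is never optimal; the default scales with the portfolio's
#' worst cost-per-beta ratio.
#'
#' @inheritParams select_network_greedy
#' @param penalty_weight Cost penalty per unit of beta shortfall; `NULL`
#'   picks `10 * max(assessed_value) / min(positive beta)` capped at 1e12.
#' @param n_iter Metropolis steps per restart (default 20,000).
#' @param t_init Initial temperature as a fraction of the greedy cost
#'   (default 0.3).
#' @param cooling Geometric cooling factor per step, in `(0, 1)`; `NULL`
#'   (default) decays the temperature to 1e-4 of its initial value over
#'   `n_iter` steps.
#' @param restarts Independent annealing chains; the best feasible solution
#'   across chains is kept (default 3).
#' @param seed RNG seed.
#' @return A `reserve_network`.
#' @export
select_network_annealed <- function(portfolio, target_fraction = 0.2,
                                    penalty_weight = NULL,
                                    n_iter = 20000, t_init = 0.3,
                                    cooling = NULL, restarts = 3, seed = 1L,
                                    cost = NULL, solution_id = 1L) {
  check_portfolio(portfolio)
  n_iter <- assert_count(n_iter, "n_iter")
  restarts <- assert_count(restarts, "restarts")
  assert_scalar_number(t_init, "t_init", lower = 1e-12)
  cooling <- cooling %||% exp(log(1e-4) / n_iter)
  assert_scalar_number(cooling, "cooling", lower = 1e-6, upper = 1 - 1e-12)
  cost <- cost %||% portfolio$assessed_value
  beta <- portfolio$beta_score
  target <- target_fraction * sum(beta)
  if (is.null(penalty_weight)) {
    pos <- beta[beta > 0]
    penalty_weight <- min(1e12, 10 * max(cost) / min(pos))
  }
  assert_scalar_number(penalty_weight, "penalty_weight", lower = 1e-12,
                       finite = FALSE)

  greedy <- select_network_greedy(portfolio, target_fraction, cost, solution_id)
  start <- portfolio$parcel_id %in% greedy$parcel_ids
  obj <- function(sel_cost, sel_beta) {
    sel_cost + penalty_weight * max(0, target - sel_beta)
  }
  n <- nrow(portfolio)
  best <- start
  best_obj <- obj(sum(cost[start]), sum(beta[start]))
  chain_seeds <- derive_seeds(seed, restarts)
  for (chain in seq_len(restarts)) {
    sel <- start
    cur_cost <- sum(cost[sel]); cur_beta <- sum(beta[sel])
    cur_obj <- obj(cur_cost, cur_beta)
    with_seed(chain_seeds[chain], {
      temp <- t_init * max(cur_cost, 1)
      flips <- sample.int(n, n_iter, replace = TRUE)
      us <- stats::runif(n_iter)
      for (i in seq_len(n_iter)) {
        j <- flips[i]
        delta_cost <- if (sel[j]) -cost[j] else cost[j]
        delta_beta <- if (sel[j]) -beta[j] else beta[j]
        new_obj <- obj(cur_cost + delta_cost, cur_beta + delta_beta)
        if (new_obj <= cur_obj || us[i] < exp((cur_obj - new_obj) / temp)) {
          sel[j] <- !sel[j]
          cur_cost <- cur_cost + delta_cost
          cur_beta <- cur_beta + delta_beta
          cur_obj <- new_obj
          if (cur_obj < best_obj && cur_beta >= target - 1e-9) {
            best <- sel; best_obj <- cur_obj
          }
        }
        temp <- temp * cooling
      }
    })
  }
  # polish: (a) drop redundant parcels, most expensive first, while the
  # target still holds; (b) 1-swap local search (replace a selected parcel
  # by a cheaper unselected one when feasible); iterate to a local optimum.
  # Applied to both the annealed best and the greedy start; the cheaper
  # result is kept, so the output never costs more than the greedy solution.
  polish <- function(sel) {
    repeat {
      changed <- FALSE
      sel_beta <- sum(beta[sel])
      for (j in order(-cost)) {
        if (sel[j] && sel_beta - beta[j] >= target - 1e-9) {
          sel[j] <- FALSE
          sel_beta <- sel_beta - beta[j]
          changed <- TRUE
        }
      }
      for (i in which(sel)) {
        candidates <- which(!sel & cost < cost[i] &
                              sel_beta - beta[i] + beta >= target - 1e-9)
        if (length(candidates) > 0L) {
          j <- candidates[which.min(cost[candidates])]
          sel[i] <- FALSE; sel[j] <- TRUE
          sel_beta <- sel_beta - beta[i] + beta[j]
          changed <- TRUE
        }
      }
      if (!changed) return(sel)
    }
  }
  # candidates: annealed best, the greedy start, and backward elimination
  # from the full set (strong when the optimum is many small parcels)
  cand <- list(polish(best),
               polish(portfolio$parcel_id %in% greedy$parcel_ids),
               polish(rep(TRUE, n)))
  feasible <- vapply(cand, function(s) sum(beta[s]) >= target - 1e-9, logical(1))
  cand <- cand[feasible]
  costs <- vapply(cand, function(s) sum(cost[s]), numeric(1))
  new_reserve_network(portfolio, which(cand[[which.min(costs)]]), solution_id)
}

#' Generate an ensemble of reserve networks
#'
#' Emulates the run-to-run variability of the systematic reserve-design
#' solver: for each solution, parcel costs are perturbed by independent
#' `Uniform(1 - jitter, 1 + jitter)` multipliers before greedy selection.
#' Every returned network meets the target on the true (unperturbed) beta
#' scores. Deterministic for a fixed seed.
#'
#' @inheritParams select_network_greedy
#' @param n_solutions Ensemble size (default 100).
#' @param jitter Half-width of the uniform cost perturbation, in `[0, 1)`
#'   (default 0.05).
#' @param seed RNG seed.
#' @return List of `reserve_network` objects with `solution_id` 1..n.
#' @export
generate_solution_set <- function(portfolio, n_solutions = 100,
                                  target_fraction = 0.2, jitter = 0.05,
                                  seed = 1L) {
  check_portfolio(portfolio)
  n_solutions <- assert_count(n_solutions, "n_solutions")
  assert_scalar_number(jitter, "jitter", lower = 0)
  if (jitter >= 1) stop_config("jitter must be < 1")
  with_seed(seed, {
    lapply(seq_len(n_solutions), function(s) {
      mult <- if (jitter > 0) {
        stats::runif(nrow(portfolio), 1 - jitter, 1 + jitter)
      } else rep(1, nrow(portfolio))
      select_network_greedy(portfolio, target_fraction,
                            cost = portfolio$assessed_value * mult,
                            solution_id = s)
    })
  })
}

#' Read / write a parcel portfolio CSV
#'
#' Column contract: `parcel_id,area_acres,assessed_value,beta_score`
#' (UTF-8, '.' decimal separator). Extra columns are preserved.
#'
#' @param path File path.
#' @return `read_portfolio_csv` returns the validated `data.frame`.
#' @export
read_portfolio_csv <- function(path) {
  if (!file.exists(path)) stop_input("portfolio file not found: ", path)
  check_portfolio(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_portfolio_csv
#' @param portfolio Parcel `data.frame`.
#' @export
write_portfolio_csv <- function(portfolio, path) {
  check_portfolio(portfolio)
  utils::write.csv(portfolio, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
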