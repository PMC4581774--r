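# shared fixtures and independent oracles

# tiny hand-specified portfolio: ratio order is 1, 2, 3
toy_portfolio <- function() {
  data.frame(
    parcel_id = c("A1", "A2", "A3"),
    area_acres = c(1, 2, 3),
    assessed_value = c(1, 2, 3),
    beta_score = c(10, 10, 10),
    stringsAsFactors = FALSE
  )
}

random_portfolio <- function(n, seed) {
  set.seed(seed)
  data.frame(
    parcel_id = sprintf("R%03d", seq_len(n)),
    area_acres = round(rlnorm(n, log(5), 1), 3),
    assessed_value = round(rlnorm(n, 12, 1.2), 2),
    beta_score = round(rlnorm(n, log(0.3), 0.7), 4),
    stringsAsFactors = FALSE
  )
}

# brute-force minimum-cost subset meeting the beta target (independent of
# the package's selection code); n <= 20
enumerate_optimum_cost <- function(portfolio, target_fraction) {
  n <- nrow(portfolio)
  stopifnot(n <= 20)
  target <- target_fraction * sum(portfolio$beta_score)
  beta <- portfolio$beta_score
  value <- portfolio$assessed_value
  best <- Inf
  for (mask in seq_len(2^n) - 1L) {
    sel <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L
    if (sum(beta[sel]) >= target - 1e-9) {
      cost <- sum(value[sel])
      if (cost < best) best <- cost
    }
  }
  best
}

# closed-form CDF of the bounded power-law dispute cost, written
# independently of the package: u ~ U(u_min, u_max), cost = a u^-b
oracle_dispute_cdf <- function(q, a = 4845.78, b = 0.701,
                               L = 1000, U = 400000) {
  u_min <- (a / U)^(1 / b)
  u_max <- (a / L)^(1 / b)
  p <- (u_max - (a / q)^(1 / b)) / (u_max - u_min)
  pmin(1, pmax(0, p))
}

# mean of the bounded power-law by quadrature over the uniform index
oracle_dispute_mean <- function(a = 4845.78, b = 0.701, L = 1000, U = 400000) {
  u_min <- (a / U)^(1 / b)
  u_max <- (a / L)^(1 / b)
  stats::integrate(function(u) a * u^(-b) / (u_max - u_min),
                   u_min, u_max, rel.tol = 1e-10)$value
}

# E[ clamp_{[0,1]}(x + e) ], e ~ N(0, sd): closed form
oracle_clamped_mean <- function(x, sd) {
  if (sd == 0) return(pmin(1, pmax(0, x)))
  a <- (0 - x) / sd
  b <- (1 - x) / sd
  x * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a)) + (1 - pnorm(b))
}

# mean DE loss fraction per event, by quadrature over the cost index
oracle_mean_loss <- function(jitter_sd, a = 4845.78, b = 0.701,
                             L = 1000, U = 400000) {
  u_min <- (a / U)^(1 / b)
  u_max <- (a / L)^(1 / b)
  stats::integrate(function(u) {
    x <- (pmin(U, pmax(L, a * u^(-b))) - L) / (U - L)
    oracle_clamped_mean(x, jitter_sd) / (u_max - u_min)
  }, u_min, u_max, rel.tol = 1e-9)$value
}

# a small reserve network built directly (bypasses selection) with n
# identical easements, for closed-form simulation checks
uniform_network <- function(n, area = 1, value = 1e5, beta = 1) {
  pf <- data.frame(
    parcel_id = sprintf("U%04d", seq_len(n)),
    area_acres = rep(area, n),
    assessed_value = rep(value, n),
    beta_score = rep(beta, n),
    stringsAsFactors = FALSE
  )
  select_network_greedy(pf, target_fraction = 1)
}
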