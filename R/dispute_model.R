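# Dispute event model.
#
# Dispute costs follow an inverse (low-cost-heavy) profile obtained from a
# rank-cost power fit across surveyed land trusts,
#   cost[$] = a * disputes^(-b),  a = 4,845.78, b = 0.701,
# bounded between $1,000 and $400,000. We draw the dispute index uniformly
# over the interval that maps onto [L, U] under the power function, which is
# equivalent to a bounded Pareto on [L, U] with shape 1/b (~1.43): small
# costs are frequent, large ones rare. An optional heavy-tail mixture adds,
# with small probability, draws from a normal distribution centred at the
# upper bound with its left tail cut off, to represent catastrophic suits.
#
# A dispute is either pre-emptive enforcement (PE: the holder sues before
# damage occurs -- monetary cost, no habitat loss) or damage enforcement
# (DE: damage already done, compensation recovered -- no net monetary cost,
# but biodiversity is lost). The DE loss fraction reuses the cost profile,
# linearly rescaled from [L, U] to [0, 1], with optional Gaussian jitter.

#' Dispute cost profile
#'
#' Constants of the bounded power-law dispute-cost distribution and its
#' optional truncated-normal heavy tail.
#'
#' @param coefficient Power-function coefficient `a` in CAD (default 4,845.78).
#' @param exponent Positive power-function exponent `b` (default 0.701).
#' @param lower_bound,upper_bound Support bounds in CAD (default 1,000 and
#'   400,000); `0 < lower_bound < upper_bound`.
#' @param tail_enabled If `TRUE`, mix in the heavy tail.
#' @param tail_probability Mixture weight of the tail component (default 0.01).
#' @param tail_mean,tail_sd Mean/SD of the tail normal, truncated below at
#'   `tail_mean` (defaults 400,000 and 1,000,000 CAD).
#' @return An object of class `dispute_cost_profile`.
#' @export
dispute_cost_profile <- function(coefficient = 4845.78,
                                 exponent = 0.701,
                                 lower_bound = 1000,
                                 upper_bound = 400000,
                                 tail_enabled = FALSE,
                                 tail_probability = 0.01,
                                 tail_mean = 400000,
                                 tail_sd = 1e6) {
  assert_scalar_number(coefficient, "coefficient", lower = 1e-12)
  assert_scalar_number(exponent, "exponent", lower = 1e-12)
  assert_scalar_number(lower_bound, "lower_bound", lower = 1e-12)
  assert_scalar_number(upper_bound, "upper_bound", lower = 1e-12)
  if (lower_bound >= upper_bound) stop_config("lower_bound must be < upper_bound")
  assert_scalar_number(tail_probability, "tail_probability", lower = 0, upper = 1)
  assert_scalar_number(tail_mean, "tail_mean", lower = 0)
  assert_scalar_number(tail_sd, "tail_sd", lower = 0)
  stopifnot(is.logical(tail_enabled), length(tail_enabled) == 1L)
  structure(list(coefficient = coefficient, exponent = exponent,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 tail_enabled = tail_enabled,
                 tail_probability = tail_probability,
                 tail_mean = tail_mean, tail_sd = tail_sd),
            class = "dispute_cost_profile")
}

# dispute-index interval that maps onto [L, U] under cost = a * u^(-b)
dispute_index_bounds <- function(profile) {
  with(profile, c(
    u_min = (coefficient / upper_bound)^(1 / exponent),
    u_max = (coefficient / lower_bound)^(1 / exponent)
  ))
}

#' Sample dispute costs
#'
#' Base draw: dispute index `u ~ Uniform(u_min, u_max)` where
#' `u_min = (a/U)^(1/b)` and `u_max = (a/L)^(1/b)`; cost is
#' `a * u^(-b)` clamped to `[L, U]`. With `tail_enabled`, each draw is
#' replaced with probability `tail_probability` by a draw from
#' `Normal(tail_mean, tail_sd)` truncated below at `tail_mean`.
#'
#' Consumes the caller's RNG stream.
#'
#' @param n Number of draws.
#' @param profile A [dispute_cost_profile()].
#' @return Numeric vector of costs in CAD.
#' @export
sample_dispute_cost <- function(n, profile = dispute_cost_profile()) {
  stopifnot(inherits(profile, "dispute_cost_profile"))
  n <- assert_count(n, "n", lower = 0L)
  if (n == 0L) return(numeric(0))
  ub <- dispute_index_bounds(profile)
  u <- stats::runif(n, ub[["u_min"]], ub[["u_max"]])
  cost <- pmin(profile$upper_bound,
               pmax(profile$lower_bound,
                    profile$coefficient * u^(-profile$exponent)))
  if (profile$tail_enabled && profile$tail_probability > 0) {
    in_tail <- stats::runif(n) < profile$tail_probability
    k <- sum(in_tail)
    if (k > 0L) {
      # left-truncated normal via inverse CDF on the upper half
      cost[in_tail] <- stats::qnorm(stats::runif(k, 0.5, 1),
                                    profile$tail_mean, profile$tail_sd)
    }
  }
  cost
}

#' CDF of the base (tail-free) dispute-cost distribution
#'
#' Closed form: `P(cost <= c) = (u_max - (a/c)^(1/b)) / (u_max - u_min)` for
#' `c` in `[L, U]`.
#'
#' @param q Quantiles in CAD.
#' @param profile A [dispute_cost_profile()].
#' @return Probabilities.
#' @export
dispute_cost_cdf <- function(q, profile = dispute_cost_profile()) {
  stopifnot(inherits(profile, "dispute_cost_profile"))
  ub <- dispute_index_bounds(profile)
  p <- (ub[["u_max"]] - (profile$coefficient / q)^(1 / profile$exponent)) /
    (ub[["u_max"]] - ub[["u_min"]])
  pmin(1, pmax(0, p))
}

#' Map a dispute cost to a biodiversity-loss fraction
#'
#' The loss fraction follows the same distribution as dispute cost, linearly
#' rescaled from the cost support `[L, U]` to `[0, 1]`:
#' `(cost - L) / (U - L)`.
#'
#' @param cost Costs in CAD, each within `[lower_bound, upper_bound]`.
#' @param profile A [dispute_cost_profile()].
#' @return Loss fractions in `[0, 1]`.
#' @export
cost_to_loss_fraction <- function(cost, profile = dispute_cost_profile()) {
  stopifnot(inherits(profile, "dispute_cost_profile"))
  if (any(cost < profile$lower_bound | cost > profile$upper_bound)) {
    stop_input("cost outside [lower_bound, upper_bound]")
  }
  (cost - profile$lower_bound) / (profile$upper_bound - profile$lower_bound)
}

#' Sample biodiversity-loss fractions for DE disputes
#'
#' Draws a dispute cost from the base profile (the heavy tail never applies
#' to losses: the loss scale is bounded at 100%), rescales it to `[0, 1]`,
#' adds `Normal(0, jitter_sd)` noise and truncates to `[0, 1]`.
#'
#' @param n Number of draws.
#' @param profile A [dispute_cost_profile()].
#' @param jitter_sd SD of the additive Gaussian jitter on the `[0, 1]` loss
#'   scale (default 0.05, i.e. 5% of the total loss possible).
#' @return Loss fractions in `[0, 1]`.
#' @export
sample_loss_fraction <- function(n, profile = dispute_cost_profile(),
                                 jitter_sd = 0.05) {
  assert_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  base_profile <- profile
  base_profile$tail_enabled <- FALSE
  loss <- cost_to_loss_fraction(sample_dispute_cost(n, base_profile), profile)
  if (jitter_sd > 0 && length(loss) > 0) {
    loss <- loss + stats::rnorm(length(loss), 0, jitter_sd)
  }
  pmin(1, pmax(0, loss))
}

#' Assign dispute kinds
#'
#' Each dispute is independently pre-emptive enforcement (`"PE"`) with
#' probability `pe_probability`, else damage enforcement (`"DE"`).
#'
#' @param n Number of disputes.
#' @param pe_probability Probability of PE (default 0.5).
#' @return Character vector of `"PE"` / `"DE"`.
#' @export
assign_dispute_kind <- function(n, pe_probability = 0.5) {
  assert_scalar_number(pe_probability, "pe_probability", lower = 0, upper = 1)
  n <- assert_count(n, "n", lower = 0L)
  if (n == 0L) return(character(0))
  ifelse(stats::runif(n) < pe_probability, "PE", "DE")
}
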