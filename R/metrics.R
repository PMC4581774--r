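# Cost-effectiveness and comparative summaries.
#
# Cost-effectiveness of a scenario is the fraction of the initially
# protected biodiversity still protected, divided by the cumulative network
# cost, standardised by the same quantity for land purchase:
#   ce(t) = (B_e(t) / C_e(t)) / (B_p / C_p)
# where B is the protected fraction of the initial target (so B_p = 1 and
# with zero disputes the ratio reduces to C_p / C_e(t)). Biodiversity-loss
# percentages are always reported relative to the initially protected
# scores (the protection target = 100%), never the whole landscape.

#' Relative cost-effectiveness of an easement trajectory
#'
#' @param easement_traj,purchase_traj `trajectory` objects over the same
#'   horizon for the same network.
#' @return An object of class `cost_effectiveness`: list with `year` and
#'   `ce_relative`, the by-year ratio (values > 1 mean the easement
#'   strategy protects more biodiversity per dollar than purchase).
#' @export
relative_cost_effectiveness <- function(easement_traj, purchase_traj) {
  stopifnot(inherits(easement_traj, "trajectory"),
            inherits(purchase_traj, "trajectory"))
  if (length(easement_traj$year) != length(purchase_traj$year)) {
    stop_input("trajectories must share the same horizon")
  }
  c_p <- purchase_traj$cumulative_cost[length(purchase_traj$cumulative_cost)]
  b_p0 <- purchase_traj$protected_beta[1L]
  if (c_p <= 0 || b_p0 <= 0) stop_input("purchase cost and beta must be > 0")
  if (any(easement_traj$cumulative_cost <= 0)) {
    stop_input("easement cumulative cost must be > 0 at every year")
  }
  b_e <- easement_traj$protected_beta / easement_traj$protected_beta[1L]
  b_p <- purchase_traj$protected_beta / b_p0
  ce <- (b_e / easement_traj$cumulative_cost) /
    (b_p[length(b_p)] / c_p)
  structure(list(year = easement_traj$year, ce_relative = ce),
            class = "cost_effectiveness")
}

#' Percent cost reduction of an easement strategy versus purchase
#'
#' `100 * (1 - easement / purchase)`.
#'
#' @param purchase_cost_total,easement_cost_total Scenario totals (same units).
#' @return Percentage.
#' @export
pct_cost_reduction <- function(purchase_cost_total, easement_cost_total) {
  if (any(purchase_cost_total <= 0)) stop_input("purchase cost must be > 0")
  100 * (1 - easement_cost_total / purchase_cost_total)
}

#' Scenario cost as a percentage of a baseline
#'
#' `pct_cost_of_baseline` returns `100 * cost / baseline` (the "cost level");
#' `pct_cost_change` returns `100 * (cost / baseline - 1)` (the increase).
#'
#' @param cost_total,baseline_cost_total Scenario totals (same units).
#' @return Percentage.
#' @export
pct_cost_of_baseline <- function(cost_total, baseline_cost_total) {
  if (any(baseline_cost_total <= 0)) stop_input("baseline cost must be > 0")
  100 * cost_total / baseline_cost_total
}

#' @rdname pct_cost_of_baseline
#' @export
pct_cost_change <- function(cost_total, baseline_cost_total) {
  pct_cost_of_baseline(cost_total, baseline_cost_total) - 100
}

#' Summarise an experiment in the style of the main results table
#'
#' One row per scenario: mean (min-max) cumulative cost at the horizon, mean
#' (min-max) biodiversity-loss percentage relative to the initially
#' protected scores, percent cost change versus the no-dispute easement
#' baseline, and percent cost reduction versus land purchase. Values are
#' exact; rounding is left to report writers.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @return A `data.frame` with columns `scenario`, `dispute_rate`,
#'   `cost_mean`, `cost_min`, `cost_max`, `loss_pct_mean`, `loss_pct_min`,
#'   `loss_pct_max`, `cost_change_vs_no_dispute_pct`,
#'   `cost_reduction_vs_purchase_pct`.
#' @export
summarize_table2 <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  tr <- result$trajectories
  horizon <- max(tr$year)
  fin <- tr[tr$year == horizon, ]
  key <- unique(fin[, c("scenario", "dispute_rate")])
  key <- key[order(is.na(key$dispute_rate), key$dispute_rate,
                   decreasing = c(TRUE, FALSE), method = "radix"), ]

  per_scen <- lapply(seq_len(nrow(key)), function(i) {
    f <- fin[fin$scenario == key$scenario[i], ]
    loss <- 100 * (1 - f$beta_fraction)
    data.frame(scenario = key$scenario[i],
               dispute_rate = key$dispute_rate[i],
               cost_mean = mean(f$cumulative_cost),
               cost_min = min(f$cumulative_cost),
               cost_max = max(f$cumulative_cost),
               loss_pct_mean = mean(loss),
               loss_pct_min = min(loss),
               loss_pct_max = max(loss),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_scen)

  purchase_mean <- tab$cost_mean[tab$scenario == "purchase"]
  base_row <- tab$scenario != "purchase" & tab$dispute_rate == 0
  tab$cost_change_vs_no_dispute_pct <- NA_real_
  tab$cost_reduction_vs_purchase_pct <- NA_real_
  if (any(base_row)) {
    base_mean <- tab$cost_mean[base_row][1]
    ease <- tab$scenario != "purchase"
    tab$cost_change_vs_no_dispute_pct[ease] <-
      pct_cost_change(tab$cost_mean[ease], base_mean)
  }
  if (length(purchase_mean) == 1) {
    tab$cost_reduction_vs_purchase_pct <-
      pct_cost_reduction(purchase_mean, tab$cost_mean)
  }
  rownames(tab) <- NULL
  tab
}
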